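# Variable-site detection, sliding-window geometry and IUPAC consensus
# calling: the building blocks of the copy-separation workflow.

#' Parameters for copy separation
#'
#' Houses the three parameters the workflow is driven by (`copy_number`,
#' `read_length`, `overlap`) plus the thresholds of this implementation.
#' Defaults mirror the standard parameterization for 300 bp amplicon reads:
#' `copy_number = 2`, `read_length = 300`, `overlap = 225`.
#'
#' @param copy_number Number of gene copies expected (k), `>= 1`. 2 for a
#'   tetraploid.
#' @param read_length Sliding-window width in bp (the sequencing read
#'   length).
#' @param overlap Overlap between consecutive windows in bp;
#'   `0 < overlap < read_length`.
#' @param min_site_coverage Minimum reads covering a column for it to enter
#'   variable-site detection.
#' @param copy_site_freq Minor-state frequency at or above which a variable
#'   site is classified copy-distinguishing (expected ~1/k for a true
#'   inter-copy difference); in `(0, 0.5]`.
#' @param allele_freq_band Two fractions `(low, high)`: within one copy's
#'   read cluster, a minor base whose frequency reaches `low` is treated as
#'   a real allele and written as an IUPAC ambiguity code.
#' @param min_link_support Minimum number of concordant reads spanning a
#'   pair of copy-distinguishing sites for a junction to count as linked.
#' @param noise_freq Floor of the per-column noise threshold; the effective
#'   threshold is `max(noise_freq, 3/coverage)`.
#' @param seed Integer seed controlling any stochastic refinement.
#' @return An object of class `separator_params`.
#' @export
separator_params <- function(copy_number = 2L, read_length = 300L,
                             overlap = 225L, min_site_coverage = 5L,
                             copy_site_freq = 0.35,
                             allele_freq_band = c(0.30, 0.70),
                             min_link_support = 2L, noise_freq = 0.05,
                             seed = 1L) {
  copy_number <- as.integer(copy_number)
  read_length <- as.integer(read_length)
  overlap <- as.integer(overlap)
  if (copy_number < 1L) stop("copy_number must be >= 1")
  if (read_length < 2L) stop("read_length must be >= 2")
  if (!(overlap > 0L && overlap < read_length)) {
    stop("overlap must satisfy 0 < overlap < read_length")
  }
  if (!(copy_site_freq > 0 && copy_site_freq <= 0.5)) {
    stop("copy_site_freq must be in (0, 0.5]")
  }
  if (!(length(allele_freq_band) == 2L &&
        allele_freq_band[1] < allele_freq_band[2] &&
        allele_freq_band[1] > 0 && allele_freq_band[2] <= 1)) {
    stop("allele_freq_band must be (low, high) with 0 < low < high <= 1")
  }
  structure(
    list(copy_number = copy_number, read_length = read_length,
         overlap = overlap,
         min_site_coverage = as.integer(min_site_coverage),
         copy_site_freq = copy_site_freq,
         allele_freq_band = as.numeric(allele_freq_band),
         min_link_support = as.integer(min_link_support),
         noise_freq = noise_freq, seed = as.integer(seed)),
    class = "separator_params"
  )
}

# Per-column state counts. mat: character matrix; cover: logical matrix of
# the same shape (votes only inside a read's mapped span). Returns an
# ncol(mat) x 5 matrix with columns A, C, G, T, '-'. 'N' and ambiguity
# codes in reads never vote.
.state_counts <- function(mat, cover = NULL) {
  if (is.null(cover)) cover <- matrix(TRUE, nrow(mat), ncol(mat))
  cnt <- vapply(.base_states,
                function(b) colSums((mat == b) & cover),
                numeric(ncol(mat)))
  if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = 1L)
  colnames(cnt) <- .base_states
  cnt
}

# bits (1..15) -> IUPAC code lookup for vectorized consensus calling
.bits_to_code <- local({
  base_bit <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  out <- character(15L)
  for (key in names(.iupac_set_to_code)) {
    bases <- strsplit(key, "")[[1L]]
    out[sum(base_bit[bases])] <- .iupac_set_to_code[[key]]
  }
  out
})

# Vectorized consensus from a count matrix (rows = columns of the
# alignment, cols = A,C,G,T,'-'). Rule, per column:
#   * no votes                         -> 'N'
#   * gap fraction > 1/2               -> '-'
#   * else merge every nucleotide whose frequency (over all votes) reaches
#     band[1] into one IUPAC code; if none reaches it, the major nucleotide.
.consensus_from_counts <- function(cnt, band) {
  covs <- rowSums(cnt)
  out <- rep("N", nrow(cnt))
  has <- covs > 0
  if (!any(has)) return(out)
  frac <- cnt / pmax(covs, 1)
  bits <- (frac[, 1L] >= band[1]) * 1L + (frac[, 2L] >= band[1]) * 2L +
    (frac[, 3L] >= band[1]) * 4L + (frac[, 4L] >= band[1]) * 8L
  call <- ifelse(bits > 0L, .bits_to_code[pmax(bits, 1L)], NA_character_)
  nuc <- cnt[, 1:4, drop = FALSE]
  majn <- max.col(nuc, ties.method = "first")
  need <- is.na(call)
  call[need] <- c("A", "C", "G", "T")[majn[need]]
  gap_major <- frac[, 5L] > 0.5
  call[gap_major] <- "-"
  out[has] <- call[has]
  out
}

#' Call an IUPAC consensus from a cluster of aligned reads
#'
#' Within one copy's read cluster the two alleles are expected near 50/50,
#' so a column whose minor base frequency falls inside `band` is written as
#' the IUPAC merge of the bases involved (unphased allelic variation); an
#' error-level minority is dropped in favor of the major base. A column
#' whose votes are mostly gaps is called `'-'`; a column with no votes is
#' `'N'`.
#'
#' @param reads Character vector of equal-length aligned sequences, or a
#'   character matrix (reads x columns).
#' @param band Allele-frequency band `(low, high)`; bases at frequency
#'   `>= low` are merged.
#' @param cover Optional logical matrix marking which cells lie inside each
#'   read's mapped span (defaults to everything).
#' @return A single consensus string.
#' @export
call_consensus <- function(reads, band = c(0.30, 0.70), cover = NULL) {
  mat <- if (is.matrix(reads)) reads else do.call(rbind, strsplit(reads, ""))
  cnt <- .state_counts(mat, cover)
  paste(.consensus_from_counts(cnt, band), collapse = "")
}

#' Detect variable sites in a read alignment
#'
#' Scans every column for a minor state (the gap is a countable deletion
#' allele; `N` never votes) whose frequency clears the noise threshold
#' `max(noise_freq, 3/coverage)`, and classifies each retained site:
#' `copy_distinguishing` when the minor frequency is at least
#' `copy_site_freq` (the ~1/k signal of an inter-copy difference at k
#' equally amplified copies), otherwise `allelic` (the ~1/(2k) signal of a
#' heterozygous allele within one copy).
#'
#' @param aln A [read_alignment()].
#' @param params A [separator_params()].
#' @return A data frame with columns `column`, `major`, `minor`,
#'   `major_count`, `minor_count`, `coverage`, `minor_freq`, `klass`.
#' @export
detect_variable_sites <- function(aln, params = separator_params()) {
  stopifnot(inherits(aln, "read_alignment"))
  cnt <- .state_counts(aln$mat, aln$cover)
  coverage <- rowSums(cnt)
  if (all(coverage == 0)) stop("empty alignment: no column has any coverage")
  idx <- seq_len(nrow(cnt))
  maj_i <- max.col(cnt, ties.method = "first")
  maj_n <- cnt[cbind(idx, maj_i)]
  cnt2 <- cnt
  cnt2[cbind(idx, maj_i)] <- -1
  min_i <- max.col(cnt2, ties.method = "first")
  min_n <- cnt[cbind(idx, min_i)]
  minor_freq <- ifelse(coverage > 0, min_n / coverage, 0)
  noise_thr <- pmax(params$noise_freq, 3 / pmax(coverage, 1))
  keep <- coverage >= params$min_site_coverage & min_n > 0 &
    minor_freq >= noise_thr
  klass <- ifelse(minor_freq >= params$copy_site_freq,
                  "copy_distinguishing", "allelic")
  data.frame(
    column = which(keep),
    major = .base_states[maj_i[keep]],
    minor = .base_states[min_i[keep]],
    major_count = as.integer(maj_n[keep]),
    minor_count = as.integer(min_n[keep]),
    coverage = as.integer(coverage[keep]),
    minor_freq = minor_freq[keep],
    klass = klass[keep],
    stringsAsFactors = FALSE
  )
}

#' Build the sliding windows of the separation workflow
#'
#' Windows of width `read_length` start at column 1 and advance by
#' `read_length - overlap`, so consecutive windows share exactly `overlap`
#' columns. The final window is right-anchored at `aln_length` (its start
#' shifted left, never truncated) so the 3' tail keeps full width and at
#' least the nominal overlap.
#'
#' @param aln_length Alignment length in columns.
#' @param read_length Window width in bp; if it reaches `aln_length` a
#'   single full-length window is returned.
#' @param overlap Overlap between consecutive windows, `< read_length`.
#' @return Data frame with columns `index`, `start`, `end`.
#' @export
build_windows <- function(aln_length, read_length, overlap) {
  aln_length <- as.integer(aln_length)
  read_length <- as.integer(read_length)
  overlap <- as.integer(overlap)
  stopifnot(aln_length >= 1L, read_length >= 1L)
  if (overlap >= read_length || overlap < 1L) {
    stop("overlap must satisfy 0 < overlap < read_length")
  }
  if (read_length >= aln_length) {
    return(data.frame(index = 1L, start = 1L, end = aln_length))
  }
  step <- read_length - overlap
  starts <- seq.int(1L, aln_length - read_length + 1L, by = step)
  last_start <- aln_length - read_length + 1L
  if (starts[length(starts)] < last_start) starts <- c(starts, last_start)
  data.frame(index = seq_along(starts), start = starts,
             end = starts + read_length - 1L)
}
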