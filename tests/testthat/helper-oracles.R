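# Independent oracles and small fixture builders used across the suite.
# Every oracle is a deliberately naive re-computation, kept separate from
# the package's own code paths.

NUCS <- c("A", "C", "G", "T")

mk_aln <- function(seqs, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("r%03d", seq_along(seqs))
  read_alignment(stats::setNames(seqs, ids))
}

random_seq <- function(n, alphabet = NUCS) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Exhaustive minimum of the window-clustering objective over ALL
# 2-partitions of the reads (k = 2): for each cluster and column, reads
# with a countable state minus the majority count.
oracle_min_objective <- function(mat, sites) {
  Ci <- matrix(match(mat[, sites, drop = FALSE], c(NUCS, "-")), nrow(mat))
  n <- nrow(Ci)
  m <- ncol(Ci)
  best <- Inf
  for (mask in 0:(2^(n - 1L) - 1L)) {
    sel <- c(TRUE, bitwAnd(mask, bitwShiftL(1L, 0:(n - 2L))) > 0L)
    J <- 0
    for (side in list(sel, !sel)) {
      if (!any(side)) next
      sub <- Ci[side, , drop = FALSE]
      for (j in seq_len(m)) {
        v <- sub[, j]
        v <- v[!is.na(v)]
        if (length(v)) J <- J + length(v) - max(tabulate(v, 5L))
      }
    }
    if (J < best) best <- J
  }
  best
}

# Naive per-position scan for mismatch columns of a sequence pair
# (IUPAC-aware through base-set expansion, N skipped, '-' only matching
# itself).
oracle_site_positions <- function(a, b) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  sets <- function(ch) {
    if (ch == "-") return("-")
    if (ch == "N") return(character(0))
    strsplit(Biostrings::IUPAC_CODE_MAP[[ch]], "")[[1L]]
  }
  out <- integer(0)
  for (i in seq_along(av)) {
    if (av[i] == "N" || bv[i] == "N") next
    if (!length(intersect(sets(av[i]), sets(bv[i])))) out <- c(out, i)
  }
  out
}

# Naive codon scan for premature stops: drop gaps, drop frame_offset
# leading bases, read successive triplets, report the alignment column of
# base 1 of every TAA/TAG/TGA before the last complete codon. Ambiguity
# codes are expanded; a codon counts only if all resolutions are stops.
oracle_stop_scan <- function(seq, frame_offset = 0L) {
  s <- strsplit(seq, "")[[1L]]
  keep <- which(s != "-")
  if (frame_offset > 0L) keep <- keep[-(1:frame_offset)]
  ncod <- length(keep) %/% 3L
  res <- integer(0)
  if (ncod < 2L) return(res)
  expand <- function(ch) {
    v <- Biostrings::IUPAC_CODE_MAP[[ch]]
    if (is.null(v)) return(NULL)
    strsplit(v, "")[[1L]]
  }
  for (ci in seq_len(ncod - 1L)) {
    idx <- keep[(3L * ci - 2L):(3L * ci)]
    e <- lapply(s[idx], expand)
    if (any(vapply(e, is.null, logical(1)))) next
    combos <- expand.grid(e[[1L]], e[[2L]], e[[3L]],
                          stringsAsFactors = FALSE)
    codons <- apply(combos, 1L, paste, collapse = "")
    if (all(codons %in% c("TAA", "TAG", "TGA"))) res <- c(res, idx[1L])
  }
  res
}
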