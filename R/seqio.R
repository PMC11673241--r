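# FASTA input/output and the aligned read-matrix container.
#
# All coordinates in this package are 1-based alignment columns, inclusive at
# both ends ("628-634" style ranges).

#' Read sequences from a FASTA file
#'
#' Records are returned in file order as a named character vector,
#' uppercased, with RNA `U` normalized to `T`. The parser is shape-agnostic:
#' rectangularity is only enforced when a [read_alignment()] is built.
#'
#' @param path Path to a (multi-record, wrapped or unwrapped) FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty FASTA file: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!startsWith(trimws(first), ">")) {
    stop("malformed FASTA (line 1 does not start with '>'): ", path)
  }
  x <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("malformed FASTA in ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(x) == 0L) stop("no records in FASTA file: ", path)
  seqs <- chartr("U", "T", toupper(as.character(x)))
  names(seqs) <- names(x)
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width in characters.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), length(seqs) > 0L)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("every sequence needs a non-empty name")
  }
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path,
                              width = width)
  invisible(path)
}

#' Construct a rectangular read alignment
#'
#' Represents an exported multiple alignment of reads mapped to a single
#' reference amplicon, with the reference row already removed. Every
#' sequence must have the same length; the alphabet is the 16 IUPAC codes
#' plus `'-'`.
#'
#' @param seqs Named character vector of gap-padded aligned reads. Unnamed
#'   input gets `read1..n` labels.
#' @param reference_id Optional label of the mapping reference, stored as
#'   metadata only. It must not appear among the read names.
#' @return An object of class `read_alignment` with elements `ids`, `mat`
#'   (character matrix, reads x columns), `length`, `spans` (first/last
#'   non-gap column per read), `cover` (logical matrix: is column j inside
#'   read i's mapped span) and `reference_id`.
#' @export
read_alignment <- function(seqs, reference_id = NULL) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  if (is.null(names(seqs))) {
    names(seqs) <- sprintf("read%d", seq_along(seqs))
  }
  lens <- unique(nchar(seqs))
  if (length(lens) != 1L) {
    stop("alignment is not rectangular: sequence lengths ",
         paste(sort(lens), collapse = ", "))
  }
  if (!is.null(reference_id) && reference_id %in% names(seqs)) {
    stop("the reference row must be removed before analysis: ", reference_id)
  }
  mat <- do.call(rbind, strsplit(unname(seqs), ""))
  bad <- setdiff(unique(as.vector(mat)), names(.iupac_code_to_set))
  if (length(bad)) {
    stop("invalid symbols in alignment: ",
         paste(sQuote(bad), collapse = ", "))
  }
  nongap <- mat != "-"
  spans <- t(apply(nongap, 1L, function(z) {
    w <- which(z)
    if (length(w)) c(w[1L], w[length(w)]) else c(NA_integer_, NA_integer_)
  }))
  jj <- matrix(seq_len(lens), nrow = nrow(mat), ncol = lens, byrow = TRUE)
  cover <- jj >= spans[, 1L] & jj <= spans[, 2L]
  cover[is.na(cover)] <- FALSE
  structure(
    list(ids = names(seqs), mat = mat, length = lens, spans = spans,
         cover = cover, reference_id = reference_id),
    class = "read_alignment"
  )
}

#' @export
as.character.read_alignment <- function(x, ...) {
  stats::setNames(apply(x$mat, 1L, paste, collapse = ""), x$ids)
}

#' @export
print.read_alignment <- function(x, ...) {
  cat("read_alignment:", nrow(x$mat), "reads x", x$length, "columns\n")
  if (!is.null(x$reference_id)) cat("  mapped against:", x$reference_id, "\n")
  invisible(x)
}

#' Non-gap length of aligned sequences
#'
#' @param seqs Character vector of (possibly gapped) sequences.
#' @return Integer vector of lengths counted over non-gap characters.
#' @export
nongap_length <- function(seqs) {
  nchar(gsub("-", "", seqs, fixed = TRUE))
}

#' Drop reads shorter than a minimum non-gap length
#'
#' Mirrors the upstream length filter applied before mapping ("reads equal
#' to or larger than a set value, e.g. 250"). Length is counted on non-gap
#' characters; order is preserved and the result may be empty.
#'
#' @param reads Named character vector of reads (gapped or not).
#' @param min_length Minimum length in bp; 0 keeps everything.
#' @return Filtered character vector.
#' @export
filter_short_reads <- function(reads, min_length) {
  stopifnot(is.numeric(min_length), length(min_length) == 1L,
            min_length >= 0)
  reads[nongap_length(reads) >= min_length]
}

#' Remove exact-duplicate reads
#'
#' Collapses reads with identical aligned sequence (including gaps) to the
#' first occurrence, keeping that read's id; order is otherwise stable.
#'
#' @param reads Named character vector of reads.
#' @return Deduplicated character vector.
#' @export
dedup_reads <- function(reads) {
  reads[!duplicated(unname(reads))]
}

#' Trim an alignment to the amplicon boundaries
#'
#' Removes every column outside `[start, end]` (1-based, inclusive), e.g.
#' positions mapped beyond the span of the PCR primers. Reads that become
#' all-gaps are dropped.
#'
#' @param aln A [read_alignment()].
#' @param start,end Column bounds, `1 <= start <= end <= aln$length`.
#' @return A new `read_alignment` of width `end - start + 1`.
#' @export
trim_to_boundaries <- function(aln, start, end) {
  stopifnot(inherits(aln, "read_alignment"))
  if (!(is.numeric(start) && is.numeric(end) && start >= 1 &&
        end <= aln$length && start <= end)) {
    stop("invalid trim range [", start, ",", end,
         "] for alignment of length ", aln$length)
  }
  sub <- aln$mat[, start:end, drop = FALSE]
  seqs <- stats::setNames(apply(sub, 1L, paste, collapse = ""), aln$ids)
  keep <- grepl("[^-]", seqs)
  if (!any(keep)) stop("no reads left after trimming to [", start, ",", end, "]")
  read_alignment(seqs[keep], reference_id = aln$reference_id)
}
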