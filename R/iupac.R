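# IUPAC nucleotide-code algebra shared by all modules.
#
# Conventions used package-wide:
#   * '-' is an alignment gap. Inside the mapped span of a read it is a real,
#     countable state (a deletion allele); outside the span it is padding.
#   * 'N' is missing data: it matches nothing and never votes.

.iupac_code_to_set <- local({
  m <- strsplit(Biostrings::IUPAC_CODE_MAP, "")
  m[["-"]] <- "-"
  m
})

.iupac_set_to_code <- local({
  m <- Biostrings::IUPAC_CODE_MAP
  stats::setNames(
    names(m),
    vapply(strsplit(m, ""), function(b) paste(sort(b), collapse = ""), "")
  )
})

# 4-bit base encoding: A=1, C=2, G=4, T=8; ambiguity codes are unions. The
# gap gets its own bit so it only ever matches itself, and 'N' is 0 so that
# missing data matches nothing.
.iupac_bits <- local({
  base_bit <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  bits <- vapply(.iupac_code_to_set, function(b) {
    sum(base_bit[b[b %in% names(base_bit)]])
  }, integer(1))
  bits["N"] <- 0L
  bits["-"] <- 16L
  bits
})

.base_states <- c("A", "C", "G", "T", "-")

#' Bases represented by an IUPAC nucleotide code
#'
#' @param code A single IUPAC nucleotide code (or `"-"`).
#' @return Character vector of the bases in `{A,C,G,T}` the code stands for
#'   (`"-"` returns itself).
#' @examples
#' iupac_bases("R") # A, G
#' @export
iupac_bases <- function(code) {
  stopifnot(is.character(code), length(code) == 1L, nchar(code) == 1L)
  set <- .iupac_code_to_set[[toupper(code)]]
  if (is.null(set)) stop("not an IUPAC nucleotide code: '", code, "'")
  set
}

#' Merge a set of bases into one IUPAC ambiguity code
#'
#' The inverse of [iupac_bases()]: the standard one-letter code whose base
#' set equals the input. Symmetric in input order and idempotent on
#' singletons.
#'
#' @param bases Non-empty character vector over `{A,C,G,T}` (duplicates
#'   allowed).
#' @return A single IUPAC code, e.g. `iupac_merge(c("A","G"))` is `"R"`.
#' @export
iupac_merge <- function(bases) {
  bases <- toupper(as.character(bases))
  if (length(bases) == 0L) {
    stop("iupac_merge() needs a non-empty set of bases")
  }
  bad <- setdiff(unique(bases), c("A", "C", "G", "T"))
  if (length(bad)) {
    stop("not nucleotide bases: ", paste(bad, collapse = ", "))
  }
  key <- paste(sort(unique(bases)), collapse = "")
  unname(.iupac_set_to_code[[key]])
}

#' IUPAC-aware symbol comparison
#'
#' Two symbols match when their base sets intersect (so `"A"` matches `"R"`).
#' The gap `"-"` matches only itself; `"N"` and any non-IUPAC symbol match
#' nothing (missing data carries no information).
#'
#' @param a,b Character vectors of single symbols, recycled to a common
#'   length.
#' @return Logical vector.
#' @export
match_iupac <- function(a, b) {
  ba <- .iupac_bits[a]
  bb <- .iupac_bits[b]
  ba[is.na(ba)] <- 0L
  bb[is.na(bb)] <- 0L
  unname(bitwAnd(ba, bb) > 0L)
}
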