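# Reading-frame quality control (indels, unexpected stop codons) and
# neighboring-variable-site distance diagnostics.
#
# Coordinates are 1-based alignment columns throughout; ranges print as
# "start–end" (inclusive). Decayed gene copies accumulate deletions and
# premature stops, and the distances between neighboring variable sites of
# a sequence pair determine the read length needed to phase it.

#' Find indels of a sequence relative to a reference
#'
#' Maximal runs of `'-'` in `seq` where the reference has bases are
#' deletions; runs of `'-'` in the reference where `seq` has bases are
#' insertions (tagged as such, e.g. "1292 (insertion)").
#'
#' @param seq,reference Aligned sequences of equal length (character
#'   scalars).
#' @return Data frame with columns `start`, `end`, `type`
#'   (`deletion`/`insertion`) and `label` (formatted range), sorted by
#'   `start`.
#' @export
find_indels <- function(seq, reference) {
  s <- strsplit(seq[[1L]], "")[[1L]]
  r <- strsplit(reference[[1L]], "")[[1L]]
  if (length(s) != length(r)) {
    stop("sequence and reference have different aligned lengths (",
         length(s), " vs ", length(r), ")")
  }
  runs_of <- function(mask) {
    if (!any(mask)) {
      return(data.frame(start = integer(0), end = integer(0)))
    }
    rl <- rle(mask)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    data.frame(start = starts[rl$values], end = ends[rl$values])
  }
  del <- runs_of(s == "-" & r != "-")
  ins <- runs_of(r == "-" & s != "-")
  out <- rbind(
    if (nrow(del)) cbind(del, type = "deletion") else NULL,
    if (nrow(ins)) cbind(ins, type = "insertion") else NULL
  )
  if (is.null(out)) {
    out <- data.frame(start = integer(0), end = integer(0),
                      type = character(0), stringsAsFactors = FALSE)
  }
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out$label <- vapply(seq_len(nrow(out)), function(i) {
    base <- if (out$start[i] == out$end[i]) {
      as.character(out$start[i])
    } else {
      paste0(out$start[i], "–", out$end[i])
    }
    if (out$type[i] == "insertion") paste0(base, " (insertion)") else base
  }, "")
  out
}

#' Find unexpected stop codons in an aligned coding sequence
#'
#' Gap columns are skipped and the remaining bases compacted into codons
#' starting after `frame_offset` leading bases — so a frameshifting indel
#' propagates downstream, exactly how a decayed copy accumulates stops.
#' Every TAA/TAG/TGA before the final codon is reported at the alignment
#' column of its first base. An IUPAC-ambiguous codon counts only if every
#' resolution is a stop (e.g. TAR, TRA).
#'
#' @param seq Aligned sequence (character scalar; may contain `'-'` and
#'   IUPAC codes).
#' @param frame_offset 0, 1 or 2 leading non-gap bases before the first
#'   codon.
#' @return Integer vector of alignment columns (first base of each
#'   premature stop codon).
#' @export
find_unexpected_stops <- function(seq, frame_offset = 0L) {
  stopifnot(frame_offset %in% 0:2)
  s <- strsplit(seq[[1L]], "")[[1L]]
  keep <- which(s != "-")
  if (frame_offset > 0L) keep <- keep[-seq_len(min(frame_offset, length(keep)))]
  n_codons <- length(keep) %/% 3L
  if (n_codons < 2L) return(integer(0))
  stops <- c("TAA", "TAG", "TGA")
  is_stop <- function(codon) {
    sets <- lapply(codon, function(ch) {
      set <- .iupac_code_to_set[[ch]]
      if (is.null(set) || identical(set, "-")) return(NULL)
      set
    })
    if (any(vapply(sets, is.null, logical(1)))) return(FALSE)
    combos <- expand.grid(sets, stringsAsFactors = FALSE)
    all(apply(combos, 1L, paste, collapse = "") %in% stops)
  }
  out <- integer(0)
  for (ci in seq_len(n_codons - 1L)) {           # final codon excluded
    idx <- keep[(3L * ci - 2L):(3L * ci)]
    if (is_stop(s[idx])) out <- c(out, idx[1L])
  }
  out
}

#' Distances between neighboring variable sites of a sequence pair
#'
#' Finds the columns where two aligned sequences differ (IUPAC-aware:
#' symbols whose base sets intersect are a match, so an R in a copy
#' consensus matches an A allele; columns where either sequence is `N` are
#' skipped; a gap mismatches any base) and the base-pair distances between
#' neighboring such sites. These gaps determine the read length needed to
#' phase the pair.
#'
#' @param seqA,seqB Aligned sequences of equal length (character scalars).
#' @param comparison_kind `"copy_pair"` (two homoeologs) or `"allele_pair"`
#'   (two alleles of one copy); metadata only.
#' @return Object of class `site_distance_profile`: `positions` (ascending
#'   mismatch columns), `gaps` (successive differences, bp), `max_gap`
#'   (`NA` with fewer than two sites), `length`, `comparison_kind`. Zero
#'   mismatches give an empty, valid profile.
#' @export
site_distances <- function(seqA, seqB, comparison_kind = "copy_pair") {
  a <- strsplit(seqA[[1L]], "")[[1L]]
  b <- strsplit(seqB[[1L]], "")[[1L]]
  if (length(a) != length(b)) {
    stop("sequences have different aligned lengths (", length(a), " vs ",
         length(b), ")")
  }
  usable <- a != "N" & b != "N"
  mism <- usable & !match_iupac(a, b)
  positions <- which(mism)
  gaps <- if (length(positions) >= 2L) diff(positions) else integer(0)
  structure(
    list(positions = positions, gaps = gaps,
         max_gap = if (length(gaps)) max(gaps) else NA_integer_,
         length = length(a), comparison_kind = comparison_kind),
    class = "site_distance_profile")
}

#' @export
print.site_distance_profile <- function(x, ...) {
  cat("site_distance_profile (", x$comparison_kind, "): ",
      length(x$positions), " variable sites over ", x$length, " bp",
      sep = "")
  if (length(x$gaps)) cat("; max gap ", x$max_gap, " bp", sep = "")
  cat("\n")
  invisible(x)
}

#' Read length required to phase a sequence pair
#'
#' A linking read must span two neighboring variable sites within the
#' usable fraction of its length (the window overlap of the assembly
#' workflow, 225/300 = 0.75 by default). The bound is
#' `ceiling((max_gap + 1) / overlap_fraction)`: the smallest read length
#' whose usable span covers the widest inter-site gap plus both end sites.
#' Allele pairs with gaps beyond ~800 bp therefore cannot be phased by any
#' short-read platform.
#'
#' @param profile A [site_distances()] result.
#' @param overlap_fraction Usable fraction of the read length, in (0, 1].
#' @return List of class `read_length_requirement`: `required` (bp; 0 with
#'   a notice when the profile has fewer than two sites), `max_gap`,
#'   `overlap_fraction`, `formula`, `notice`.
#' @export
required_read_length <- function(profile, overlap_fraction = 0.75) {
  stopifnot(inherits(profile, "site_distance_profile"),
            overlap_fraction > 0, overlap_fraction <= 1)
  if (length(profile$gaps) == 0L) {
    return(structure(
      list(required = 0L, max_gap = NA_integer_,
           overlap_fraction = overlap_fraction,
           formula = "ceiling((max_gap + 1) / overlap_fraction)",
           notice = paste("fewer than two variable sites: no linking",
                          "constraint, requirement undefined")),
      class = "read_length_requirement"))
  }
  required <- as.integer(ceiling((profile$max_gap + 1) / overlap_fraction))
  structure(
    list(required = required, max_gap = profile$max_gap,
         overlap_fraction = overlap_fraction,
         formula = "ceiling((max_gap + 1) / overlap_fraction)",
         notice = NULL),
    class = "read_length_requirement")
}

#' @export
print.read_length_requirement <- function(x, ...) {
  if (!is.null(x$notice)) {
    cat("read length requirement: undefined (", x$notice, ")\n", sep = "")
  } else {
    cat("required read length: ", x$required, " bp  [max inter-site gap ",
        x$max_gap, " bp, usable fraction ", x$overlap_fraction, "]\n",
        sep = "")
  }
  invisible(x)
}

#' Strip plot of neighboring-variable-site distances
#'
#' One strip per profile (per gene for copy pairs, per species for allele
#' pairs), with every inter-site gap as one point, plus the tidy table
#' behind the plot.
#'
#' @param profiles Named list of [site_distances()] results.
#' @param file Optional PNG path; when `NULL` the plot goes to the active
#'   device.
#' @param main Plot title.
#' @return Data frame with columns `group` and `gap` (one row per plotted
#'   point), invisibly.
#' @export
plot_site_distances <- function(profiles, file = NULL,
                                main = "Distances between neighboring variable sites") {
  if (!length(profiles)) stop("no profiles to plot")
  if (is.null(names(profiles)) || any(!nzchar(names(profiles)))) {
    names(profiles) <- sprintf("pair%d", seq_along(profiles))
  }
  tab <- do.call(rbind, lapply(names(profiles), function(nm) {
    g <- profiles[[nm]]$gaps
    if (!length(g)) return(NULL)
    data.frame(group = nm, gap = as.integer(g), stringsAsFactors = FALSE)
  }))
  if (is.null(tab) || !nrow(tab)) {
    stop("no inter-site distances to plot (all profiles have < 2 sites)")
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 520)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  graphics::stripchart(gap ~ factor(group, levels = unique(group)),
                       data = tab, vertical = TRUE, method = "jitter",
                       jitter = 0.15, pch = 1,
                       ylab = "distance between neighboring variable sites (bp)",
                       main = main)
  invisible(tab)
}
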