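# Phasing of Sanger-sequenced clone sets into homoeologous copies and
# alleles, with removal of PCR-chimeric clones.
#
# A clone set for one amplicon holds up to a few dozen full-length Sanger
# sequences. True haplotypes come in at most 2k flavors (k copies x up to 2
# alleles); PCR template switching occasionally produces a recombinant
# clone whose prefix matches one haplotype and suffix another. Work happens
# on the alignment reduced to its variable columns.

#' Reduce a clone alignment to its variable sites
#'
#' @param clones Named character vector of equal-length aligned clone
#'   sequences.
#' @return List with `columns` (1-based alignment positions where at least
#'   two distinct non-N states occur), `reduced` (clones x variable-sites
#'   character matrix) and `n_clones`. Zero columns signals a single
#'   haplotype.
#' @export
reduce_to_variable_sites <- function(clones) {
  stopifnot(is.character(clones), length(clones) >= 2L)
  lens <- unique(nchar(clones))
  if (length(lens) != 1L) stop("clones must be aligned to equal length")
  if (is.null(names(clones))) {
    names(clones) <- sprintf("clone%d", seq_along(clones))
  }
  mat <- do.call(rbind, strsplit(unname(clones), ""))
  rownames(mat) <- names(clones)
  nstates <- apply(mat, 2L, function(col) {
    length(unique(col[col != "N"]))
  })
  columns <- which(nstates >= 2L)
  list(columns = columns,
       reduced = mat[, columns, drop = FALSE],
       full = mat,
       n_clones = length(clones))
}

# mismatch between two signature vectors, ignoring positions where either
# is 'N'
.sig_dist <- function(a, b) {
  ok <- a != "N" & b != "N"
  sum(a[ok] != b[ok])
}

# Best single-crossover explanation of signature x as prefix-of-a +
# suffix-of-b. Returns the minimal mismatch and the cut index (crossover
# between variable sites cut and cut+1), or NULL when x has < 2 sites.
.best_crossover <- function(x, a, b) {
  m <- length(x)
  if (m < 2L) return(NULL)
  pa <- cumsum(x != a & x != "N" & a != "N")
  sb <- rev(cumsum(rev(x != b & x != "N" & b != "N")))
  cost <- pa[seq_len(m - 1L)] + sb[2L:m]
  cut <- which.min(cost)
  list(mismatch = cost[cut], cut = cut)
}

#' Detect PCR-chimeric clones
#'
#' Clusters clone signatures into haplotype groups by identity within
#' `max_mismatch`, then classifies each minority group: its clones are
#' chimeric when the group consensus is more than `max_mismatch` away from
#' every accepted haplotype group yet is explained within `max_mismatch` by
#' a single crossover between two accepted group consensuses (prefix from
#' one, suffix from the other). The inferred crossover is reported as the
#' interval between the flanking discordant variable sites. Groups that are
#' neither real haplotypes (more than `2k` already found) nor explainable
#' by one crossover fall to `unassigned`.
#'
#' @param reduced A [reduce_to_variable_sites()] result (or a character
#'   matrix of clones x variable sites, in which case crossover intervals
#'   are reported in site indices).
#' @param k Number of gene copies (so up to `2k` haplotype groups).
#' @param max_mismatch Tolerated mismatches (sequencing error) between a
#'   clone and its group consensus.
#' @return Data frame with one row per clone: `id`, `group` (haplotype
#'   group index or NA), `status` in `{assigned, chimeric, unassigned}`,
#'   `crossover_start`, `crossover_end` (alignment columns, NA unless
#'   chimeric). Attribute `groups` holds the accepted group consensuses.
#' @export
detect_chimeric_clones <- function(reduced, k = 2L, max_mismatch = 1L) {
  if (is.matrix(reduced)) {
    reduced <- list(columns = seq_len(ncol(reduced)), reduced = reduced,
                    n_clones = nrow(reduced))
  }
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2 for chimera detection")
  mat <- reduced$reduced
  cols <- reduced$columns
  ids <- rownames(mat)
  if (is.null(ids)) ids <- sprintf("clone%d", seq_len(nrow(mat)))
  n <- nrow(mat)
  res <- data.frame(id = ids, group = NA_integer_,
                    status = "unassigned",
                    crossover_start = NA_integer_,
                    crossover_end = NA_integer_,
                    stringsAsFactors = FALSE)
  if (ncol(mat) == 0L) {
    # no variable sites: a single haplotype, nothing can be chimeric
    res$group <- 1L
    res$status <- "assigned"
    attr(res, "groups") <- matrix(character(0), nrow = 1L)
    return(res)
  }

  sigstr <- apply(mat, 1L, paste, collapse = "")
  u_str <- sort(unique(sigstr))
  counts <- as.integer(table(factor(sigstr, levels = u_str)))
  # order unique signatures by support (desc), then lexicographically:
  # deterministic and invariant to clone input order
  ouniq <- order(-counts, u_str)
  u_str <- u_str[ouniq]
  counts <- counts[ouniq]
  U <- do.call(rbind, strsplit(u_str, ""))

  # greedy grouping of signatures within max_mismatch of a group consensus
  g_members <- list()
  for (i in seq_along(u_str)) {
    placed <- FALSE
    for (g in seq_along(g_members)) {
      cons <- .group_consensus_chr(U, counts, g_members[[g]])
      if (.sig_dist(U[i, ], cons) <= max_mismatch) {
        g_members[[g]] <- c(g_members[[g]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) g_members[[length(g_members) + 1L]] <- i
  }
  g_support <- vapply(g_members, function(mm) sum(counts[mm]), integer(1))
  g_cons <- lapply(seq_along(g_members), function(g) {
    .group_consensus_chr(U, counts, g_members[[g]])
  })
  # process groups by support desc (ties: consensus lexicographic)
  g_ord <- order(-g_support,
                 vapply(g_cons, paste, "", collapse = ""))

  accepted <- integer(0)
  g_status <- rep(NA_character_, length(g_members))
  g_cross <- vector("list", length(g_members))
  for (g in g_ord) {
    x <- g_cons[[g]]
    # within tolerance of an already accepted haplotype? (can happen when
    # greedy grouping split borderline signatures)
    d_acc <- vapply(accepted, function(h) .sig_dist(x, g_cons[[h]]),
                    integer(1))
    if (length(accepted) && any(d_acc <= max_mismatch)) {
      tgt <- accepted[which.min(d_acc)]
      g_members[[tgt]] <- c(g_members[[tgt]], g_members[[g]])
      g_status[g] <- "merged"
      g_cross[[g]] <- tgt
      next
    }
    # single-crossover explanation by two accepted haplotypes?
    explained <- NULL
    if (length(accepted) >= 2L) {
      for (ai in accepted) {
        for (bi in setdiff(accepted, ai)) {
          bc <- .best_crossover(x, g_cons[[ai]], g_cons[[bi]])
          if (!is.null(bc) && bc$mismatch <= max_mismatch) {
            if (is.null(explained) || bc$mismatch < explained$mismatch) {
              explained <- c(bc, list(a = ai, b = bi))
            }
          }
        }
      }
    }
    if (!is.null(explained)) {
      g_status[g] <- "chimeric"
      g_cross[[g]] <- explained
    } else if (length(accepted) < 2L * k) {
      accepted <- c(accepted, g)
      g_status[g] <- "accepted"
    } else {
      g_status[g] <- "unassigned"
      warning("clone group beyond 2k haplotypes and not explainable by a ",
              "single crossover; left unassigned", call. = FALSE)
    }
  }

  group_label <- stats::setNames(seq_along(accepted), accepted)
  for (g in seq_along(g_members)) {
    st <- g_status[g]
    if (is.na(st) || st == "merged") next
    rows <- which(sigstr %in% u_str[g_members[[g]]])
    if (st == "accepted") {
      res$group[rows] <- group_label[[as.character(g)]]
      res$status[rows] <- "assigned"
    } else if (st == "chimeric") {
      res$status[rows] <- "chimeric"
      cut <- g_cross[[g]]$cut
      res$crossover_start[rows] <- cols[cut]
      res$crossover_end[rows] <- cols[cut + 1L]
    } else {
      res$status[rows] <- "unassigned"
    }
  }
  # clones merged into an accepted group
  for (g in seq_along(g_members)) {
    if (!identical(g_status[g], "merged")) next
    tgt <- g_cross[[g]]
    rows <- which(sigstr %in% u_str[setdiff(g_members[[g]],
                                            unlist(g_members[accepted]))])
    rows <- rows[res$status[rows] == "unassigned"]
    res$group[rows] <- group_label[[as.character(tgt)]]
    res$status[rows] <- "assigned"
  }
  attr(res, "groups") <- do.call(rbind, g_cons[accepted])
  attr(res, "columns") <- cols
  res
}

.group_consensus_chr <- function(U, counts, members) {
  sub <- U[members, , drop = FALSE]
  w <- counts[members]
  vapply(seq_len(ncol(sub)), function(j) {
    v <- sub[, j]
    ok <- v != "N"
    if (!any(ok)) return("N")
    tab <- tapply(w[ok], v[ok], sum)
    names(tab)[order(-tab, names(tab))][1L]
  }, "")
}

#' Phase a clone set into copies and alleles
#'
#' Removes chimeric clones ([detect_chimeric_clones()]), then merges the
#' surviving haplotype groups into `k` copies by pairing the two groups
#' most similar to each other (alleles of one copy diverge far less than
#' homoeologous copies do). Copy consensuses are full-length, with IUPAC
#' ambiguity codes where the two alleles differ; allele sequences are
#' reported when each allele group is supported by at least two clones.
#' Copies are labeled so that the one with more gap characters gets the
#' later label; alleles are suffixed `a`/`b` by support.
#'
#' @param clones Named character vector of aligned clone sequences.
#' @param k Number of gene copies expected.
#' @param max_mismatch Per-clone mismatch tolerance (Sanger error).
#' @return An object of class `phased_haplotypes`: `copies` (named
#'   character vector of consensus sequences), `alleles` (named list of
#'   length-2 character vectors, possibly empty), `assignments` (the clone
#'   table), `removed_chimeras` (subset of chimeric clones with crossover
#'   intervals) and `warnings`.
#' @export
phase_clone_set <- function(clones, k = 2L, max_mismatch = 1L) {
  red <- reduce_to_variable_sites(clones)
  warnings <- character(0)
  if (length(red$columns) == 0L) {
    cons <- call_consensus(red$full, band = c(0.30, 0.70))
    return(structure(
      list(copies = stats::setNames(cons, "Copy I"),
           alleles = list(),
           assignments = data.frame(id = names(clones), group = 1L,
                                    status = "assigned",
                                    stringsAsFactors = FALSE),
           removed_chimeras = data.frame(),
           warnings = "no variable sites: single haplotype"),
      class = "phased_haplotypes"))
  }
  det <- detect_chimeric_clones(red, k = k, max_mismatch = max_mismatch)
  if (all(det$status == "chimeric")) {
    stop("all clones look chimeric; cannot phase this clone set")
  }
  groups <- sort(unique(det$group[det$status == "assigned"]))
  n_groups <- length(groups)
  full <- red$full

  group_seq <- function(g) {
    members <- det$id[det$status == "assigned" & det$group == g]
    sub <- full[members, , drop = FALSE]
    # plain majority per column: Sanger clones are single molecules, so no
    # allele band applies within one haplotype group
    vapply(seq_len(ncol(sub)), function(j) {
      v <- sub[, j]
      ok <- v != "N"
      if (!any(ok)) return("N")
      tab <- table(v[ok])
      names(tab)[order(-tab, names(tab))][1L]
    }, "")
  }
  g_seqs <- lapply(groups, group_seq)
  g_supp <- vapply(groups, function(g) {
    sum(det$status == "assigned" & det$group == g)
  }, integer(1))

  if (n_groups < k) {
    warnings <- c(warnings, paste0(
      "only ", n_groups, " haplotype group(s) found for copy_number ", k,
      "; a copy may be missing or lost"))
  }

  # pair groups into copies by minimum inter-consensus distance: each
  # pairing merges two allele groups into one copy, so with n_groups
  # haplotype groups and k copies exactly n_groups - k pairings happen
  pairs <- list()
  remaining <- seq_len(n_groups)
  for (pi in seq_len(max(0L, n_groups - k))) {
    dd <- expand.grid(i = remaining, j = remaining)
    dd <- dd[dd$i < dd$j, , drop = FALSE]
    dd$d <- mapply(function(i, j) {
      .sig_dist(g_seqs[[i]], g_seqs[[j]])
    }, dd$i, dd$j)
    best <- dd[order(dd$d, dd$i, dd$j), ][1L, ]
    pairs[[length(pairs) + 1L]] <- c(best$i, best$j)
    remaining <- setdiff(remaining, c(best$i, best$j))
  }
  units <- c(pairs, as.list(remaining))

  copy_seq <- function(unit) {
    if (length(unit) == 1L) return(paste(g_seqs[[unit]], collapse = ""))
    a <- g_seqs[[unit[1L]]]
    b <- g_seqs[[unit[2L]]]
    merged <- vapply(seq_along(a), function(j) {
      if (a[j] == b[j]) return(a[j])
      if (a[j] %in% c("A", "C", "G", "T") && b[j] %in% c("A", "C", "G", "T")) {
        return(iupac_merge(c(a[j], b[j])))
      }
      if (a[j] == "N") return(b[j])
      if (b[j] == "N") return(a[j])
      # gap vs base heterozygosity cannot be coded in IUPAC; keep the base
      if (a[j] == "-") b[j] else a[j]
    }, "")
    paste(merged, collapse = "")
  }
  copy_seqs <- vapply(units, copy_seq, "")
  gapn <- nchar(copy_seqs) - nongap_length(copy_seqs)
  ordc <- order(gapn, copy_seqs)
  units <- units[ordc]
  copy_seqs <- copy_seqs[ordc]
  labels <- paste("Copy", as.character(utils::as.roman(seq_along(units))))
  names(copy_seqs) <- labels

  alleles <- list()
  for (ci in seq_along(units)) {
    unit <- units[[ci]]
    if (length(unit) == 2L && all(g_supp[unit] >= 2L)) {
      ao <- unit[order(-g_supp[unit], unit)]
      al <- stats::setNames(
        c(paste(g_seqs[[ao[1L]]], collapse = ""),
          paste(g_seqs[[ao[2L]]], collapse = "")),
        paste0(gsub("Copy ", "", labels[ci]), c("a", "b")))
      alleles[[labels[ci]]] <- al
    }
  }

  chim <- det[det$status == "chimeric",
              c("id", "crossover_start", "crossover_end")]
  structure(
    list(copies = copy_seqs, alleles = alleles, assignments = det,
         removed_chimeras = chim, warnings = warnings),
    class = "phased_haplotypes")
}

#' @export
print.phased_haplotypes <- function(x, ...) {
  cat("phased_haplotypes:", length(x$copies), "cop",
      if (length(x$copies) == 1L) "y" else "ies", "\n")
  for (lab in names(x$copies)) {
    has_al <- if (!is.null(x$alleles[[lab]])) " (alleles a/b)" else ""
    cat("  ", lab, ": ", nongap_length(x$copies[[lab]]), " bp", has_al,
        "\n", sep = "")
  }
  cat("  chimeric clones removed:", nrow(x$removed_chimeras), "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
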