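# Per-window read clustering, overlap linking of window consensuses into
# full-length copy chains, and automated chimera verification.

# ---- internal clustering machinery -----------------------------------------

# Weighted clustering objective: total mismatch of member reads to their
# cluster's majority consensus at the window's copy-distinguishing sites.
# Ci: integer-coded signature matrix (unique signatures x sites, NA =
# uninformative), w: multiplicity of each signature, grp: cluster label.
.cluster_objective <- function(Ci, w, grp, k) {
  total <- 0
  for (c in seq_len(k)) {
    rows <- which(grp == c)
    if (!length(rows)) next
    sub <- Ci[rows, , drop = FALSE]
    wc <- w[rows]
    for (j in seq_len(ncol(sub))) {
      v <- sub[, j]
      ok <- !is.na(v)
      if (!any(ok)) next
      cnts <- vapply(1:5, function(s) sum(wc[ok][v[ok] == s]), numeric(1))
      total <- total + sum(cnts) - max(cnts)
    }
  }
  total
}

# Majority consensus codes (1..5, NA if uncovered) per cluster at the
# signature sites; ties go to the lexicographically first state.
.group_site_consensus <- function(Ci, w, grp, k) {
  cons <- matrix(NA_integer_, k, ncol(Ci))
  for (c in seq_len(k)) {
    rows <- which(grp == c)
    if (!length(rows)) next
    sub <- Ci[rows, , drop = FALSE]
    wc <- w[rows]
    for (j in seq_len(ncol(sub))) {
      v <- sub[, j]
      ok <- !is.na(v)
      if (!any(ok)) next
      cnts <- vapply(1:5, function(s) sum(wc[ok][v[ok] == s]), numeric(1))
      cons[c, j] <- which.max(cnts)
    }
  }
  cons
}

# Mismatch count of each signature against each cluster consensus (NA cells
# on either side carry no information).
.signature_cost <- function(Ci, cons) {
  u <- nrow(Ci)
  k <- nrow(cons)
  cost <- matrix(0, u, k)
  for (c in seq_len(k)) {
    cm <- matrix(cons[c, ], u, ncol(Ci), byrow = TRUE)
    d <- (Ci != cm)
    d[is.na(d)] <- FALSE
    cost[, c] <- rowSums(d)
  }
  cost
}

# Exact minimum-mismatch bipartition of unique signatures (weighted), by
# enumeration over all 2^(u-1) splits. Used for k = 2 whenever at most
# .exact_signature_limit distinct signatures occur in a window, so that
# small problems are solved to optimality; larger windows fall back to the
# agglomerative + swap-refinement heuristic below.
.exact_signature_limit <- 15L

.exact_bipartition <- function(Ci, w) {
  u <- nrow(Ci)
  m <- ncol(Ci)
  OH <- matrix(0, u, m * 5L)
  for (s in 1:5) {
    hit <- (Ci == s)
    hit[is.na(hit)] <- FALSE
    OH[, (seq_len(m) - 1L) * 5L + s] <- hit * w
  }
  tot <- colSums(OH)
  site_max <- function(v) {
    mm <- matrix(v, nrow = 5L)
    sum(pmax(mm[1L, ], mm[2L, ], mm[3L, ], mm[4L, ], mm[5L, ]))
  }
  bestJ <- Inf
  bestg <- rep(1L, u)
  for (mask in 0:(2^(u - 1L) - 1L)) {
    sel <- c(TRUE, bitwAnd(mask, bitwShiftL(1L, 0:(u - 2L))) > 0L)
    cs1 <- colSums(OH[sel, , drop = FALSE])
    cs2 <- tot - cs1
    J <- sum(cs1) - site_max(cs1) + sum(cs2) - site_max(cs2)
    if (J < bestJ - 1e-9) {
      bestJ <- J
      bestg <- ifelse(sel, 1L, 2L)
    }
  }
  bestg
}

# Deterministic clustering of unique read signatures into k groups:
# weighted average-linkage agglomeration, consensus/reassignment iteration,
# then steepest single-signature moves on the exact objective.
.cluster_signatures <- function(Ci, w, k) {
  u <- nrow(Ci)
  m <- ncol(Ci)
  # pairwise normalized mismatch; pairs sharing no informative site sit at
  # a neutral 0.5 so they merge neither eagerly nor last
  D <- matrix(0, u, u)
  SH <- matrix(0, u, u)
  for (j in seq_len(m)) {
    v <- Ci[, j]
    nn <- !is.na(v)
    sh <- outer(nn, nn, "&")
    df <- outer(v, v, "!=")
    df[is.na(df)] <- FALSE
    SH <- SH + sh
    D <- D + (df & sh)
  }
  dist <- ifelse(SH > 0, D / SH, 0.5)
  # weighted average-linkage agglomeration down to k clusters
  active <- seq_len(u)
  W <- as.numeric(w)
  CD <- dist
  grp_of <- seq_len(u)
  members <- as.list(seq_len(u))
  while (length(active) > k) {
    na_ <- length(active)
    best <- c(Inf, NA, NA)
    for (ai in seq_len(na_ - 1L)) {
      for (bi in (ai + 1L):na_) {
        a <- active[ai]; b <- active[bi]
        if (CD[a, b] < best[1] - 1e-12) best <- c(CD[a, b], a, b)
      }
    }
    a <- best[2]; b <- best[3]
    for (c in setdiff(active, c(a, b))) {
      CD[a, c] <- CD[c, a] <-
        (W[a] * CD[a, c] + W[b] * CD[b, c]) / (W[a] + W[b])
    }
    W[a] <- W[a] + W[b]
    members[[a]] <- c(members[[a]], members[[b]])
    active <- setdiff(active, b)
  }
  grp <- integer(u)
  for (ci in seq_along(active)) grp[members[[active[ci]]]] <- ci
  # consensus / reassignment iteration
  for (iter in 1:50) {
    cons <- .group_site_consensus(Ci, w, grp, k)
    cost <- .signature_cost(Ci, cons)
    newgrp <- vapply(seq_len(u), function(i) {
      cands <- which(cost[i, ] == min(cost[i, ]))
      if (grp[i] %in% cands) grp[i] else cands[1L]
    }, integer(1))
    if (identical(newgrp, grp)) break
    grp <- newgrp
  }
  # steepest single-signature moves on the exact objective
  curJ <- .cluster_objective(Ci, w, grp, k)
  repeat {
    best <- list(J = curJ, i = NA, c = NA)
    for (i in seq_len(u)) {
      for (c in seq_len(k)) {
        if (c == grp[i]) next
        g2 <- grp
        g2[i] <- c
        J2 <- .cluster_objective(Ci, w, g2, k)
        if (J2 < best$J - 1e-9) best <- list(J = J2, i = i, c = c)
      }
    }
    if (is.na(best$i)) break
    grp[best$i] <- best$c
    curJ <- best$J
  }
  grp
}

.window_consensus <- function(aln, members, ws, we, band) {
  width <- we - ws + 1L
  if (!length(members)) return(strrep("N", width))
  cnt <- .state_counts(aln$mat[members, ws:we, drop = FALSE],
                       aln$cover[members, ws:we, drop = FALSE])
  paste(.consensus_from_counts(cnt, band), collapse = "")
}

# ---- exported operations ---------------------------------------------------

#' Cluster the reads of one window into copy groups
#'
#' Reads covering at least one copy-distinguishing site inside the window
#' are partitioned into up to `k` clusters minimizing the total mismatch to
#' the cluster consensuses at those sites (agglomerative initialization
#' followed by swap refinement; fully deterministic). Reads covering no
#' informative site stay unassigned. Each cluster gets an IUPAC consensus
#' over all window columns from its member reads.
#'
#' @param aln A [read_alignment()].
#' @param window Window bounds: a numeric `c(start, end)` or a one-row slice
#'   of [build_windows()] output.
#' @param sites Copy-distinguishing columns (any outside the window are
#'   ignored).
#' @param k Number of clusters sought (`copy_number`).
#' @param params A [separator_params()] (consensus band).
#' @return An object of class `window_cluster`: `window`, `sites`,
#'   `assignment` (integer per read of `aln`, NA = unassigned), `consensus`
#'   (one string per cluster over the window columns), `k` (clusters
#'   found), `objective` (total within-cluster mismatch), `degenerate`
#'   (fewer distinct signatures than `k`), `informative` (at least two
#'   clusters that differ at a window site).
#' @export
cluster_window <- function(aln, window, sites, k = 2L,
                           params = separator_params()) {
  stopifnot(inherits(aln, "read_alignment"))
  if (is.data.frame(window)) {
    ws <- as.integer(window$start[1L]); we <- as.integer(window$end[1L])
  } else {
    ws <- as.integer(window[1L]); we <- as.integer(window[2L])
  }
  stopifnot(ws >= 1L, we <= aln$length, ws <= we)
  k <- as.integer(k)
  band <- params$allele_freq_band
  sites <- sort(unique(as.integer(sites[sites >= ws & sites <= we])))
  n_all <- nrow(aln$mat)
  asg <- rep(NA_integer_, n_all)

  finish <- function(asg, cons, keff, objective, degenerate) {
    site_cols <- sites - ws + 1L
    cons_sites <- if (length(site_cols)) {
      vapply(cons, function(s) {
        paste(substring(s, site_cols, site_cols), collapse = "")
      }, "")
    } else {
      rep("", length(cons))
    }
    informative <- length(sites) > 0L && keff >= 2L &&
      length(unique(cons_sites)) >= 2L
    structure(
      list(window = c(start = ws, end = we), sites = sites,
           assignment = stats::setNames(asg, aln$ids), consensus = cons,
           k = keff, objective = objective, degenerate = degenerate,
           informative = informative),
      class = "window_cluster"
    )
  }

  overl <- which(aln$spans[, 1L] <= we & aln$spans[, 2L] >= ws)
  if (!length(sites)) {
    asg[overl] <- 1L
    cons <- .window_consensus(aln, overl, ws, we, band)
    return(finish(asg, cons, 1L, 0, k > 1L))
  }

  sig <- aln$mat[, sites, drop = FALSE]
  sig[!aln$cover[, sites, drop = FALSE]] <- NA
  sig[!(sig %in% .base_states)] <- NA
  elig <- which(rowSums(!is.na(sig)) > 0)
  if (!length(elig)) {
    asg[overl] <- 1L
    cons <- .window_consensus(aln, overl, ws, we, band)
    return(finish(asg, cons, 1L, 0, k > 1L))
  }
  sig <- sig[elig, , drop = FALSE]
  sigstr <- apply(sig, 1L, function(r) {
    paste(ifelse(is.na(r), ".", r), collapse = "")
  })
  # canonical read order (by signature) makes the result invariant to the
  # input order of the reads
  ord <- order(sigstr)
  elig <- elig[ord]
  sigstr <- sigstr[ord]
  u_str <- unique(sigstr)
  u <- length(u_str)
  w <- as.integer(table(factor(sigstr, levels = u_str)))
  Ci <- matrix(match(strsplit(paste(u_str, collapse = ""), "")[[1L]],
                     .base_states),
               nrow = u, ncol = length(sites), byrow = TRUE)

  keff <- min(k, u)
  degenerate <- u < k
  if (degenerate && k > 1L) {
    warning("window [", ws, ",", we, "]: only ", u,
            " distinct haplotype signature(s) for copy_number ", k,
            call. = FALSE)
  }
  grp <- if (u <= keff) {
    seq_len(u)
  } else if (keff == 2L && u <= .exact_signature_limit) {
    .exact_bipartition(Ci, w)
  } else {
    .cluster_signatures(Ci, w, keff)
  }
  objective <- .cluster_objective(Ci, w, grp, keff)
  read_grp <- grp[match(sigstr, u_str)]
  asg[elig] <- read_grp
  cons <- vapply(seq_len(keff), function(c) {
    .window_consensus(aln, elig[read_grp == c], ws, we, band)
  }, "")
  # canonical cluster order: by consensus at the window sites, then by size
  site_cols <- sites - ws + 1L
  keyfun <- function(s) paste(substring(s, site_cols, site_cols),
                              collapse = "")
  sizes <- vapply(seq_len(keff), function(c) sum(w[grp == c]), integer(1))
  ordc <- order(vapply(cons, keyfun, ""), -sizes)
  relab <- match(seq_len(keff), ordc)
  asg[elig] <- relab[read_grp]
  cons <- cons[ordc]
  finish(asg, cons, keff, objective, degenerate)
}

# consensus character of cluster i of window_cluster wc at alignment column
.wc_char <- function(wc, i, col) {
  substring(wc$consensus[[i]], col - wc$window[["start"]] + 1L,
            col - wc$window[["start"]] + 1L)
}

# Sites where the clusters of a window actually disagree (at least two
# distinct non-N consensus symbols).
.distinct_sites <- function(wc) {
  if (wc$k < 2L || !length(wc$sites)) return(integer(0))
  keep <- vapply(wc$sites, function(s) {
    ch <- vapply(seq_len(wc$k), function(i) .wc_char(wc, i, s), "")
    ch <- ch[ch != "N"]
    length(unique(ch)) >= 2L
  }, logical(1))
  wc$sites[keep]
}

# Evaluate the junction between two informative windows a and b and choose
# the chain pairing. Returns mapping (cluster of a -> cluster of b), the
# junction status, and its evidence.
.pair_clusters <- function(a, b, aln, params) {
  ka <- a$k
  kb <- b$k
  os <- max(a$window[["start"]], b$window[["start"]])
  oe <- min(a$window[["end"]], b$window[["end"]])
  ocols <- if (os <= oe) os:oe else integer(0)

  ident <- matrix(NA_real_, ka, kb)
  for (i in seq_len(ka)) {
    for (j in seq_len(kb)) {
      if (!length(ocols)) break
      ca <- substring(a$consensus[[i]],
                      ocols - a$window[["start"]] + 1L,
                      ocols - a$window[["start"]] + 1L)
      cb <- substring(b$consensus[[j]],
                      ocols - b$window[["start"]] + 1L,
                      ocols - b$window[["start"]] + 1L)
      comp <- ca != "N" & cb != "N"
      ident[i, j] <- if (any(comp)) mean(match_iupac(ca[comp], cb[comp])) else NA_real_
    }
  }

  da <- .distinct_sites(a)
  db <- .distinct_sites(b)
  inf_overlap <- length(intersect(intersect(da, db), ocols)) > 0L

  # anchor sites for spanning-read support: the distinguishing site of a
  # nearest the junction and the first distinguishing site of b
  sL <- if (length(da)) max(da) else NA_integer_
  sR <- if (length(db)) min(db) else NA_integer_

  # candidate pairings (square case: permutations; otherwise greedy by
  # identity with sharing allowed)
  if (ka == kb) {
    perms <- .permutations(ka)
  } else {
    perms <- list(vapply(seq_len(ka), function(i) {
      which.max(ifelse(is.na(ident[i, ]), -1, ident[i, ]))
    }, integer(1)))
  }
  ident_score <- vapply(perms, function(p) {
    v <- ident[cbind(seq_len(ka), p)]
    sum(v, na.rm = TRUE) + ifelse(all(is.na(v)), NA_real_, 0)
  }, numeric(1))

  votes <- rep(0L, length(perms))
  if (!is.na(sL) && !is.na(sR) && sL != sR) {
    ok <- aln$cover[, sL] & aln$cover[, sR] &
      aln$mat[, sL] %in% .base_states & aln$mat[, sR] %in% .base_states
    if (any(ok)) {
      bl <- aln$mat[ok, sL]
      br <- aln$mat[ok, sR]
      for (pi in seq_along(perms)) {
        p <- perms[[pi]]
        hit <- rep(FALSE, sum(ok))
        for (i in seq_len(ka)) {
          hit <- hit | (match_iupac(bl, .wc_char(a, i, sL)) &
                        match_iupac(br, .wc_char(b, p[i], sR)))
        }
        votes[pi] <- sum(hit)
      }
    }
  }

  pick_by_ident <- function() {
    sc <- ifelse(is.na(ident_score), -Inf, ident_score)
    cand <- which(sc == max(sc))
    if (length(cand) > 1L) {
      cand <- cand[order(-votes[cand], cand)][1L]
    }
    cand
  }

  if (inf_overlap) {
    pi <- pick_by_ident()
    status <- "linked"
    support <- votes[pi]
  } else {
    ovote <- order(-votes)
    best <- ovote[1L]
    second <- if (length(votes) > 1L) votes[ovote[2L]] else 0L
    if (votes[best] >= params$min_link_support && votes[best] > second) {
      pi <- best
      status <- "linked"
      support <- votes[best]
    } else {
      pi <- pick_by_ident()
      status <- "ambiguous"
      support <- votes[pi]
    }
  }
  list(mapping = perms[[pi]], status = status,
       ident = ident_score[pi] / max(1L, ka), support = support,
       span = c(ifelse(is.na(sL), os, sL), ifelse(is.na(sR), oe, sR)))
}

.permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in .permutations(k - 1L)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

#' Link window clusters into copy chains
#'
#' Walks the informative windows (those whose clusters disagree at at least
#' one copy-distinguishing site) left to right and matches cluster labels
#' across each junction, first by overlap-consensus identity, then by the
#' number of reads spanning the nearest distinguishing sites on either
#' side. A junction whose overlap carries no copy-distinguishing difference
#' and whose spanning-read support falls below `min_link_support` is marked
#' `ambiguous`: the pairing is still recorded (assembly completes), but the
#' chimera report will flag it.
#'
#' @param clusters List of [cluster_window()] results, in window order.
#' @param params A [separator_params()].
#' @param aln The [read_alignment()] the clusters came from.
#' @return A list: `chain_map` (chains x windows matrix of cluster labels,
#'   NA at uninformative windows), `informative` (window indices),
#'   `n_chains`, and `junctions` (one row per junction with `status`,
#'   overlap identity and spanning support).
#' @export
link_windows <- function(clusters, params, aln) {
  empty <- data.frame(from = integer(0), to = integer(0),
                      start = integer(0), end = integer(0),
                      status = character(0), ident = numeric(0),
                      support = integer(0), stringsAsFactors = FALSE)
  inf <- which(vapply(clusters, function(x) isTRUE(x$informative),
                      logical(1)))
  if (!length(inf)) {
    return(list(chain_map = matrix(NA_integer_, 1L, length(clusters)),
                informative = inf, n_chains = 1L, junctions = empty))
  }
  n_chains <- clusters[[inf[1L]]]$k
  chain_map <- matrix(NA_integer_, n_chains, length(clusters))
  chain_map[, inf[1L]] <- seq_len(n_chains)
  junctions <- empty
  if (length(inf) >= 2L) {
    for (t in 2L:length(inf)) {
      a <- clusters[[inf[t - 1L]]]
      b <- clusters[[inf[t]]]
      pr <- .pair_clusters(a, b, aln, params)
      prev <- chain_map[, inf[t - 1L]]
      chain_map[, inf[t]] <- pr$mapping[prev]
      junctions <- rbind(junctions, data.frame(
        from = inf[t - 1L], to = inf[t],
        start = pr$span[1L], end = pr$span[2L],
        status = pr$status, ident = pr$ident,
        support = as.integer(pr$support), stringsAsFactors = FALSE))
    }
  }
  list(chain_map = chain_map, informative = inf, n_chains = n_chains,
       junctions = junctions)
}

#' Separate and assemble gene copies from a read alignment
#'
#' The full copy-separation workflow: detect variable sites, slide windows
#' of `read_length` bp advancing by `read_length - overlap`, cluster the
#' reads of each window into `copy_number` groups at the
#' copy-distinguishing sites, link the window consensuses through their
#' overlaps into full-length chains, and call an IUPAC consensus per chain
#' (allelic sites become ambiguity codes such as R, Y, M or K). Copies are
#' labeled "Copy I", "Copy II", ... arbitrarily except that the copy with
#' more gap columns (more deletions) gets the later label. Junctions
#' lacking linking evidence are flagged rather than silently joined; the
#' chimera report replaces the manual inspection of the assembly.
#'
#' @param aln A [read_alignment()].
#' @param params A [separator_params()].
#' @return An object of class `copy_assembly_set`: `sequences` (named
#'   character, alignment coordinates with gaps preserved), `degapped`,
#'   `support` (per-column read counts per copy), `sites`, `windows`,
#'   `junctions`, `verification` (spanning-read check per adjacent site
#'   pair), `verdict` (`"clean"` or `"suspect"`), `notices` and `params`.
#'   With zero copy-distinguishing sites a single consensus is returned
#'   (never `k` fabricated duplicates) with an explanatory notice.
#' @export
sep_assem <- function(aln, params = separator_params()) {
  stopifnot(inherits(aln, "read_alignment"),
            inherits(params, "separator_params"))
  set.seed(params$seed)
  notices <- character(0)
  pool_cnt <- .state_counts(aln$mat, aln$cover)
  coverage <- rowSums(pool_cnt)
  lowcov <- which(coverage < params$min_site_coverage)
  if (length(lowcov)) {
    notices <- c(notices, paste0(
      "coverage below min_site_coverage at columns ",
      .format_ranges(lowcov)))
  }
  sites_df <- detect_variable_sites(aln, params)
  copy_sites <- sites_df$column[sites_df$klass == "copy_distinguishing"]
  band <- params$allele_freq_band

  mk_result <- function(seqs, support, windows, junctions, verification,
                        verdict, notices) {
    degapped <- gsub("-", "", seqs, fixed = TRUE)
    names(degapped) <- names(seqs)
    structure(
      list(sequences = seqs, degapped = degapped, support = support,
           sites = sites_df, windows = windows, junctions = junctions,
           verification = verification, verdict = verdict,
           notices = notices, params = params),
      class = "copy_assembly_set"
    )
  }

  empty_junc <- data.frame(from = integer(0), to = integer(0),
                           start = integer(0), end = integer(0),
                           status = character(0), ident = numeric(0),
                           support = integer(0), stringsAsFactors = FALSE)

  if (length(copy_sites) == 0L) {
    notices <- c(notices, paste0(
      "copies indistinguishable: no copy-distinguishing variable sites; ",
      "returning a single consensus"))
    cons <- paste(.consensus_from_counts(pool_cnt, band), collapse = "")
    seqs <- stats::setNames(cons, "Consensus")
    supp <- stats::setNames(list(coverage), "Consensus")
    verification <- verify_assembly(seqs, aln, copy_sites, params)
    return(mk_result(seqs, supp,
                     build_windows(aln$length, params$read_length,
                                   params$overlap),
                     empty_junc, verification, "clean", notices))
  }

  wins <- build_windows(aln$length, params$read_length, params$overlap)
  clusters <- lapply(seq_len(nrow(wins)), function(i) {
    cluster_window(aln, c(wins$start[i], wins$end[i]), copy_sites,
                   params$copy_number, params)
  })
  link <- link_windows(clusters, params, aln)

  n <- nrow(aln$mat)
  L <- aln$length
  seqs <- character(link$n_chains)
  support <- vector("list", link$n_chains)
  for (c in seq_len(link$n_chains)) {
    M <- matrix(FALSE, n, L)
    for (wi in link$informative) {
      cl <- clusters[[wi]]
      q <- link$chain_map[c, wi]
      rows <- which(!is.na(cl$assignment) & cl$assignment == q)
      if (length(rows)) {
        M[rows, cl$window[["start"]]:cl$window[["end"]]] <- TRUE
      }
    }
    Mv <- M & aln$cover
    cnt <- vapply(.base_states,
                  function(b) colSums((aln$mat == b) & Mv),
                  numeric(L))
    if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = 1L)
    covc <- rowSums(cnt)
    # columns reached by no informative window fall back to the pooled
    # consensus (they are invariant between copies up to allele noise)
    fb <- covc == 0
    cnt[fb, ] <- pool_cnt[fb, , drop = FALSE]
    seqs[c] <- paste(.consensus_from_counts(cnt, band), collapse = "")
    support[[c]] <- covc
  }

  # never fabricate: identical chains collapse to one sequence
  if (anyDuplicated(seqs)) {
    keep <- !duplicated(seqs)
    notices <- c(notices, paste0(
      "chains produced ", sum(keep), " distinct sequence(s) for copy_number ",
      params$copy_number, "; identical chains collapsed"))
    seqs <- seqs[keep]
    support <- support[keep]
  }

  gapn <- nchar(seqs) - nongap_length(seqs)
  ordc <- order(gapn, seqs)
  seqs <- seqs[ordc]
  support <- support[ordc]
  labels <- if (length(seqs) == 1L && length(copy_sites) == 0L) {
    "Consensus"
  } else {
    paste("Copy", as.character(utils::as.roman(seq_along(seqs))))
  }
  names(seqs) <- labels
  names(support) <- labels

  verification <- verify_assembly(seqs, aln, copy_sites, params)
  verdict <- if ((nrow(link$junctions) &&
                  any(link$junctions$status == "ambiguous")) ||
                 (nrow(verification) &&
                  any(verification$status == "suspect"))) {
    "suspect"
  } else {
    "clean"
  }
  if (verdict == "suspect") {
    notices <- c(notices,
                 "assembly flagged suspect: see junctions/verification")
  }
  mk_result(seqs, support, wins, link$junctions, verification, verdict,
            notices)
}

#' @export
print.copy_assembly_set <- function(x, ...) {
  cat("copy_assembly_set:", length(x$sequences), "assembled sequence(s),",
      nrow(x$sites), "variable site(s) (",
      sum(x$sites$klass == "copy_distinguishing"),
      "copy-distinguishing )\n")
  for (lab in names(x$sequences)) {
    cat(sprintf("  %-8s %d bp degapped\n", lab,
                nchar(x$degapped[[lab]])))
  }
  if (nrow(x$junctions)) {
    cat("  junctions:", sum(x$junctions$status == "linked"), "linked,",
        sum(x$junctions$status == "ambiguous"), "ambiguous\n")
  }
  cat("  verdict:", x$verdict, "\n")
  for (msg in x$notices) cat("  note:", msg, "\n")
  invisible(x)
}

#' Verify an assembly for chimeric joins
#'
#' Automates the manual check that no chimeric sequence was created: for
#' every pair of adjacent copy-distinguishing sites, reads spanning both
#' are tallied as concordant (jointly matching one copy's phase) or
#' discordant (crossing phases). A pair is `clean` with at least
#' `min_link_support` concordant reads and no discordant majority;
#' otherwise `suspect`.
#'
#' @param copies Named character vector of assembled copy sequences in
#'   alignment coordinates (or a `copy_assembly_set`).
#' @param aln The [read_alignment()] used for assembly.
#' @param sites Copy-distinguishing columns.
#' @param params A [separator_params()] (for `min_link_support`).
#' @return Data frame with one row per adjacent site pair (`p`, `q`,
#'   `concordant`, `discordant`, `status`, `reason`); attribute `verdict`
#'   is `"suspect"` if any pair is.
#' @export
verify_assembly <- function(copies, aln, sites,
                            params = separator_params()) {
  if (inherits(copies, "copy_assembly_set")) copies <- copies$sequences
  stopifnot(inherits(aln, "read_alignment"))
  sites <- sort(unique(as.integer(sites)))
  out <- data.frame(p = integer(0), q = integer(0),
                    concordant = integer(0), discordant = integer(0),
                    status = character(0), reason = character(0),
                    stringsAsFactors = FALSE)
  if (length(sites) >= 2L && length(copies) >= 2L) {
    cmat <- do.call(rbind, strsplit(unname(copies), ""))
    for (idx in seq_len(length(sites) - 1L)) {
      p <- sites[idx]
      q <- sites[idx + 1L]
      ok <- aln$cover[, p] & aln$cover[, q] &
        aln$mat[, p] %in% .base_states & aln$mat[, q] %in% .base_states
      bp <- aln$mat[ok, p]
      bq <- aln$mat[ok, q]
      nc <- length(copies)
      mp <- vapply(seq_len(nc), function(i) match_iupac(bp, cmat[i, p]),
                   logical(length(bp)))
      mq <- vapply(seq_len(nc), function(i) match_iupac(bq, cmat[i, q]),
                   logical(length(bq)))
      if (is.null(dim(mp))) mp <- matrix(mp, ncol = nc)
      if (is.null(dim(mq))) mq <- matrix(mq, ncol = nc)
      full <- mp & mq
      conc <- rowSums(full) > 0
      disc <- !conc & rowSums(mp) > 0 & rowSums(mq) > 0
      n_conc <- sum(conc)
      n_disc <- sum(disc)
      status <- "clean"
      reason <- ""
      if (n_conc < params$min_link_support) {
        status <- "suspect"
        reason <- "insufficient concordant spanning reads"
      } else if (n_disc >= n_conc) {
        status <- "suspect"
        reason <- "discordant spanning reads dominate"
      }
      out <- rbind(out, data.frame(
        p = p, q = q, concordant = n_conc, discordant = n_disc,
        status = status, reason = reason, stringsAsFactors = FALSE))
    }
  }
  attr(out, "verdict") <- if (nrow(out) && any(out$status == "suspect")) {
    "suspect"
  } else {
    "clean"
  }
  out
}

#' Write an assembly to FASTA files and a JSON report
#'
#' @param x A `copy_assembly_set` from [sep_assem()].
#' @param prefix Output path prefix: writes `<prefix>_copy<i>.fasta`
#'   (alignment coordinates), `<prefix>_copy<i>_degapped.fasta` and
#'   `<prefix>_report.json`.
#' @return Character vector of the files written, invisibly.
#' @export
write_assembly <- function(x, prefix) {
  stopifnot(inherits(x, "copy_assembly_set"))
  files <- character(0)
  for (i in seq_along(x$sequences)) {
    lab <- gsub(" ", "_", names(x$sequences)[i])
    f1 <- paste0(prefix, "_copy", i, ".fasta")
    write_fasta(stats::setNames(x$sequences[i], lab), f1)
    f2 <- paste0(prefix, "_copy", i, "_degapped.fasta")
    write_fasta(stats::setNames(x$degapped[i], lab), f2)
    files <- c(files, f1, f2)
  }
  report <- list(
    version = as.character(utils::packageVersion("homeophase")),
    parameters = unclass(x$params),
    copies = names(x$sequences),
    verdict = x$verdict,
    notices = x$notices,
    junctions = x$junctions,
    verification = x$verification,
    n_variable_sites = nrow(x$sites),
    n_copy_distinguishing = sum(x$sites$klass == "copy_distinguishing")
  )
  fr <- paste0(prefix, "_report.json")
  jsonlite::write_json(report, fr, auto_unbox = TRUE, pretty = TRUE,
                       digits = 8, null = "null", na = "null")
  invisible(c(files, fr))
}

# "628-634"-style 1-based inclusive range formatting (en dash, as the
# coordinate convention used in reports)
.format_ranges <- function(positions) {
  if (!length(positions)) return(character(0))
  positions <- sort(unique(as.integer(positions)))
  brk <- c(0L, which(diff(positions) != 1L), length(positions))
  parts <- vapply(seq_len(length(brk) - 1L), function(i) {
    seg <- positions[(brk[i] + 1L):brk[i + 1L]]
    if (length(seg) == 1L) {
      as.character(seg)
    } else {
      paste0(seg[1L], "–", seg[length(seg)])
    }
  }, "")
  paste(parts, collapse = "; ")
}
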