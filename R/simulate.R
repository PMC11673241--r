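# Synthetic allotetraploid amplicon data with ground truth.
#
# A single-copy nuclear gene in an allotetraploid has two homoeologous
# copies, each with up to two near-identical alleles (four haplotypes).
# The generator draws an ancestral sequence, diverges the copies and then
# the alleles under a uniform (Jukes-Cantor-style) substitution model,
# optionally plants deletions and premature stop codons in the "decayed"
# copy, and emits reads or Sanger clones from the four haplotypes. All
# randomness flows from one integer seed, with stage sub-seeds derived
# deterministically.

#' Simulation parameters for a tetraploid locus
#'
#' Defaults describe a RAG1-like amplicon: 1500 bp, two homoeologs at 2%
#' divergence, alleles at 0.2%, 300 bp reads at 100x mean coverage with a
#' 0.2% per-base error rate.
#'
#' @param length Locus length in bp (alignment columns before indels).
#' @param copy_number Number of homoeologous copies (k).
#' @param copy_divergence Expected substitutions/site between homoeologs.
#' @param allele_divergence Expected substitutions/site between the two
#'   alleles of one copy.
#' @param read_length Read length in bp.
#' @param coverage Mean reads covering a column.
#' @param error_rate Per-base substitution error rate per read.
#' @param chimera_rate Probability that a simulated clone is a
#'   single-crossover PCR recombinant.
#' @param n_clones Number of Sanger clones to draw.
#' @param indels List of `c(start, end)` column ranges deleted from the
#'   decayed (last) copy.
#' @param stops Integer vector of alignment columns at which a TAA stop
#'   codon is planted (first base) in the decayed copy.
#' @param orf Logical; keep every haplotype free of stop-codon triplets in
#'   every reading frame except the planted ones (emulates purifying
#'   selection on the conserved copy and makes planted lesions the only
#'   frame defects).
#' @param engineered_gap Optional `c(start, width)`: clears all variation
#'   inside `(start, start+width)` and plants copy-distinguishing sites at
#'   both ends, producing an exactly `width`-bp invariant gap between
#'   neighboring copy-distinguishing sites.
#' @param skew Optional per-haplotype relative abundances (recycled to 2k),
#'   for unequal PCR amplification of copies.
#' @param boundary_frac Fraction of reads anchored at an amplicon boundary.
#'   Shearing a PCR amplicon leaves every molecule's terminal fragments
#'   ending exactly at the primer-defined ends, so mapped alignments cover
#'   the terminal columns; without this the extreme columns of a simulated
#'   alignment would be read-free, which real amplicon data are not.
#' @param seed Integer master seed.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(length = 1500L, copy_number = 2L,
                       copy_divergence = 0.02, allele_divergence = 0.002,
                       read_length = 300L, coverage = 100,
                       error_rate = 0.002, chimera_rate = 0,
                       n_clones = 20L, indels = NULL, stops = NULL,
                       orf = FALSE, engineered_gap = NULL, skew = NULL,
                       boundary_frac = 0.1, seed = 1L) {
  stopifnot(length >= 3L, copy_number >= 1L,
            copy_divergence >= 0, copy_divergence <= 1,
            allele_divergence >= 0, allele_divergence <= 1,
            read_length >= 2L, coverage > 0, error_rate >= 0,
            chimera_rate >= 0, chimera_rate <= 1)
  structure(
    list(length = as.integer(length), copy_number = as.integer(copy_number),
         copy_divergence = copy_divergence,
         allele_divergence = allele_divergence,
         read_length = as.integer(read_length), coverage = coverage,
         error_rate = error_rate, chimera_rate = chimera_rate,
         n_clones = as.integer(n_clones), indels = indels, stops = stops,
         orf = isTRUE(orf), engineered_gap = engineered_gap, skew = skew,
         boundary_frac = boundary_frac, seed = as.integer(seed)),
    class = "sim_params")
}

.nucs <- c("A", "C", "G", "T")

# does s (character vector) contain a stop triplet anywhere in any frame
# overlapping positions lo..hi?
.has_stop_near <- function(s, lo, hi) {
  lo <- max(1L, lo - 2L)
  hi <- min(length(s), hi + 2L)
  if (hi - lo < 2L) return(FALSE)
  seg <- paste(s[lo:hi], collapse = "")
  grepl("TAA|TAG|TGA", seg)
}

# mutate each position independently with probability rate; under orf,
# substitutions that would create a stop triplet in any frame try the
# remaining bases and give up (skip) if none works
.mutate_seq <- function(s, rate, orf) {
  if (rate <= 0) return(s)
  pos <- which(stats::runif(length(s)) < rate)
  for (p in pos) {
    cands <- sample(setdiff(.nucs, s[p]))
    for (b in cands) {
      old <- s[p]
      s[p] <- b
      if (!orf || !.has_stop_near(s, p, p)) break
      s[p] <- old
    }
  }
  s
}

#' Simulate a tetraploid locus with ground truth
#'
#' Draws an ancestor uniformly over A/C/G/T (or stop-free in every frame
#' when `orf = TRUE`), derives each copy by independent substitutions at
#' rate `copy_divergence / 2`, each allele at `allele_divergence / 2`, and
#' applies the planted features of `params` to the decayed (last) copy.
#'
#' @param params A [sim_params()].
#' @return Object of class `sim_truth`: `haplotypes` (named character
#'   vector, `Copy_I_a` ... in alignment coordinates), `copies` (named
#'   merged consensus per copy, alleles IUPAC-merged), `diff_positions`
#'   (columns where the copies are cleanly distinguishable, i.e. their
#'   IUPAC base sets are disjoint), `ancestor`, `planted`, `params`.
#' @export
simulate_locus <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  L <- params$length
  k <- params$copy_number
  # ancestor
  if (params$orf) {
    # no TA or TG dinucleotide anywhere => no TAA/TAG/TGA in any frame
    anc <- character(L)
    anc[1L] <- sample(.nucs, 1L)
    for (i in 2:L) {
      anc[i] <- if (anc[i - 1L] == "T") sample(c("C", "T"), 1L)
                else sample(.nucs, 1L)
    }
  } else {
    anc <- sample(.nucs, L, replace = TRUE)
  }

  copies <- lapply(seq_len(k), function(ci) {
    .mutate_seq(anc, params$copy_divergence / 2, params$orf)
  })
  haps <- list()
  for (ci in seq_len(k)) {
    for (al in c("a", "b")) {
      haps[[paste0("Copy_", as.character(utils::as.roman(ci)), "_", al)]] <-
        .mutate_seq(copies[[ci]], params$allele_divergence / 2, params$orf)
    }
  }

  roman_last <- as.character(utils::as.roman(k))
  decayed <- paste0("Copy_", roman_last, "_", c("a", "b"))

  if (!is.null(params$engineered_gap)) {
    gs <- as.integer(params$engineered_gap[1L])
    gw <- as.integer(params$engineered_gap[2L])
    ge <- gs + gw
    stopifnot(gs >= 1L, ge <= L)
    for (h in names(haps)) haps[[h]][gs:ge] <- anc[gs:ge]
    for (p in c(gs, ge)) {
      placed <- FALSE
      for (b in setdiff(.nucs, anc[p])) {
        old <- haps[[decayed[1L]]][p]
        ok <- TRUE
        for (h in decayed) {
          haps[[h]][p] <- b
          if (params$orf && .has_stop_near(haps[[h]], p, p)) ok <- FALSE
        }
        if (ok) {
          placed <- TRUE
          break
        }
        for (h in decayed) haps[[h]][p] <- old
      }
      if (!placed) {
        stop("could not place engineered copy-distinguishing site at ", p)
      }
    }
  }

  planted_stops <- integer(0)
  if (!is.null(params$stops)) {
    for (p in as.integer(params$stops)) {
      stopifnot(p >= 1L, p + 2L <= L)
      if (!is.null(params$indels)) {
        for (rng in params$indels) {
          if (p <= rng[2L] && p + 2L >= rng[1L]) {
            stop("planted stop at ", p, " overlaps deleted range ",
                 rng[1L], "-", rng[2L])
          }
        }
      }
      for (h in decayed) haps[[h]][p:(p + 2L)] <- c("T", "A", "A")
      planted_stops <- c(planted_stops, p)
    }
  }
  if (!is.null(params$indels)) {
    for (rng in params$indels) {
      stopifnot(rng[1L] >= 1L, rng[2L] <= L, rng[1L] <= rng[2L])
      for (h in decayed) haps[[h]][rng[1L]:rng[2L]] <- "-"
    }
  }
  if (params$orf) {
    # a deletion shifts the downstream reading frame; remove any stop the
    # shift (or the junction) produced, keeping planted stops untouched
    for (h in names(haps)) {
      repeat {
        found <- find_unexpected_stops(paste(haps[[h]], collapse = ""), 0L)
        extra <- setdiff(found, planted_stops)
        if (!length(extra)) break
        haps[[h]][extra[1L]] <- "C"
      }
    }
  }

  hap_chr <- vapply(haps, paste, "", collapse = "")
  copy_labels <- paste("Copy", as.character(utils::as.roman(seq_len(k))))
  copy_cons <- vapply(seq_len(k), function(ci) {
    a <- haps[[2L * ci - 1L]]
    b <- haps[[2L * ci]]
    merged <- ifelse(a == b, a, NA)
    nas <- which(is.na(merged))
    for (j in nas) {
      merged[j] <- if (a[j] %in% .nucs && b[j] %in% .nucs) {
        iupac_merge(c(a[j], b[j]))
      } else if (a[j] == "-") b[j] else a[j]
    }
    paste(merged, collapse = "")
  }, "")
  names(copy_cons) <- copy_labels

  diff_positions <- integer(0)
  if (k >= 2L) {
    cm <- do.call(rbind, strsplit(unname(copy_cons), ""))
    bits <- matrix(.iupac_bits[cm], nrow(cm), ncol(cm))
    bits[is.na(bits)] <- 0L
    # cleanly distinguishable: no pair of copies shares a base at the column
    disjoint <- rep(TRUE, ncol(cm))
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        disjoint <- disjoint & bitwAnd(bits[i, ], bits[j, ]) == 0L
      }
    }
    diff_positions <- which(disjoint)
  }

  structure(
    list(haplotypes = hap_chr, copies = copy_cons,
         diff_positions = diff_positions,
         ancestor = paste(anc, collapse = ""),
         planted = list(indels = params$indels, stops = planted_stops,
                        engineered_gap = params$engineered_gap),
         params = params),
    class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth:", length(x$haplotypes), "haplotypes,",
      x$params$length, "bp,", length(x$diff_positions),
      "copy-distinguishing columns\n")
  invisible(x)
}

#' Simulate aligned amplicon reads from a locus
#'
#' Reads of `read_length` bp are drawn from the haplotypes (equal weights
#' unless `skew` is set), placed uniformly along each haplotype, hit by
#' independent substitution errors at `error_rate`, and padded with gaps
#' into alignment coordinates — the shape of a mapped-and-exported read
#' alignment.
#'
#' @param truth A [simulate_locus()] result.
#' @param params The [sim_params()] to draw reads under (defaults to the
#'   truth's own).
#' @return A [read_alignment()] with attribute `provenance`: a data frame
#'   of `id`, `haplotype`, `start` (alignment column).
#' @export
simulate_reads <- function(truth, params = truth$params) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(params$seed + 1000003L)
  L <- params$length
  rl <- params$read_length
  haps <- truth$haplotypes
  nh <- length(haps)
  n_total <- max(nh, round(params$coverage * L / rl))
  wts <- if (is.null(params$skew)) rep(1, nh) else rep_len(params$skew, nh)
  n_per <- floor(n_total * wts / sum(wts))
  for (i in seq_len(n_total - sum(n_per))) {
    n_per[(i - 1L) %% nh + 1L] <- n_per[(i - 1L) %% nh + 1L] + 1L
  }
  seqs <- character(0)
  prov <- list()
  ridx <- 0L
  for (h in seq_len(nh)) {
    hchr <- strsplit(haps[[h]], "")[[1L]]
    cols <- which(hchr != "-")
    hlen <- length(cols)
    take <- min(rl, hlen)
    n_h <- n_per[h]
    # boundary-anchored reads (terminal fragments of the sheared amplicon),
    # split between the two ends; the rest start uniformly
    n_anchor <- round(ifelse(is.null(params$boundary_frac), 0,
                             params$boundary_frac) * n_h)
    starts <- c(rep(1L, ceiling(n_anchor / 2)),
                rep(max(1L, hlen - take + 1L), floor(n_anchor / 2)),
                sample.int(max(1L, hlen - take + 1L), n_h - n_anchor,
                           replace = TRUE))
    for (s in starts) {
      ridx <- ridx + 1L
      idx <- cols[s:(s + take - 1L)]
      bases <- hchr[idx]
      err <- which(stats::runif(take) < params$error_rate)
      for (e in err) {
        bases[e] <- sample(setdiff(.nucs, bases[e]), 1L)
      }
      read <- rep("-", L)
      read[idx] <- bases
      seqs <- c(seqs, paste(read, collapse = ""))
      prov[[ridx]] <- data.frame(id = sprintf("r%05d", ridx),
                                 haplotype = names(haps)[h],
                                 start = idx[1L],
                                 stringsAsFactors = FALSE)
    }
  }
  names(seqs) <- vapply(prov, function(p) p$id, "")
  aln <- read_alignment(seqs)
  attr(aln, "provenance") <- do.call(rbind, prov)
  aln
}

#' Simulate a Sanger clone set from a locus
#'
#' Non-chimeric clones are spread as evenly as possible across the 2k
#' haplotypes (each clone is one sequenced molecule). With probability
#' `chimera_rate` a clone is instead a single-crossover recombinant of two
#' distinct haplotypes, with the crossover placed uniformly between their
#' differing sites (so the product differs from both parents).
#'
#' @param truth A [simulate_locus()] result.
#' @param n_clones Number of clones.
#' @param chimera_rate Per-clone chimera probability.
#' @param seed Integer seed.
#' @return Named character vector of clone sequences with attribute
#'   `truth`: a data frame of `id`, `source` (haplotype name or
#'   `"chimera"`), `parent1`, `parent2`, `junction_start`, `junction_end`.
#' @export
simulate_clones <- function(truth, n_clones = 20L, chimera_rate = 0,
                            seed = truth$params$seed) {
  stopifnot(inherits(truth, "sim_truth"), n_clones >= 2L)
  set.seed(seed + 2000003L)
  haps <- lapply(truth$haplotypes, function(x) strsplit(x, "")[[1L]])
  nh <- length(haps)
  is_chim <- stats::runif(n_clones) < chimera_rate
  hap_cycle <- rep_len(seq_len(nh), sum(!is_chim))
  out <- character(n_clones)
  info <- data.frame(id = sprintf("clone%02d", seq_len(n_clones)),
                     source = NA_character_, parent1 = NA_character_,
                     parent2 = NA_character_,
                     junction_start = NA_integer_,
                     junction_end = NA_integer_,
                     stringsAsFactors = FALSE)
  ri <- 0L
  for (i in seq_len(n_clones)) {
    if (!is_chim[i]) {
      ri <- ri + 1L
      h <- hap_cycle[ri]
      out[i] <- paste(haps[[h]], collapse = "")
      info$source[i] <- names(haps)[h]
    } else {
      repeat {
        pq <- sample.int(nh, 2L)
        a <- haps[[pq[1L]]]
        b <- haps[[pq[2L]]]
        dcols <- which(!match_iupac(a, b))
        if (length(dcols) >= 2L) break
      }
      cut <- if (length(dcols) == 2L) 1L else sample.int(length(dcols) - 1L, 1L)
      cc <- dcols[cut]
      clone <- c(a[seq_len(cc)], b[(cc + 1L):length(b)])
      out[i] <- paste(clone, collapse = "")
      info$source[i] <- "chimera"
      info$parent1[i] <- names(haps)[pq[1L]]
      info$parent2[i] <- names(haps)[pq[2L]]
      info$junction_start[i] <- dcols[cut]
      info$junction_end[i] <- dcols[cut + 1L]
    }
  }
  names(out) <- info$id
  attr(out, "truth") <- info
  out
}

#' Score recovery of assembled copies against simulated truth
#'
#' Assembled sequences are assigned to truth copies by the permutation
#' maximizing total IUPAC-aware identity. The switch count of an assembled
#' copy is the number of adjacent truth-distinguishing columns at which its
#' best-matching truth label changes — 0 means non-chimeric.
#'
#' @param assembled Named character vector of assembled sequences in
#'   alignment coordinates (or a `copy_assembly_set`).
#' @param truth A [simulate_locus()] result.
#' @return List: `assignment` (assembled label -> truth label), `identity`
#'   (percent per assembled copy), `mean_identity`, `switches` (per
#'   assembled copy), `n_diff_positions`.
#' @export
evaluate_recovery <- function(assembled, truth) {
  if (inherits(assembled, "copy_assembly_set")) {
    assembled <- assembled$sequences
  }
  stopifnot(inherits(truth, "sim_truth"))
  tc <- truth$copies
  if (any(nchar(assembled) != nchar(tc[1L]))) {
    stop("assembled and truth sequences have different lengths")
  }
  am <- lapply(assembled, function(s) strsplit(s, "")[[1L]])
  tm <- lapply(tc, function(s) strsplit(s, "")[[1L]])
  ident <- function(a, t) 100 * mean(match_iupac(a, t))
  ka <- length(am)
  kt <- length(tm)
  # best injective assignment assembled -> truth
  cands <- if (ka <= kt) {
    lapply(.permutations(kt), function(p) p[seq_len(ka)])
  } else {
    stop("more assembled sequences than truth copies")
  }
  cands <- unique(cands)
  scores <- vapply(cands, function(p) {
    sum(vapply(seq_len(ka), function(i) ident(am[[i]], tm[[p[i]]]),
               numeric(1)))
  }, numeric(1))
  best <- cands[[which.max(scores)]]
  identity <- vapply(seq_len(ka), function(i) ident(am[[i]], tm[[best[i]]]),
                     numeric(1))
  names(identity) <- names(assembled)
  dp <- truth$diff_positions
  switches <- vapply(seq_len(ka), function(i) {
    a <- am[[i]]
    lab <- vapply(dp, function(col) {
      hits <- vapply(seq_len(kt), function(t) {
        match_iupac(a[col], tm[[t]][col])
      }, logical(1))
      if (sum(hits) == 1L) which(hits) else NA_integer_
    }, integer(1))
    lab <- lab[!is.na(lab)]
    if (length(lab) < 2L) 0L else sum(diff(lab) != 0L)
  }, integer(1))
  names(switches) <- names(assembled)
  list(assignment = stats::setNames(names(tc)[best], names(assembled)),
       identity = identity, mean_identity = mean(identity),
       switches = switches, n_diff_positions = length(dp))
}
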