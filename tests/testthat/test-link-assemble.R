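# Small deterministic loci for junction behavior: two copies, hand-placed
# distinguishing sites, error-free reads at every start position.
tile_reads <- function(haps, L, rl) {
  seqs <- character(0)
  for (h in haps) {
    for (s in seq_len(L - rl + 1L)) {
      r <- rep("-", L)
      r[s:(s + rl - 1L)] <- strsplit(h, "")[[1L]][s:(s + rl - 1L)]
      seqs <- c(seqs, paste(r, collapse = ""))
    }
  }
  mk_aln(seqs)
}

test_that("a distinguishing site inside the overlap links the junction", {
  base <- strrep("ACGT", 15)                 # 60 bp
  h1 <- base
  h2 <- base
  for (p in c(10, 30, 50)) {                 # distinguishing sites
    substr(h2, p, p) <- setdiff(NUCS, substr(base, p, p))[1]
  }
  aln <- tile_reads(c(h1, h1, h2, h2), 60, 40)
  res <- sep_assem(aln, separator_params(read_length = 40, overlap = 30,
                                         min_site_coverage = 2))
  expect_true(all(res$junctions$status == "linked"))
  expect_setequal(unname(res$sequences), c(h1, h2))
  expect_identical(res$verdict, "clean")
})

test_that("a gap wider than the read span leaves the junction ambiguous", {
  set.seed(33)
  L <- 200
  base <- random_seq(L)
  h1 <- base
  h2 <- base
  # two distinguishing sites 120 bp apart, reads of 60 bp cannot span
  substr(h2, 40, 40) <- setdiff(NUCS, substr(base, 40, 40))[1]
  substr(h2, 160, 160) <- setdiff(NUCS, substr(base, 160, 160))[1]
  aln <- tile_reads(c(h1, h1, h2, h2), L, 60)
  res <- suppressWarnings(
    sep_assem(aln, separator_params(read_length = 60, overlap = 45,
                                    min_site_coverage = 2)))
  expect_true(any(res$junctions$status == "ambiguous"))
  expect_identical(res$verdict, "suspect")
})

test_that("identical reads give a single consensus, never fabricated copies", {
  aln <- mk_aln(rep(strrep("ACGT", 20), 30))
  res <- sep_assem(aln, separator_params(read_length = 40, overlap = 30,
                                         min_site_coverage = 2))
  expect_identical(length(res$sequences), 1L)
  expect_identical(unname(res$sequences), strrep("ACGT", 20))
  expect_true(any(grepl("indistinguishable", res$notices)))
})

test_that("error-free simulated loci are recovered exactly", {
  p <- sim_params(length = 600, coverage = 60, error_rate = 0,
                  read_length = 200, seed = 5)
  truth <- simulate_locus(p)
  reads <- simulate_reads(truth, p)
  res <- sep_assem(reads, separator_params(read_length = 200, overlap = 150,
                                           seed = 5))
  expect_identical(sort(unname(res$sequences)),
                   sort(unname(truth$copies)))
  ev <- evaluate_recovery(res, truth)
  expect_equal(unname(ev$identity), c(100, 100))
  expect_identical(unname(ev$switches), c(0L, 0L))
})

test_that("outputs are deterministic and stable under read reordering", {
  p <- sim_params(length = 500, coverage = 50, read_length = 150, seed = 8)
  truth <- simulate_locus(p)
  reads <- simulate_reads(truth, p)
  sp <- separator_params(read_length = 150, overlap = 110, seed = 8)
  r1 <- sep_assem(reads, sp)
  r2 <- sep_assem(reads, sp)
  expect_identical(r1$sequences, r2$sequences)
  expect_identical(r1$junctions, r2$junctions)
  # shuffle read order: the set of output sequences must not change
  set.seed(99)
  shuf <- as.character(reads)[sample(nrow(reads$mat))]
  r3 <- sep_assem(read_alignment(shuf), sp)
  expect_setequal(unname(r3$sequences), unname(r1$sequences))
})

test_that("more read error never reduces ambiguous junctions (trend)", {
  amb <- function(err, seed) {
    p <- sim_params(length = 500, coverage = 40, read_length = 120,
                    error_rate = err, seed = seed)
    truth <- simulate_locus(p)
    reads <- simulate_reads(truth, p)
    res <- suppressWarnings(
      sep_assem(reads, separator_params(read_length = 120, overlap = 90,
                                        seed = seed)))
    sum(res$junctions$status == "ambiguous")
  }
  lo <- vapply(1:8, function(s) amb(0.002, s), numeric(1))
  hi <- vapply(1:8, function(s) amb(0.08, s), numeric(1))
  expect_gte(mean(hi), mean(lo))
})
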