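test_that("zero divergence collapses all haplotypes to the ancestor", {
  truth <- simulate_locus(sim_params(length = 300, copy_divergence = 0,
                                     allele_divergence = 0, seed = 2))
  expect_identical(length(unique(truth$haplotypes)), 1L)
  expect_identical(unname(truth$haplotypes[1]), truth$ancestor)
  expect_identical(truth$diff_positions, integer(0))
})

test_that("inter-copy difference counts match the substitution model", {
  n <- vapply(1:60, function(s) {
    length(simulate_locus(sim_params(seed = s))$diff_positions)
  }, integer(1))
  # ~Poisson(30): the mean over seeds must sit well inside the 99% band
  expect_gt(mean(n), 30 - 3 * sqrt(30 / 60))
  expect_lt(mean(n), 30 + 3 * sqrt(30 / 60))
  # diff_positions are recomputable from the copies (consistency)
  truth <- simulate_locus(sim_params(seed = 4))
  cm <- strsplit(unname(truth$copies), "")
  manual <- which(!match_iupac(cm[[1]], cm[[2]]))
  expect_identical(truth$diff_positions, manual)
})

test_that("planted indels and stops round-trip through frame QC", {
  p <- sim_params(seed = 6, orf = TRUE, allele_divergence = 0,
                  indels = list(c(628, 634)), stops = 574L)
  truth <- simulate_locus(p)
  decayed <- truth$haplotypes[["Copy_II_a"]]
  ref <- truth$haplotypes[["Copy_I_a"]]
  ind <- find_indels(decayed, ref)
  expect_identical(ind$label, "628–634")
  expect_identical(find_unexpected_stops(decayed, 0), 574L)
  # contradictory plant: stop inside a deleted range
  expect_error(simulate_locus(sim_params(seed = 6, indels = list(c(100, 120)),
                                         stops = 110L)),
               "overlaps deleted range")
})

test_that("read simulation is deterministic with expected depth and provenance", {
  p <- sim_params(length = 600, coverage = 50, read_length = 150, seed = 12)
  truth <- simulate_locus(p)
  r1 <- simulate_reads(truth, p)
  r2 <- simulate_reads(truth, p)
  expect_identical(as.character(r1), as.character(r2))
  expect_equal(nrow(r1$mat), round(50 * 600 / 150))
  # error-free reads substring-match their source haplotype
  p0 <- sim_params(length = 600, coverage = 20, read_length = 150,
                   error_rate = 0, seed = 12)
  r0 <- simulate_reads(truth, p0)
  prov <- attr(r0, "provenance")
  for (i in seq_len(nrow(r0$mat))) {
    hap <- strsplit(truth$haplotypes[[prov$haplotype[i]]], "")[[1]]
    sp <- r0$spans[i, ]
    expect_identical(r0$mat[i, sp[1]:sp[2]], hap[sp[1]:sp[2]])
  }
})

test_that("clone simulation honors the chimera rate", {
  truth <- simulate_locus(sim_params(length = 500, seed = 14,
                                     allele_divergence = 0.01))
  none <- simulate_clones(truth, n_clones = 12, chimera_rate = 0, seed = 14)
  expect_true(all(unname(none) %in% unname(truth$haplotypes)))
  all_ch <- simulate_clones(truth, n_clones = 12, chimera_rate = 1, seed = 14)
  info <- attr(all_ch, "truth")
  expect_true(all(info$source == "chimera"))
  # every chimera differs from both of its parents
  for (i in seq_len(nrow(info))) {
    expect_false(all_ch[[i]] == truth$haplotypes[[info$parent1[i]]])
    expect_false(all_ch[[i]] == truth$haplotypes[[info$parent2[i]]])
  }
  expect_identical(length(simulate_clones(truth, 26, 0, 1)), 26L)
})

test_that("evaluate_recovery has the right fixed point and flags chimeras", {
  truth <- simulate_locus(sim_params(length = 500, seed = 16))
  ev <- evaluate_recovery(truth$copies, truth)
  expect_equal(unname(ev$identity), c(100, 100))
  expect_identical(unname(ev$switches), c(0L, 0L))
  # half-and-half chimera must show a switch
  c1 <- strsplit(truth$copies[[1]], "")[[1]]
  c2 <- strsplit(truth$copies[[2]], "")[[1]]
  chim <- paste(c(c1[1:250], c2[251:500]), collapse = "")
  ev2 <- evaluate_recovery(c(x = chim, y = truth$copies[[2]]), truth)
  expect_gte(ev2$switches[["x"]], 1L)
})
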