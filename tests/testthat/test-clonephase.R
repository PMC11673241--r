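test_that("reduce_to_variable_sites finds polymorphic columns", {
  red <- reduce_to_variable_sites(c(a = "ACGT", b = "ACGA"))
  expect_identical(red$columns, 4L)
  expect_identical(unname(red$reduced[, 1]), c("T", "A"))
  expect_identical(reduce_to_variable_sites(c(a = "ACGT", b = "ACGT"))$columns,
                   integer(0))
  # oracle: brute-force column scan on random clone sets
  set.seed(23)
  for (rep in 1:10) {
    n <- sample(3:10, 1)
    L <- sample(10:60, 1)
    clones <- stats::setNames(
      vapply(seq_len(n), function(i) random_seq(L, c(NUCS, "N")), ""),
      sprintf("c%02d", seq_len(n)))
    red <- reduce_to_variable_sites(clones)
    mat <- do.call(rbind, strsplit(unname(clones), ""))
    manual <- which(vapply(seq_len(L), function(j) {
      v <- mat[, j]
      length(unique(v[v != "N"])) >= 2
    }, logical(1)))
    expect_identical(red$columns, manual)
  }
})

test_that("single-crossover recombinants are recognized, members are not", {
  clones <- c(g1a = "AAAA", g1b = "AAAA", g1c = "AAAA",
              g2a = "GGGG", g2b = "GGGG", g2c = "GGGG",
              chim = "AAGG")
  cm <- do.call(rbind, strsplit(unname(clones), ""))
  rownames(cm) <- names(clones)
  det <- detect_chimeric_clones(cm, k = 2, max_mismatch = 0)
  expect_identical(det$status[det$id == "chim"], "chimeric")
  expect_identical(det$crossover_start[det$id == "chim"], 2L)
  expect_identical(det$crossover_end[det$id == "chim"], 3L)
  expect_true(all(det$status[det$id != "chim"] == "assigned"))
})

test_that("a clone within max_mismatch of a group is assigned, not chimeric", {
  clones <- c(a1 = "AAAA", a2 = "AAAA", a3 = "AAGA",
              b1 = "GGGG", b2 = "GGGG")
  cm <- do.call(rbind, strsplit(unname(clones), ""))
  rownames(cm) <- names(clones)
  det <- detect_chimeric_clones(cm, k = 2, max_mismatch = 1)
  expect_true(all(det$status == "assigned"))
  expect_identical(det$group[det$id == "a3"], det$group[det$id == "a1"])
})

test_that("error-free clone sets phase to the exact truth haplotypes", {
  p <- sim_params(length = 800, copy_divergence = 0.02,
                  allele_divergence = 0.01, seed = 31)
  truth <- simulate_locus(p)
  clones <- simulate_clones(truth, n_clones = 16, chimera_rate = 0,
                            seed = 31)
  res <- phase_clone_set(clones, k = 2, max_mismatch = 0)
  expect_identical(length(res$copies), 2L)
  expect_identical(nrow(res$removed_chimeras), 0L)
  expect_identical(sort(unname(unlist(res$alleles))),
                   sort(unname(truth$haplotypes)))
  # copy consensuses carry IUPAC merges of the allele pairs
  expect_setequal(unname(res$copies), unname(truth$copies))
})

test_that("chimeras are removed without disturbing the phased consensuses", {
  p <- sim_params(length = 800, copy_divergence = 0.02,
                  allele_divergence = 0.01, seed = 37)
  truth <- simulate_locus(p)
  clean <- simulate_clones(truth, n_clones = 16, chimera_rate = 0, seed = 37)
  res_clean <- phase_clone_set(clean, k = 2, max_mismatch = 0)
  withmix <- simulate_clones(truth, n_clones = 20, chimera_rate = 0.15,
                             seed = 37)
  info <- attr(withmix, "truth")
  res_mix <- phase_clone_set(withmix, k = 2, max_mismatch = 0)
  expect_identical(sort(res_mix$assignments$id[
    res_mix$assignments$status == "chimeric"]),
    sort(info$id[info$source == "chimera"]))
  expect_identical(sort(unname(res_mix$copies)),
                   sort(unname(res_clean$copies)))
})

test_that("phasing is invariant to clone input order", {
  p <- sim_params(length = 600, copy_divergence = 0.02,
                  allele_divergence = 0.01, seed = 41)
  truth <- simulate_locus(p)
  clones <- simulate_clones(truth, n_clones = 18, chimera_rate = 0.1,
                            seed = 41)
  r1 <- phase_clone_set(clones, k = 2, max_mismatch = 0)
  set.seed(1)
  r2 <- phase_clone_set(clones[sample(length(clones))], k = 2,
                        max_mismatch = 0)
  expect_identical(sort(unname(r1$copies)), sort(unname(r2$copies)))
  expect_setequal(r1$assignments$id[r1$assignments$status == "chimeric"],
                  r2$assignments$id[r2$assignments$status == "chimeric"])
})

test_that("clones from a single copy yield one copy and a warning", {
  truth <- simulate_locus(sim_params(length = 400, seed = 43,
                                     allele_divergence = 0))
  one_copy <- rep(truth$haplotypes[1], 6)
  names(one_copy) <- sprintf("c%d", 1:6)
  res <- phase_clone_set(one_copy, k = 2)
  expect_identical(length(res$copies), 1L)
  expect_true(length(res$warnings) > 0)
})
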