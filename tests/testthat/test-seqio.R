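test_that("read_fasta normalizes case and RNA and preserves order", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">r1", "acgu", ">r2", "NN-RY"), f)
  x <- read_fasta(f)
  expect_identical(x, c(r1 = "ACGT", r2 = "NN-RY"))
})

test_that("read_fasta rejects missing, empty and malformed input", {
  expect_error(read_fasta(file.path(tempdir(), "nope.fa")), "not found")
  f <- withr::local_tempfile(fileext = ".fasta")
  file.create(f)
  expect_error(read_fasta(f), "empty")
  writeLines(c("ACGT", ">r1"), f)
  expect_error(read_fasta(f), "line 1")
})

test_that("write/read round-trip is lossless for random record sets", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(1:8, 1)
    seqs <- stats::setNames(
      vapply(seq_len(n), function(i) {
        random_seq(sample(1:200, 1), c(NUCS, "-", "N", "R", "Y"))
      }, ""),
      sprintf("seq%02d", seq_len(n)))
    f <- tempfile(fileext = ".fasta")
    write_fasta(seqs, f, width = sample(c(10, 60, 100), 1))
    expect_identical(read_fasta(f), seqs)
    unlink(f)
  }
})

test_that("filter_short_reads counts non-gap length and keeps order", {
  reads <- c(a = paste(rep("A", 300), collapse = ""),
             b = paste(c(rep("C", 249), rep("-", 60)), collapse = ""),
             d = paste(rep("G", 250), collapse = ""))
  expect_identical(names(filter_short_reads(reads, 250)), c("a", "d"))
  expect_identical(filter_short_reads(reads, 0), reads)
  # oracle: independent recount
  set.seed(3)
  pool <- stats::setNames(
    vapply(1:200, function(i) random_seq(50, c(NUCS, "-")), ""),
    sprintf("x%03d", 1:200))
  kept <- filter_short_reads(pool, 30)
  manual <- pool[vapply(pool, function(s) {
    sum(strsplit(s, "")[[1]] != "-") >= 30
  }, logical(1))]
  expect_identical(kept, manual)
})

test_that("dedup_reads collapses exact duplicates to the first id", {
  reads <- c(a = "ACGT", b = "ACGT", d = "ACGA")
  expect_identical(names(dedup_reads(reads)), c("a", "d"))
  expect_identical(dedup_reads(character(0)), character(0))
  set.seed(5)
  pool <- stats::setNames(sample(c("AAAA", "CCCC", "ACGT"), 50, TRUE),
                          sprintf("r%02d", 1:50))
  dd <- dedup_reads(pool)
  expect_false(any(duplicated(unname(dd))))
  expect_setequal(unname(dd), unique(unname(pool)))
  expect_identical(dedup_reads(dd), dd)   # idempotent
})

test_that("read_alignment enforces rectangularity and alphabet", {
  expect_error(read_alignment(c(a = "ACG", b = "AC")), "rectangular")
  expect_error(read_alignment(c(a = "AXG")), "invalid symbols")
  expect_error(read_alignment(c(ref = "ACG"), reference_id = "ref"),
               "reference row")
  aln <- read_alignment(c(a = "-ACG-", b = "AA--T"))
  expect_identical(aln$length, 5L)
  expect_identical(unname(aln$spans[1, ]), c(2L, 4L))
  expect_identical(unname(aln$cover[1, ]), c(FALSE, TRUE, TRUE, TRUE, FALSE))
})

test_that("trim_to_boundaries slices columns and composes", {
  set.seed(9)
  seqs <- vapply(1:6, function(i) random_seq(10, c(NUCS, "-")), "")
  aln <- mk_aln(seqs)
  tr <- trim_to_boundaries(aln, 3, 7)
  expect_identical(tr$length, 5L)
  # oracle: direct slice
  for (id in tr$ids) {
    expect_identical(unname(as.character(tr)[id]),
                     substr(seqs[match(id, aln$ids)], 3, 7))
  }
  expect_identical(as.character(trim_to_boundaries(aln, 1, 10)),
                   as.character(aln))
  # composition: [2,9] then relative [2,6] == [3,7]
  t2 <- trim_to_boundaries(trim_to_boundaries(aln, 2, 9), 2, 6)
  expect_identical(as.character(t2), as.character(tr))
  expect_error(trim_to_boundaries(aln, 7, 3), "invalid trim range")
  expect_error(trim_to_boundaries(aln, 0, 5), "invalid trim range")
})
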