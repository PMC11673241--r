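test_that("find_indels reports deletion and insertion runs", {
  ref <- strrep("A", 20)
  s <- paste0(strrep("A", 5), strrep("-", 4), strrep("A", 11))
  ind <- find_indels(s, ref)
  expect_identical(ind$start, 6L)
  expect_identical(ind$end, 9L)
  expect_identical(ind$type, "deletion")
  expect_identical(ind$label, "6–9")
  # insertion relative to the reference
  ind2 <- find_indels(strrep("A", 20),
                      paste0(strrep("A", 10), "-", strrep("A", 9)))
  expect_identical(ind2$type, "insertion")
  expect_identical(ind2$label, "11 (insertion)")
  expect_identical(nrow(find_indels(ref, ref)), 0L)
  expect_error(find_indels("AC", "ACG"), "different aligned lengths")
})

test_that("find_indels equals a brute-force run scan on random gap patterns", {
  set.seed(53)
  for (rep in 1:15) {
    L <- sample(30:120, 1)
    s <- strsplit(random_seq(L, c(NUCS, "-")), "")[[1]]
    r <- strsplit(random_seq(L, c(NUCS, "-")), "")[[1]]
    ind <- find_indels(paste(s, collapse = ""), paste(r, collapse = ""))
    # naive scan
    manual <- data.frame(start = integer(0), end = integer(0),
                         type = character(0))
    for (kind in c("deletion", "insertion")) {
      mask <- if (kind == "deletion") s == "-" & r != "-" else r == "-" & s != "-"
      i <- 1L
      while (i <= L) {
        if (mask[i]) {
          j <- i
          while (j < L && mask[j + 1L]) j <- j + 1L
          manual <- rbind(manual,
                          data.frame(start = i, end = j, type = kind))
          i <- j + 1L
        } else i <- i + 1L
      }
    }
    manual <- manual[order(manual$start), ]
    expect_equal(ind[, c("start", "end", "type")], manual,
                 ignore_attr = TRUE)
    # planted ranges round-trip through the report
    expect_true(all(ind$start <= ind$end))
  }
})

test_that("find_unexpected_stops reports premature stops at base-1 columns", {
  # open reading frame with only a terminal stop
  orf <- paste0(strrep("ATG", 5), "TAA")
  expect_identical(find_unexpected_stops(orf, 0), integer(0))
  # planted TAA at column 7 (frame 0)
  s <- paste0("ATGATG", "TAA", strrep("ATG", 4), "TGA")
  expect_identical(find_unexpected_stops(s, 0), 7L)
  # gaps are skipped and shift the frame downstream
  s2 <- paste0("ATG", "-", "TA", "AATG")   # compacted: ATG TAA ATG
  expect_identical(find_unexpected_stops(s2, 0), 5L)
  # ambiguity: TAR is always a stop, TAY never
  expect_identical(find_unexpected_stops("TARCCCGGG", 0), 1L)
  expect_identical(find_unexpected_stops("TAYCCCGGG", 0), integer(0))
})

test_that("stop scan equals the brute-force codon oracle on random input", {
  set.seed(59)
  for (rep in 1:20) {
    L <- sample(30:150, 1)
    s <- random_seq(L, c(NUCS, NUCS, "-", "R", "Y"))
    off <- sample(0:2, 1)
    expect_identical(find_unexpected_stops(s, off), oracle_stop_scan(s, off),
                     info = sprintf("rep %d offset %d", rep, off))
  }
})

test_that("site_distances matches examples, the oracle, and is symmetric", {
  L <- 300
  a <- strrep("A", L)
  b_ <- strsplit(a, "")[[1]]
  b_[c(10, 110, 260)] <- "G"
  b <- paste(b_, collapse = "")
  pr <- site_distances(a, b)
  expect_identical(pr$positions, c(10L, 110L, 260L))
  expect_identical(pr$gaps, c(100L, 150L))
  expect_identical(pr$max_gap, 150L)
  expect_identical(site_distances(a, a)$positions, integer(0))
  # IUPAC-aware: R vs A is a match; N skipped; '-' vs base is a mismatch
  expect_identical(site_distances("RAN-", "AG-A")$positions, c(2L, 4L))
  set.seed(61)
  for (rep in 1:25) {
    n <- sample(20:150, 1)
    x <- random_seq(n, c(NUCS, "N", "R", "-"))
    y <- random_seq(n, c(NUCS, "N", "Y", "-"))
    expect_identical(site_distances(x, y)$positions,
                     oracle_site_positions(x, y))
    expect_identical(site_distances(x, y)$gaps, site_distances(y, x)$gaps)
  }
})

test_that("required_read_length applies the spanning bound", {
  mk_prof <- function(positions, L = 2000) {
    a <- strrep("A", L)
    b_ <- strsplit(a, "")[[1]]
    b_[positions] <- "G"
    site_distances(a, paste(b_, collapse = ""))
  }
  expect_identical(required_read_length(mk_prof(c(50, 150)), 1.0)$required,
                   101L)
  expect_identical(required_read_length(mk_prof(c(10, 110, 260)), 0.75)$required,
                   202L)
  # a >800 bp allele-pair gap exceeds any short-read length
  big <- required_read_length(mk_prof(c(100, 901)))
  expect_gt(big$required, 800L)
  # monotone in max_gap
  reqs <- vapply(c(50, 100, 200, 400), function(g) {
    required_read_length(mk_prof(c(10, 10 + g)))$required
  }, integer(1))
  expect_true(all(diff(reqs) >= 0))
  empty <- required_read_length(mk_prof(integer(0)))
  expect_identical(empty$required, 0L)
  expect_match(empty$notice, "fewer than two")
})

test_that("plot_site_distances writes a file and a tidy table", {
  prof <- list(
    RAG1 = site_distances(strrep("A", 300), {
      b <- strsplit(strrep("A", 300), "")[[1]]
      b[c(10, 110, 260)] <- "C"
      paste(b, collapse = "")
    }),
    EGR3 = site_distances(strrep("G", 100), {
      b <- strsplit(strrep("G", 100), "")[[1]]
      b[c(5, 50, 95)] <- "T"
      paste(b, collapse = "")
    }))
  f <- tempfile(fileext = ".png")
  tab <- plot_site_distances(prof, file = f)
  expect_true(file.exists(f))
  expect_identical(nrow(tab), 4L)
  expect_identical(tab$gap[tab$group == "RAG1"], c(100L, 150L))
  expect_error(plot_site_distances(list()), "no profiles")
  unlink(f)
})
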