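test_that("EM recovers an identical planted word at every site", {
  ps <- planted_word_set(50, 60, "MKTAYIAK", seed = 15)
  m <- em_motif(ps$seqs, 8, seed = 2)
  expect_identical(m$consensus, "MKTAYIAK")
  expect_equal(nrow(m$occurrences), 50)
  expect_identical(m$occurrences$start[match(names(ps$seqs),
                                             m$occurrences$id)], ps$starts)
  expect_monotone_trace(m)
  expect_gt(m$gamma, 0.9)
})

test_that("EM keeps its probabilistic contracts on degenerate input", {
  s <- random_protein(50)
  seqs <- setNames(rep(s, 50), sprintf("d%02d", 1:50))
  m <- em_motif(seqs, 8, background = rep(1 / 20, 20), seed = 4)
  expect_equal(colSums(m$ppm), rep(1, 8), tolerance = 1e-9)
  expect_monotone_trace(m)
})

test_that("EM objective is non-decreasing on varied inputs", {
  set.seed(21)
  for (rep in 1:5) {
    seqs <- random_seq_set(15, 50)
    m <- em_motif(seqs, sample(6:12, 1), seed = rep)
    expect_monotone_trace(m)
    expect_equal(colSums(m$ppm), rep(1, m$width), tolerance = 1e-9)
  }
})

test_that("sequences shorter than the width are excluded with a warning", {
  seqs <- c(a = random_protein(30), b = random_protein(30),
            c = random_protein(5))
  expect_warning(m <- em_motif(seqs, 10, seed = 1), "excluded")
  expect_false("c" %in% m$occurrences$id)
  expect_error(suppressWarnings(em_motif(c(x = "MKT", y = "ACD"), 10)))
})

test_that("discovery is deterministic and honours the width bounds", {
  fams <- sim_three_families(61, n = 15, L = 80)
  m1 <- discover_motifs(fams[[1]], n_motifs = 2, seed = 9)
  m2 <- discover_motifs(fams[[1]], n_motifs = 2, seed = 9)
  expect_identical(m1, m2)
  expect_length(m1, 2)
  expect_identical(vapply(m1, `[[`, 0L, "rank"), 1:2)
  for (m in m1) {
    expect_gte(m$width, 6)
    expect_lte(m$width, 30)
  }
  expect_error(discover_motifs(c(a = "MKT", b = "ACD"), w_min = 6),
               "no admissible")
})

test_that("two disjoint planted words are recovered in occupancy order", {
  set.seed(33)
  n <- 40; L <- 90
  w1 <- "RQWFDEKYAH"; w2 <- "CIVPTNGSML"
  seqs <- character(n)
  for (i in seq_len(n)) {
    s <- random_protein(L)
    s <- paste0(substr(s, 1, 9), w1, substr(s, 20, 45), w2, substr(s, 56, L))
    # second word only at 60% occupancy
    if (i > 24) s <- paste0(substr(s, 1, 45), random_protein(10),
                            substr(s, 56, L))
    seqs[i] <- s
  }
  names(seqs) <- sprintf("t%02d", seq_len(n))
  ms <- discover_motifs(seqs, widths = 10, n_motifs = 2, seed = 12)
  expect_identical(ms[[1]]$consensus, w1)
  expect_identical(ms[[2]]$consensus, w2)
})

test_that("masking prevents overlap with earlier motif occurrences", {
  ps <- planted_word_set(30, 70, "MKTAYIAKQR", seed = 44)
  ms <- discover_motifs(ps$seqs, widths = 10, n_motifs = 3, seed = 3)
  occ1 <- ms[[1]]$occurrences
  for (r in 2:3) {
    occr <- ms[[r]]$occurrences
    for (q in seq_len(nrow(occr))) {
      prev <- occ1[occ1$id == occr$id[q], ]
      if (nrow(prev) == 0) next
      overlap <- pmin(prev$start + 9, occr$start[q] + 9) -
        pmax(prev$start, occr$start[q]) + 1
      expect_true(all(overlap <= 0))
    }
  }
})

test_that("scanning finds the consensus and tandem copies", {
  ps <- planted_word_set(40, 60, "MKTAYIAK", seed = 55)
  m <- em_motif(ps$seqs, 8, seed = 6)
  hit <- scan_motif(m, c(solo = m$consensus))
  expect_equal(nrow(hit), 1)
  expect_equal(hit$start, 1)
  # k copies separated by random spacers
  set.seed(66)
  k <- 4
  tandem <- paste0(random_protein(10),
                   paste(vapply(seq_len(k), function(i)
                     paste0(m$consensus, random_protein(7)), ""),
                     collapse = ""))
  hits <- scan_motif(m, c(rep5 = tandem))
  expect_equal(nrow(hits), k)
  # empty input
  expect_equal(nrow(scan_motif(m, character())), 0)
})

test_that("permutation E-values separate planted signal from noise", {
  ps <- planted_word_set(30, 60, "MKTAYIAK", seed = 77)
  m <- em_motif(ps$seqs, 8, seed = 7, n_starts = 5, n_candidates = 50)
  e <- permutation_evalue(m, ps$seqs, B = 99, seed = 8)
  expect_lte(as.numeric(e), 0.05)
  # E is monotone non-increasing in the observed llr for a fixed null sample
  null <- attr(e, "null_llr")
  e_at <- function(llr) (1 + sum(null >= llr)) / (length(null) + 1)
  grid <- sort(c(null, m$llr))
  expect_true(all(diff(vapply(grid, e_at, 0)) <= 0))
  # null calibration on pure random sequences
  set.seed(88)
  sig <- vapply(1:20, function(rep) {
    seqs <- random_seq_set(15, 50)
    mm <- em_motif(seqs, 8, n_starts = 5, n_candidates = 30)
    as.numeric(permutation_evalue(mm, seqs, B = 19)) <= 0.05
  }, TRUE)
  expect_gte(mean(!sig), 0.95)
})

test_that("MEME minimal output carries the alphabet, background and matrices", {
  ps <- planted_word_set(20, 50, "MKTAYIAK", seed = 99)
  ms <- discover_motifs(ps$seqs, widths = 8, n_motifs = 2, seed = 5)
  p <- tempfile(fileext = ".meme")
  write_meme(ms, p)
  lines <- readLines(p)
  expect_identical(lines[1], "MEME version 4")
  expect_true(any(grepl("^ALPHABET= ACDEFGHIKLMNPQRSTVWY$", lines)))
  expect_true(any(grepl("Background letter frequencies", lines)))
  expect_equal(sum(grepl("^MOTIF ", lines)), 2)
  expect_equal(sum(grepl("^letter-probability matrix", lines)), 2)
  # matrix rows parse back to unit-sum probability vectors
  i <- which(grepl("^letter-probability matrix", lines))[1]
  row1 <- as.numeric(strsplit(lines[i + 1], " +")[[1]])
  expect_length(row1, 20)
  expect_equal(sum(row1), 1, tolerance = 1e-4)
})
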