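toy_alignment <- function(rows) {
  p <- tempfile(fileext = ".fasta")
  write_fasta(rows, p)
  read_alignment(p)
}

test_that("column entropy matches its closed forms", {
  one <- rep(0, 20); one[3] <- 1
  expect_equal(column_entropy(one), 0, tolerance = 1e-12)
  expect_equal(column_entropy(rep(1 / 20, 20)), 1, tolerance = 1e-12)
  half <- rep(0, 20); half[c(1, 2)] <- 0.5
  expect_equal(column_entropy(half), log(2) / log(20), tolerance = 1e-12)
  # counts are normalized
  expect_equal(column_entropy(half * 30), log(2) / log(20), tolerance = 1e-12)
  expect_true(is.na(column_entropy(rep(0, 20))))
})

test_that("entropy is bounded, zero only when pure, and grows under spreading", {
  set.seed(6)
  x <- matrix(rexp(20 * 100000), nrow = 20)
  p <- sweep(x, 2, colSums(x), "/")
  S <- -colSums(ifelse(p > 0, p * log(p), 0)) / log(20)
  expect_true(all(S >= 0 & S <= 1 + 1e-12))
  # spot-check agreement with column_entropy
  for (j in sample(1e5, 25))
    expect_equal(column_entropy(p[, j]), S[j], tolerance = 1e-9)
  # spreading mass from one type to two equal types strictly increases S
  for (f in c(0.1, 0.25, 0.5)) {
    v <- rep(0, 20); v[1] <- 1 - f; v[2] <- f
    expect_gt(column_entropy(v), 0)
  }
  expect_gt(column_entropy(c(0.5, 0.5, rep(0, 18))),
            column_entropy(c(0.9, 0.1, rep(0, 18))))
})

test_that("profiles normalize per column and flag gaps", {
  aln <- toy_alignment(c(r1 = "---ACDEF", r2 = "KKKACDEF", r3 = "KKKACDEW"))
  pr <- conservation_profile(aln)
  expect_equal(colSums(pr$dist), rep(1, 8), tolerance = 1e-9)
  expect_equal(pr$S[4:7], rep(0, 4))
  expect_gt(pr$S[8], 0)
  expect_equal(pr$gap_fraction[1], 1 / 3)
  # identical rows -> all-zero entropy
  same <- toy_alignment(setNames(rep("MKTAYIAK", 4), paste0("r", 1:4)))
  expect_true(all(conservation_profile(same)$S == 0))
})

test_that("planted motif columns are less variable than their flanks", {
  cfg <- sim_config(n_families = 1, seqs_per_family = 40,
                    ancestor_length = 120, substitution_rate = 0.35,
                    seed = 51,
                    planted_motifs = list(
                      motif_plant("RQWFDEKYAHMLCIV", occupancy = 1,
                                  anchor = "fixed")))
  f <- simulate_families(cfg)[[1]]
  aln <- progressive_align(f)
  pr <- conservation_profile(aln)
  ref <- aln$ids[1]
  tr <- f$truth[f$truth$id == ref, ]
  motif_cols <- map_reference_span(aln, ref, tr$start, tr$end)
  flank_cols <- setdiff(seq_len(aln$n_columns), motif_cols)
  expect_lt(mean(pr$S[motif_cols], na.rm = TRUE),
            mean(pr$S[flank_cols], na.rm = TRUE))
})

test_that("reference masking keeps exactly the reference's residue columns", {
  aln <- toy_alignment(c(ref = "--AC-DE", oth = "KKAC-DW", thr = "KKACWDW"))
  mk <- mask_to_reference(aln, "ref")
  expect_equal(mk$n_columns, 4)
  expect_identical(mk$rows[["ref"]], "ACDE")
  expect_false(grepl("-", mk$rows[["ref"]], fixed = TRUE))
  expect_identical(attr(mk, "column_map"), c(3L, 4L, 6L, 7L))
  # ungapped reference: identity
  ug <- toy_alignment(c(a = "ACDEF", b = "AC-EF"))
  expect_identical(mask_to_reference(ug, "a")$rows[["a"]], "ACDEF")
  expect_equal(mask_to_reference(ug, "a")$n_columns, 5)
  expect_error(mask_to_reference(aln, "nope"), "unknown reference")
})

test_that("reference spans map to the documented columns", {
  aln <- toy_alignment(c(ref = "---ACDEFGH", oth = "KKKACDEFGH"))
  expect_identical(map_reference_span(aln, "ref", 1, 5), 4:8)
  expect_identical(map_reference_span(aln, "ref", 3, 3), 6L)
  expect_error(map_reference_span(aln, "ref", 5, 9), "outside")
  # masking then mapping reproduces the reference subsequence
  mk <- mask_to_reference(aln, "ref")
  cols <- map_reference_span(mk, "ref", 2, 4)
  expect_identical(paste(strsplit(mk$rows[["ref"]], "")[[1]][cols],
                         collapse = ""), "CDE")
})

test_that("consensus rules produce fixed letters, classes and wildcards", {
  # 10 rows: column 1 pure R; column 2 5V/5L; column 3 scattered
  rows <- sprintf("%s%s%s", "R", c(rep("V", 5), rep("L", 5)),
                  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "M"))
  aln <- toy_alignment(setNames(rows, paste0("r", 1:10)))
  pr <- conservation_profile(aln)
  cp <- consensus_pattern(pr, 1:3, t_fix = 0.7, t_class = 0.8)
  expect_identical(cp$pattern, "R[LV]X")
  expect_identical(cp$positions$rule, c("fixed", "class", "wildcard"))
  expect_error(consensus_pattern(pr, integer()), "empty")
  expect_error(consensus_pattern(pr, 1:3, t_fix = 0.3))
})

test_that("consensus patterns are invariant to row order", {
  set.seed(9)
  rows <- vapply(1:30, function(i) random_protein(12), "")
  names(rows) <- sprintf("r%02d", 1:30)
  a1 <- toy_alignment(rows)
  a2 <- toy_alignment(rev(rows))
  p1 <- consensus_pattern(conservation_profile(a1), 1:12)
  p2 <- consensus_pattern(conservation_profile(a2), 1:12)
  expect_identical(p1$pattern, p2$pattern)
})

test_that("logo matrices are the profile distributions over the span", {
  aln <- toy_alignment(c(a = "MKTAY", b = "MKTAY", c = "MKWAY"))
  pr <- conservation_profile(aln)
  lm <- logo_matrix(pr, 2:4)
  expect_equal(dim(lm), c(20, 3))
  expect_equal(colSums(lm), setNames(rep(1, 3), c("2", "3", "4")),
               tolerance = 1e-9)
  expect_equal(unname(lm["K", "2"]), 1) # fully conserved -> one-hot
  expect_equal(unname(lm["W", "3"]), 1 / 3)
  expect_identical(unname(lm), unname(pr$dist[, 2:4]))
})
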