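test_that("zero-mutation families reproduce their ancestors exactly", {
  cfg <- sim_config(n_families = 2, seqs_per_family = 10, ancestor_length = 50,
                    substitution_rate = 0, indel_rate = 0, seed = 3)
  fams <- simulate_families(cfg)
  expect_length(fams, 2)
  for (f in fams) {
    expect_length(f$ids, 10)
    expect_length(unique(f$seqs), 1) # all identical to the family ancestor
    expect_equal(unique(nchar(f$seqs)), 50)
  }
  # the two families have different ancestors
  expect_false(fams[[1]]$seqs[[1]] == fams[[2]]$seqs[[1]])
})

test_that("simulation is byte-identical for identical configs", {
  cfg <- sim_config(n_families = 2, seqs_per_family = 15, ancestor_length = 60,
                    substitution_rate = 0.3, indel_rate = 0.02, seed = 7,
                    planted_motifs = list(motif_plant("MKTAYIAKQR",
                                                      target_families = 1:2,
                                                      occupancy = 0.5)))
  f1 <- simulate_families(cfg)
  f2 <- simulate_families(cfg)
  expect_identical(f1, f2)
  p1 <- tempfile(); p2 <- tempfile()
  write_fasta(f1[[1]], p1)
  write_fasta(f2[[1]], p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("adding a family does not perturb earlier families", {
  c2 <- sim_config(n_families = 2, seqs_per_family = 8, ancestor_length = 40,
                   seed = 5)
  c3 <- sim_config(n_families = 3, seqs_per_family = 8, ancestor_length = 40,
                   seed = 5)
  expect_identical(simulate_families(c2), simulate_families(c3)[1:2])
})

test_that("occupancy is realized as an exact count", {
  cfg <- sim_config(n_families = 1, seqs_per_family = 200,
                    ancestor_length = 80, substitution_rate = 0.2, seed = 11,
                    planted_motifs = list(motif_plant("MKTAYIAKQRWDEFC",
                                                      occupancy = 0.5)))
  f <- simulate_families(cfg)[[1]]
  expect_equal(length(unique(f$truth$id)), round(0.5 * 200))
  expect_equal(nrow(f$truth), 100) # one copy each
})

test_that("emitted sequences use only the 20 canonical residues", {
  cfg <- sim_config(n_families = 2, seqs_per_family = 20, ancestor_length = 60,
                    substitution_rate = 0.4, indel_rate = 0.05, seed = 13,
                    planted_motifs = list(motif_plant("RXX[VL]XXKRY[TS]",
                                                      target_families = 1,
                                                      degradation = 0.3)))
  for (f in simulate_families(cfg)) {
    residues <- unique(strsplit(paste(f$seqs, collapse = ""), "")[[1]])
    expect_true(all(residues %in% AA))
  }
})

test_that("truth coordinates are consistent with the planted pattern", {
  pat <- "RQW[VL]DE[KR]YAHML"
  pos <- crossmotif:::parse_pattern(pat)
  for (deg in c(0, 0.3)) {
    cfg <- sim_config(n_families = 1, seqs_per_family = 40,
                      ancestor_length = 100, substitution_rate = 0.3,
                      indel_rate = 0.02, seed = 17,
                      planted_motifs = list(motif_plant(pat, occupancy = 1,
                                                        degradation = deg)))
    f <- simulate_families(cfg)[[1]]
    expect_equal(nrow(f$truth), 40)
    for (q in seq_len(nrow(f$truth))) {
      sub <- strsplit(substr(f$seqs[[f$truth$id[q]]], f$truth$start[q],
                             f$truth$end[q]), "")[[1]]
      mismatch <- sum(!mapply(function(ch, allowed) ch %in% allowed, sub, pos))
      expect_lte(mismatch, f$truth$n_degraded[q])
      if (deg == 0) expect_equal(mismatch, 0)
    }
  }
})

test_that("multiple copies per sequence get non-overlapping truth spans", {
  cfg <- sim_config(n_families = 1, seqs_per_family = 20,
                    ancestor_length = 200, substitution_rate = 0.2, seed = 19,
                    planted_motifs = list(motif_plant("MKTAYIAKQRWDEFC",
                                                      occupancy = 1,
                                                      copies_per_sequence = 3)))
  f <- simulate_families(cfg)[[1]]
  expect_equal(nrow(f$truth), 60)
  for (id in unique(f$truth$id)) {
    tr <- f$truth[f$truth$id == id, ]
    tr <- tr[order(tr$start), ]
    expect_true(all(tr$start[-1] > tr$end[-nrow(tr)]))
  }
})

test_that("truth table round-trips with the documented arithmetic", {
  fams <- sim_three_families(23, n = 100, L = 120,
                             plant = motif_plant("MKTAYIAKQRWDEFC",
                                                 target_families = 1:3,
                                                 occupancy = 1))
  p <- tempfile()
  truth <- write_truth(fams, p)
  expect_equal(nrow(truth), 300) # 3 families x 100 sequences x occupancy 1
  back <- read.delim(p)
  expect_equal(nrow(back), 300)
  expect_equal(back$end - back$start + 1, rep(15L, 300))
  # no plants -> header-only file
  p0 <- tempfile()
  write_truth(sim_three_families(23, n = 5, L = 50), p0)
  expect_equal(length(readLines(p0)), 1)
})

test_that("invalid patterns and configs are rejected", {
  expect_error(motif_plant("MKTAJIAK"), "invalid residue")
  expect_error(motif_plant("MKT[V"), "unclosed bracket")
  expect_error(motif_plant("MKTA"), regexp = ">=")
  expect_error(sim_config(substitution_rate = 1))
  expect_error(sim_config(ancestor_length = 10))
  expect_error(simulate_families(
    sim_config(planted_motifs = list(motif_plant("MKTAYIAK",
                                                 target_families = 5)))),
    "target_families")
})
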