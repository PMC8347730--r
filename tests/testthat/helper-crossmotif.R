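AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(L) paste(sample(AA, L, replace = TRUE), collapse = "")

random_seq_set <- function(n, L, prefix = "s") {
  setNames(vapply(seq_len(n), function(i) random_protein(L), ""),
           sprintf("%s%03d", prefix, seq_len(n)))
}

# three diverged families at the generator's default divergence, optionally
# with one planted motif
sim_three_families <- function(seed, n = 30, L = 120, plant = NULL) {
  cfg <- sim_config(n_families = 3, seqs_per_family = n, ancestor_length = L,
                    substitution_rate = 0.3,
                    planted_motifs = if (is.null(plant)) list() else
                      list(plant),
                    seed = seed)
  simulate_families(cfg)
}

# n random sequences, each with one copy of `word` at a recorded position
planted_word_set <- function(n, L, word, seed) {
  set.seed(seed)
  w <- nchar(word)
  starts <- integer(n)
  seqs <- character(n)
  for (i in seq_len(n)) {
    s <- random_protein(L)
    p <- sample(seq_len(L - w + 1), 1)
    seqs[i] <- paste0(substr(s, 1, p - 1), word, substr(s, p + w, L))
    starts[i] <- p
  }
  list(seqs = setNames(seqs, sprintf("p%03d", seq_len(n))), starts = starts)
}

# a motif-shaped object carrying just a consensus, for comparison tests
fake_motif <- function(consensus, rank = NA_integer_) {
  structure(list(consensus = consensus, rank = rank), class = "motif")
}

expect_monotone_trace <- function(m) {
  expect_true(all(diff(m$trace) >= -1e-8))
}
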