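#' Simulation settings for synthetic protein families
#'
#' Describes a set of protein families to simulate: each family descends from
#' its own independent random ancestor, and every member diverges from that
#' ancestor by point substitutions and short indels. Optionally, degenerate
#' motifs are planted into a configurable fraction of sequences, either within
#' one family or shared across families, so that motif-recovery pipelines can
#' be exercised with known ground truth.
#'
#' @param n_families number of independent families.
#' @param seqs_per_family sequences per family (>= 1).
#' @param ancestor_length ancestor length in residues (>= 30).
#' @param substitution_rate expected substitutions per site per sequence, in
#'   `[0, 1)`. Substituted sites receive one of the 19 alternative residues
#'   uniformly.
#' @param indel_rate expected indel events per site, in `[0, 0.2]`.
#' @param indel_length_mean mean indel length in residues; lengths are
#'   geometric with this mean, capped at 10.
#' @param planted_motifs list of [motif_plant()] specifications.
#' @param seed integer seed. Each family uses a sub-stream derived from this
#'   seed by a fixed offset, so adding a family never perturbs earlier ones.
#' @return an object of class `sim_config`.
#' @seealso [simulate_families()], [motif_plant()]
#' @export
sim_config <- function(n_families = 3, seqs_per_family = 100,
                       ancestor_length = 300, substitution_rate = 0.3,
                       indel_rate = 0.01, indel_length_mean = 2,
                       planted_motifs = list(), seed = 1L) {
  stopifnot(n_families >= 1, seqs_per_family >= 1, ancestor_length >= 30,
            substitution_rate >= 0, substitution_rate < 1,
            indel_rate >= 0, indel_rate <= 0.2,
            indel_length_mean >= 1)
  if (length(planted_motifs) && inherits(planted_motifs, "motif_plant"))
    planted_motifs <- list(planted_motifs)
  for (p in planted_motifs) stopifnot(inherits(p, "motif_plant"))
  structure(list(n_families = as.integer(n_families),
                 seqs_per_family = as.integer(seqs_per_family),
                 ancestor_length = as.integer(ancestor_length),
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 indel_length_mean = indel_length_mean,
                 planted_motifs = planted_motifs,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Specify a motif to plant into simulated families
#'
#' The pattern is a degenerate string over the 20-residue alphabet: fixed
#' letters, `X` wildcards, and bracket classes such as `[KR]`. Each planted
#' instance realizes the pattern (wildcards and classes sampled uniformly from
#' their allowed residues) and is then degraded: every position is replaced by
#' a uniform random residue with probability `degradation`.
#'
#' @param pattern degenerate pattern string; 6 to 30 positions.
#' @param target_families integer indices of the families to plant into.
#' @param occupancy fraction of sequences per target family that carry the
#'   motif; realized as the exact count `round(occupancy * n)` (not Bernoulli)
#'   so that downstream recovery checks are deterministic.
#' @param copies_per_sequence number of copies inserted per carrier sequence.
#' @param degradation per-position probability of replacing the realized motif
#'   residue with a uniform random residue, in `[0, 1)`.
#' @param anchor `"random"` (default) inserts every copy at a uniform random
#'   interior position of its sequence; `"fixed"` draws one ancestor position
#'   per family and inserts the first copy of every carrier there (mapped
#'   through that sequence's indels), emulating a positionally conserved
#'   motif that a multiple alignment can stack into common columns. Extra
#'   copies beyond the first always use random positions.
#' @return an object of class `motif_plant`.
#' @export
motif_plant <- function(pattern, target_families = 1L, occupancy = 1,
                        copies_per_sequence = 1L, degradation = 0,
                        anchor = c("random", "fixed")) {
  pos <- parse_pattern(pattern)
  anchor <- match.arg(anchor)
  stopifnot(length(pos) >= 6, length(pos) <= 30,
            occupancy >= 0, occupancy <= 1,
            copies_per_sequence >= 1,
            degradation >= 0, degradation < 1)
  structure(list(pattern = pattern, positions = pos,
                 target_families = as.integer(target_families),
                 occupancy = occupancy,
                 copies_per_sequence = as.integer(copies_per_sequence),
                 degradation = degradation, anchor = anchor),
            class = "motif_plant")
}

# "RXX[VL]G" -> list of allowed-residue character vectors per position
parse_pattern <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1, nzchar(pattern))
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  pos <- list()
  i <- 1
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1
      cls <- character()
      while (j <= length(chars) && chars[j] != "]") {
        cls <- c(cls, chars[j]); j <- j + 1
      }
      if (j > length(chars)) stop("unclosed bracket class in pattern: ", pattern)
      if (length(cls) < 2) stop("bracket class needs >= 2 residues: ", pattern)
      if (!all(cls %in% AA20)) stop("invalid residue in pattern class: ", pattern)
      pos[[length(pos) + 1]] <- cls
      i <- j + 1
    } else if (ch == "X") {
      pos[[length(pos) + 1]] <- AA20
      i <- i + 1
    } else {
      if (!(ch %in% AA20)) stop("invalid residue '", ch, "' in pattern: ", pattern)
      pos[[length(pos) + 1]] <- ch
      i <- i + 1
    }
  }
  pos
}

family_seed <- function(seed, fam_index) {
  (as.integer(seed) + 100003L * (fam_index - 1L)) %% 2147483647L
}

#' Simulate diverged protein families with optional planted motifs
#'
#' Each family descends from an independent uniform-random ancestor. Members
#' diverge by per-site substitutions and geometric-length indels, then planted
#' motif instances (if any) are inserted at uniform random interior positions,
#' with ground-truth coordinates (on the final sequence) recorded per copy.
#' Output is byte-reproducible for a given configuration.
#'
#' @param config a [sim_config()].
#' @return list of `seq_family` objects. Each has fields `name`, `ids`,
#'   `seqs` (named character vector), `family` (per-record family tag) and
#'   `truth` (data frame: id, family, motif, start, end, n_degraded; 1-based
#'   inclusive coordinates).
#' @export
simulate_families <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  for (p in config$planted_motifs) {
    if (length(p$positions) > config$ancestor_length)
      stop("planted motif pattern is longer than the ancestor")
    if (any(p$target_families < 1 | p$target_families > config$n_families))
      stop("motif target_families outside 1..n_families")
  }
  lapply(seq_len(config$n_families), function(f) simulate_one_family(config, f))
}

simulate_one_family <- function(config, f) {
  set.seed(family_seed(config$seed, f))
  name <- sprintf("fam%d", f)
  n <- config$seqs_per_family
  L <- config$ancestor_length
  ancestor <- sample(AA20, L, replace = TRUE)
  muts <- lapply(seq_len(n), function(i)
    mutate_sequence(ancestor, config$substitution_rate, config$indel_rate,
                    config$indel_length_mean))
  seqvs <- lapply(muts, `[[`, "seq")
  amaps <- lapply(muts, `[[`, "amap") # ancestor position of each residue
  ids <- sprintf("%s_%04d", name, seq_len(n))
  # per-sequence placement records; starts are shifted as later copies land
  placed <- replicate(n, list(), simplify = FALSE)
  for (mi in seq_along(config$planted_motifs)) {
    plant <- config$planted_motifs[[mi]]
    if (!(f %in% plant$target_families)) next
    anchor_pos <- if (plant$anchor == "fixed")
      sample.int(L - 1L, 1) else NA_integer_
    n_carriers <- round(plant$occupancy * n)
    carriers <- if (n_carriers > 0) sort(sample.int(n, n_carriers)) else integer()
    for (s in carriers) {
      for (cp in seq_len(plant$copies_per_sequence)) {
        at <- if (cp == 1L && !is.na(anchor_pos)) {
          # last surviving residue at or before the anchor ancestor position
          anc_ok <- which(!is.na(amaps[[s]]) & amaps[[s]] <= anchor_pos)
          min(max(c(1L, anc_ok)), length(seqvs[[s]]) - 1L)
        } else NA_integer_
        ins <- insert_motif(seqvs[[s]], plant, placed[[s]], at = at)
        if (is.null(ins)) next # no legal insertion point left
        seqvs[[s]] <- ins$seq
        amaps[[s]] <- append(amaps[[s]],
                             rep(NA_integer_, ins$end - ins$start + 1L),
                             after = ins$start - 1L)
        # shift earlier placements that lie right of the insertion point
        placed[[s]] <- lapply(placed[[s]], function(pl) {
          if (pl$start > ins$start - 1L) {
            w <- ins$end - ins$start + 1L
            pl$start <- pl$start + w
            pl$end <- pl$end + w
          }
          pl
        })
        placed[[s]][[length(placed[[s]]) + 1]] <-
          list(motif = mi, start = ins$start, end = ins$end,
               n_degraded = ins$n_degraded)
      }
    }
  }
  truth <- do.call(rbind, lapply(seq_len(n), function(s) {
    if (!length(placed[[s]])) return(NULL)
    do.call(rbind, lapply(placed[[s]], function(pl)
      data.frame(id = ids[s], family = name, motif = pl$motif,
                 start = pl$start, end = pl$end, n_degraded = pl$n_degraded,
                 stringsAsFactors = FALSE)))
  }))
  if (is.null(truth))
    truth <- data.frame(id = character(), family = character(),
                        motif = integer(), start = integer(),
                        end = integer(), n_degraded = integer(),
                        stringsAsFactors = FALSE)
  seqs <- vapply(seqvs, paste, "", collapse = "")
  structure(list(name = name, ids = ids, seqs = setNames(seqs, ids),
                 family = rep(name, n), truth = truth),
            class = "seq_family")
}

# Diverge one sequence from the ancestor; returns the residue vector and the
# map from each residue to its ancestor position (NA for inserted residues).
mutate_sequence <- function(ancestor, sub_rate, indel_rate, indel_mean) {
  s <- ancestor
  L <- length(s)
  amap <- seq_len(L)
  if (sub_rate > 0) {
    hit <- which(runif(L) < sub_rate)
    if (length(hit)) {
      # uniform over the 19 alternatives: shift past the current residue
      cur <- match(s[hit], AA20)
      alt <- sample.int(19L, length(hit), replace = TRUE)
      alt <- ifelse(alt >= cur, alt + 1L, alt)
      s[hit] <- AA20[alt]
    }
  }
  if (indel_rate > 0) {
    ev <- which(runif(L) < indel_rate)
    for (p in rev(ev)) { # right-to-left keeps earlier positions valid
      len <- min(1L + rgeom(1, 1 / indel_mean), 10L)
      if (runif(1) < 0.5) { # deletion starting at p
        if (p <= length(s)) {
          del <- p:min(p + len - 1L, length(s))
          s <- s[-del]
          amap <- amap[-del]
        }
      } else {             # insertion after p
        at <- min(p, length(s))
        s <- append(s, sample(AA20, len, replace = TRUE), after = at)
        amap <- append(amap, rep(NA_integer_, len), after = at)
      }
    }
    if (length(s) < 1) { s <- sample(AA20, 1); amap <- NA_integer_ }
  }
  list(seq = s, amap = amap)
}

# Insert one realized motif instance into residue vector `s`, at position
# `at` when given (clamped away from existing spans) or at a uniform random
# interior position, never splitting an existing planted span.
insert_motif <- function(s, plant, placed, at = NA_integer_) {
  L <- length(s)
  if (L < 2) return(NULL)
  allowed <- seq_len(L - 1L) # insert between p and p+1
  for (pl in placed)
    allowed <- setdiff(allowed, seq(pl$start, pl$end - 1L))
  if (!length(allowed)) return(NULL)
  p <- if (!is.na(at)) allowed[which.min(abs(allowed - at))]
       else if (length(allowed) == 1) allowed
       else sample(allowed, 1)
  inst <- vapply(plant$positions, function(a)
    if (length(a) == 1) a else sample(a, 1), "")
  n_deg <- 0L
  if (plant$degradation > 0) {
    deg <- which(runif(length(inst)) < plant$degradation)
    if (length(deg)) {
      inst[deg] <- sample(AA20, length(deg), replace = TRUE)
      n_deg <- length(deg)
    }
  }
  w <- length(inst)
  list(seq = append(s, inst, after = p), start = p + 1L, end = p + w,
       n_degraded = n_deg)
}

#' @export
print.seq_family <- function(x, ...) {
  cat(sprintf("<seq_family> %s: %d sequences, lengths %d-%d, %d planted copies\n",
              x$name, length(x$ids), min(nchar(x$seqs)), max(nchar(x$seqs)),
              nrow(x$truth)))
  invisible(x)
}

#' Write the planted-motif ground truth as a TSV table
#'
#' One row per planted copy: sequence id, family, motif index, start, end
#' (1-based inclusive on the final sequence) and the number of degraded
#' positions in that copy. A header-only file is written when nothing was
#' planted.
#'
#' @param families list of `seq_family` objects from [simulate_families()].
#' @param path output file path.
#' @return the combined truth data frame, invisibly.
#' @export
write_truth <- function(families, path) {
  if (inherits(families, "seq_family")) families <- list(families)
  truth <- do.call(rbind, lapply(families, function(f) f$truth))
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(truth)
}
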