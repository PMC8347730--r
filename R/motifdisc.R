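# ZOOPS (zero-or-one occurrence per sequence) expectation-maximization motif
# discovery. Sequences are held as integer vectors (1..20, 0 = masked); the
# per-window scoring and count accumulation run in C++.

# 0-order background over unmasked residues, with a +1 pseudocount
background_freqs <- function(iseqs) {
  cnt <- tabulate(unlist(iseqs, use.names = FALSE), nbins = 20) + 1
  setNames(cnt / sum(cnt), AA20)
}

# PPM seeded from one substring: matched residue gets prob `match`, the rest
# share the remainder uniformly
seed_ppm <- function(window, match = 0.5) {
  W <- length(window)
  ppm <- matrix((1 - match) / 19, 20, W)
  ppm[cbind(window, seq_len(W))] <- match
  ppm
}

# Full EM run; the E/M iteration lives in C++ (cpp_zoops_em). The returned
# parameters are the ones that entered the final E-step, so the reported
# posteriors, objective trace and llr (data log-likelihood gain over the
# pure-background model, prior terms excluded so the statistic is comparable
# across permutations) are mutually consistent.
em_core <- function(iseqs, width, bg, init_ppm, init_gamma = 0.5,
                    max_iter = 100, tol = 1e-6, pseudocount = 0.01) {
  fit <- cpp_zoops_em(iseqs, bg, init_ppm, init_gamma,
                      as.integer(max_iter), tol, pseudocount)
  list(ppm = fit$ppm, gamma = fit$gamma, trace = fit$trace, z = fit$z,
       zsum = fit$zsum, llr = fit$ll)
}

# candidate starts: sample windows, score each seed PPM by total cross-sequence
# support (sum over sequences of the best window log-odds), short-EM the best
n_candidate_windows <- function(iseqs, W) {
  sum(pmax(lengths(iseqs) - W + 1L, 0L))
}

sample_candidates <- function(iseqs, W, n_candidates) {
  valid <- lapply(iseqs, function(x) {
    m <- length(x) - W + 1L
    if (m < 1) return(integer())
    cs <- cumsum(c(0L, x == 0L)) # masked-residue prefix sums
    which(cs[(W + 1):(length(x) + 1L)] - cs[seq_len(m)] == 0L)
  })
  counts <- lengths(valid)
  tot <- sum(counts)
  if (tot == 0) return(NULL)
  take <- if (tot <= n_candidates) seq_len(tot) else
    sort(sample.int(tot, n_candidates))
  seq_of <- rep.int(seq_along(valid), counts)
  pos_of <- unlist(valid, use.names = FALSE)
  lapply(take, function(t) c(seq_of[t], pos_of[t]))
}

#' Single-width ZOOPS EM motif discovery
#'
#' Fits the zero-or-one-occurrence-per-sequence mixture model: each sequence
#' carries at most one instance of a width-`width` motif described by a
#' position probability matrix (PPM), against a 0-order background. The
#' E-step computes per-site and per-sequence occupancy posteriors; the M-step
#' re-estimates the PPM (Dirichlet pseudocounts) and the occupancy prior. The
#' tracked MAP objective is non-decreasing across iterations. Starting points
#' are chosen by seeding PPMs from sampled substrings, ranking them by total
#' cross-sequence support, running a 5-iteration EM on the best few and
#' continuing the best of those to convergence.
#'
#' @param x sequences: a `seq_family`, named character vector, or list of
#'   integer-coded sequences. Sequences shorter than `width` are excluded
#'   with a warning (an error if none remain).
#' @param width motif width W.
#' @param background optional length-20 background frequencies; estimated
#'   from the data when `NULL`.
#' @param max_iter,tol EM stopping rule (absolute objective change).
#' @param seed integer seed for the start-point sampling.
#' @param n_starts number of short-EM starting points.
#' @param n_candidates number of sampled candidate substrings.
#' @param pseudocount Dirichlet pseudocount per PPM cell.
#' @return object of class `motif`: PPM (20 x W), `width`, `consensus`,
#'   `occurrences` (data frame id, family, start, prob), `llr` (data
#'   log-likelihood gain over background), `gamma` (fitted occupancy prior),
#'   `trace` (objective per iteration), `background`, `evalue` (NA until
#'   [permutation_evalue()]), `rank` (NA until [discover_motifs()]).
#' @export
em_motif <- function(x, width, background = NULL, max_iter = 100, tol = 1e-6,
                     seed = NULL, n_starts = 20, n_candidates = 100,
                     pseudocount = 0.01) {
  seqs <- if (is.list(x) && !inherits(x, "seq_family")) NULL else as_seq_vector(x)
  if (is.null(seqs)) {
    iseqs <- x
    ids <- names(x) %||% sprintf("seq%d", seq_along(x))
    fams <- attr(x, "families") %||% rep(NA_character_, length(x))
  } else {
    iseqs <- lapply(seqs, encode_seq)
    ids <- names(seqs)
    fams <- seq_families_of(x)
  }
  width <- as.integer(width)
  stopifnot(width >= 1)
  long <- lengths(iseqs) >= width
  if (!all(long)) {
    warning(sum(!long), " sequence(s) shorter than the motif width excluded")
    if (!any(long)) stop("all sequences shorter than the motif width")
    iseqs <- iseqs[long]; ids <- ids[long]; fams <- fams[long]
  }
  if (length(iseqs) < 2) stop("need at least two sequences")
  if (!is.null(seed)) set.seed(seed)
  bg <- background %||% background_freqs(iseqs)
  stopifnot(length(bg) == 20, abs(sum(bg) - 1) < 1e-6)

  cands <- sample_candidates(iseqs, width, n_candidates)
  if (is.null(cands)) stop("no unmasked window of width ", width, " available")
  # support score of each candidate seed (batched in C++)
  wins <- do.call(rbind, lapply(cands, function(cd)
    iseqs[[cd[1]]][cd[2]:(cd[2] + width - 1L)]))
  support <- cpp_support_scores(iseqs, wins, bg, 0.5)
  top <- order(-support)[seq_len(min(n_starts, length(cands)))]
  best <- NULL
  for (t in top) {
    cd <- cands[[t]]
    win <- iseqs[[cd[1]]][cd[2]:(cd[2] + width - 1L)]
    fit <- em_core(iseqs, width, bg, seed_ppm(win), 0.5,
                   max_iter = 5, tol = 0, pseudocount = pseudocount)
    if (is.null(best) || tail_obj(fit) > tail_obj(best)) {
      best <- fit
      best$start_window <- win
    }
  }
  fit <- em_core(iseqs, width, bg, seed_ppm(best$start_window), 0.5,
                 max_iter = max_iter, tol = tol, pseudocount = pseudocount)
  finalize_motif(fit, iseqs, ids, fams, bg, width,
                 settings = list(max_iter = max_iter, tol = tol,
                                 n_starts = n_starts,
                                 n_candidates = n_candidates,
                                 pseudocount = pseudocount))
}

tail_obj <- function(fit) fit$trace[length(fit$trace)]

finalize_motif <- function(fit, iseqs, ids, fams, bg, width, settings) {
  occ <- list()
  for (i in seq_along(iseqs)) {
    z <- fit$z[[i]]
    if (!length(z)) next
    psite <- fit$zsum[i] # P(sequence carries the motif)
    if (psite >= 0.5) {
      j <- which.max(z)
      occ[[length(occ) + 1]] <- data.frame(id = ids[i], family = fams[i],
                                           start = j, prob = z[j],
                                           stringsAsFactors = FALSE)
    }
  }
  occ <- if (length(occ)) do.call(rbind, occ) else
    data.frame(id = character(), family = character(), start = integer(),
               prob = numeric(), stringsAsFactors = FALSE)
  ppm <- fit$ppm
  dimnames(ppm) <- list(AA20, NULL)
  structure(list(ppm = ppm, width = width,
                 consensus = paste(AA20[apply(ppm, 2, which.max)],
                                   collapse = ""),
                 occurrences = occ, llr = fit$llr, gamma = fit$gamma,
                 trace = fit$trace, background = bg, evalue = NA_real_,
                 rank = NA_integer_, settings = settings),
            class = "motif")
}

#' @export
print.motif <- function(x, ...) {
  cat(sprintf("<motif> width %d  consensus %s  llr %.1f  sites %d  E %s\n",
              x$width, x$consensus, x$llr, nrow(x$occurrences),
              if (is.na(x$evalue)) "NA" else format(x$evalue, digits = 3)))
  invisible(x)
}

#' Repeated motif discovery with masking
#'
#' Discovers `n_motifs` motifs in decreasing order of strength. For each
#' rank, single-width EM fits are run over a width grid (a coarse grid over
#' `[w_min, w_max]`, then refinement within 2 of the best width); the best
#' width is chosen by permutation E-value when `B > 0` (ties by
#' log-likelihood-ratio per column), otherwise by log-likelihood ratio per
#' column. The winning motif's occurrences are then masked (excluded from
#' both candidate sites and background re-estimation) before the next rank.
#'
#' @param x sequences (`seq_family` or named character vector).
#' @param w_min,w_max motif width bounds (defaults 6 and 30).
#' @param n_motifs number of motifs to report.
#' @param widths optional explicit width grid overriding the coarse grid +
#'   refinement.
#' @param seed integer seed; per-rank and per-width streams are derived from
#'   it, so results are reproducible.
#' @param B permutation replicates for width selection and reported E-values
#'   (0 = skip permutation testing; E-values stay `NA`).
#' @param ... passed to [em_motif()] (e.g. `n_starts`, `max_iter`).
#' @return list of `motif` objects with `rank` set (1 = strongest).
#' @export
discover_motifs <- function(x, w_min = 6, w_max = 30, n_motifs = 1,
                            widths = NULL, seed = 1L, B = 0, ...) {
  seqs <- as_seq_vector(x)
  ids <- names(seqs)
  fams <- seq_families_of(x)
  iseqs <- lapply(seqs, encode_seq)
  stopifnot(n_motifs >= 1, w_min >= 1, w_max >= w_min)
  if (max(lengths(iseqs)) < w_min)
    stop("no admissible motif width: all sequences shorter than ", w_min)
  grid <- if (!is.null(widths)) sort(unique(as.integer(widths))) else
    sort(unique(pmin(pmax(c(6, 8, 11, 15, 21, 30), w_min), w_max)))
  grid <- grid[grid >= w_min & grid <= w_max]
  if (!length(grid)) grid <- w_min

  motifs <- vector("list", n_motifs)
  for (r in seq_len(n_motifs)) {
    fit_width <- function(w) {
      m <- try(em_motif(iseqs_named(iseqs, ids, fams), w,
                        seed = (seed + 1009L * r + 97L * w) %% 2147483647L,
                        ...), silent = TRUE)
      if (inherits(m, "try-error")) return(NULL)
      if (B > 0)
        m$evalue <- permutation_evalue(m, iseqs_named(iseqs, ids, fams), B = B,
                                       seed = (seed + 7L * r + 13L * w) %%
                                         2147483647L)
      m
    }
    fits <- Filter(Negate(is.null), lapply(grid, fit_width))
    if (!length(fits)) stop("no admissible motif width for rank ", r)
    best <- pick_best(fits, B)
    if (is.null(widths)) { # refine +/- 2 around the winning width
      extra <- setdiff(max(w_min, best$width - 2):min(w_max, best$width + 2),
                       vapply(fits, `[[`, 0L, "width"))
      if (length(extra)) {
        fits2 <- Filter(Negate(is.null), lapply(extra, fit_width))
        best <- pick_best(c(list(best), fits2), B)
      }
    }
    best$rank <- r
    motifs[[r]] <- best
    # mask the winning occurrences before the next rank
    if (nrow(best$occurrences)) {
      for (q in seq_len(nrow(best$occurrences))) {
        i <- match(best$occurrences$id[q], ids)
        a <- best$occurrences$start[q]
        iseqs[[i]][a:(a + best$width - 1L)] <- 0L
      }
    }
  }
  motifs
}

iseqs_named <- function(iseqs, ids, fams) {
  x <- iseqs
  names(x) <- ids
  attr(x, "families") <- fams
  x
}

pick_best <- function(fits, B) {
  percol <- vapply(fits, function(m) m$llr / m$width, 0)
  if (B > 0) {
    ev <- vapply(fits, `[[`, 0, "evalue")
    fits[[order(ev, -percol)[1]]]
  } else {
    fits[[order(-percol)[1]]]
  }
}

# Exact (discretized) null distribution of the window log-odds score under
# the 0-order background: smallest score whose upper-tail chance probability
# per window is <= p. Computed by convolving the per-column score
# distributions on a fixed grid, as motif scanners do for p-values.
pwm_score_threshold <- function(lods, bg, p = 1e-4, step = 0.005) {
  bins <- round(lods / step)
  cur <- 1
  curlo <- 0
  for (t in seq_len(ncol(bins))) {
    bl <- bins[, t]
    mn <- min(bl)
    new <- numeric(length(cur) + max(bl) - mn)
    for (a in 1:20) {
      idx <- seq_along(cur) + (bl[a] - mn)
      new[idx] <- new[idx] + cur * bg[a]
    }
    cur <- new
    curlo <- curlo + mn
  }
  tail_p <- rev(cumsum(rev(cur)))
  k <- which(tail_p <= p)[1]
  if (is.na(k)) return(Inf) # no score is rare enough at this p
  (curlo + k - 1) * step
}

#' Scan sequences for motif occurrences
#'
#' Slides the motif's log-odds matrix (PPM against its background) over every
#' sequence and reports all windows scoring at least `threshold`; multiple
#' (even overlapping) occurrences per sequence are allowed, so tandem repeats
#' of a motif are recovered.
#'
#' @param motif a `motif`.
#' @param x sequences (`seq_family`, named character vector; may be empty).
#' @param threshold log-odds score threshold. The default is the score whose
#'   chance probability per window under the motif's background is
#'   `p_chance`, from the exact (discretized) convolution of the per-column
#'   score distributions.
#' @param p_chance per-window chance-hit probability defining the default
#'   threshold.
#' @return data frame: id, family, start, score.
#' @export
scan_motif <- function(motif, x, threshold = NULL, p_chance = 1e-4) {
  seqs <- as_seq_vector(x)
  if (!length(seqs))
    return(data.frame(id = character(), family = character(),
                      start = integer(), score = numeric(),
                      stringsAsFactors = FALSE))
  fams <- seq_families_of(x)
  iseqs <- lapply(seqs, encode_seq)
  lods <- log(motif$ppm) - log(motif$background)
  threshold <- threshold %||% pwm_score_threshold(lods, motif$background,
                                                  p = p_chance)
  sl <- cpp_window_scores(iseqs, lods)
  out <- list()
  for (i in seq_along(sl)) {
    hit <- which(sl[[i]] >= threshold)
    if (length(hit))
      out[[length(out) + 1]] <- data.frame(id = names(seqs)[i],
                                           family = fams[i], start = hit,
                                           score = sl[[i]][hit],
                                           stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(id = character(), family = character(), start = integer(),
               score = numeric(), stringsAsFactors = FALSE)
}

#' Empirical permutation E-value of a motif
#'
#' Shuffles the residues within each sequence `B` times, re-runs the
#' single-width EM fit on each shuffled set with the motif's own settings and
#' compares the resulting log-likelihood ratios with the observed one:
#' `E = n_tests * (1 + #(llr_null >= llr_obs)) / (B + 1)`, the expected
#' number of equally good motifs under the within-sequence shuffle null.
#'
#' @param motif a fitted `motif`.
#' @param x the sequence set the motif was fitted on.
#' @param B number of shuffles (>= 19).
#' @param seed integer seed.
#' @param n_tests multiple-testing multiplier (e.g. number of widths tried).
#' @return E-value in `(0, n_tests]`; the null llr sample is attached as
#'   attribute `"null_llr"`.
#' @export
permutation_evalue <- function(motif, x, B = 99, seed = NULL, n_tests = 1) {
  stopifnot(B >= 19)
  seqs <- if (is.list(x) && !inherits(x, "seq_family")) x else
    lapply(as_seq_vector(x), encode_seq)
  if (!is.null(seed)) set.seed(seed)
  st <- motif$settings
  null_llr <- numeric(B)
  for (b in seq_len(B)) {
    shuf <- lapply(seqs, function(s) {
      un <- which(s > 0)
      s[un] <- s[un][sample.int(length(un))]
      s
    })
    m <- em_motif(shuf, motif$width, max_iter = st$max_iter, tol = st$tol,
                  n_starts = st$n_starts, n_candidates = st$n_candidates,
                  pseudocount = st$pseudocount)
    null_llr[b] <- m$llr
  }
  e <- n_tests * (1 + sum(null_llr >= motif$llr)) / (B + 1)
  attr(e, "null_llr") <- null_llr
  e
}

#' Write motifs in MEME minimal format
#'
#' Emits the standard minimal motif exchange format: version header, the
#' 20-letter protein alphabet, background letter frequencies and one
#' letter-probability matrix block per motif.
#'
#' @param motifs list of `motif` objects (or a single one).
#' @param path output file.
#' @param background length-20 background frequencies; defaults to the first
#'   motif's background.
#' @return `path`, invisibly.
#' @export
write_meme <- function(motifs, path, background = NULL) {
  if (inherits(motifs, "motif")) motifs <- list(motifs)
  bg <- background %||% motifs[[1]]$background
  con <- file(path, open = "wb")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con, sep = "\n")
  w("MEME version 4")
  w("")
  w("ALPHABET= %s", paste(AA20, collapse = ""))
  w("")
  w("Background letter frequencies")
  w("%s", paste(sprintf("%s %.6f", AA20, bg), collapse = " "))
  for (m in motifs) {
    w("")
    w("MOTIF m%s %s", if (is.na(m$rank)) "1" else m$rank, m$consensus)
    w("letter-probability matrix: alength= 20 w= %d nsites= %d E= %s",
      m$width, nrow(m$occurrences),
      if (is.na(m$evalue)) "0" else format(m$evalue, digits = 4))
    for (j in seq_len(m$width))
      w("%s", paste(sprintf("%.6f", m$ppm[, j]), collapse = " "))
  }
  invisible(path)
}
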