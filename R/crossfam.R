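#' Enumerate all unordered family pairs
#'
#' @param families list of `seq_family` objects or a character vector of
#'   family names (>= 2).
#' @return data frame with columns `a` and `b`, one row per unordered pair,
#'   `F(F-1)/2` rows in deterministic order.
#' @export
family_pairs <- function(families) {
  nm <- if (is.character(families)) families else
    vapply(families, `[[`, "", "name")
  if (length(nm) < 2) stop("need at least two families")
  cb <- combn(nm, 2)
  data.frame(a = cb[1, ], b = cb[2, ], stringsAsFactors = FALSE)
}

#' Sliding-window comparison of two motif sets
#'
#' Scores every cross-set pair of motif consensus strings by ends-free
#' ("overlap") global alignment under BLOSUM62 with affine gaps (open 11,
#' extend 1), ranks pairs by descending score (ties by the two motif ranks)
#' and returns the aligned consensus strings for the top pairs.
#'
#' @param motifs_a,motifs_b lists of `motif` objects (e.g. the per-family
#'   results of [discover_motifs()]).
#' @param top_n number of top-scoring pairs to return.
#' @return data frame: rank_a, rank_b, consensus_a, consensus_b, score,
#'   aligned_a, aligned_b.
#' @export
compare_motif_sets <- function(motifs_a, motifs_b, top_n = 10) {
  if (inherits(motifs_a, "motif")) motifs_a <- list(motifs_a)
  if (inherits(motifs_b, "motif")) motifs_b <- list(motifs_b)
  if (!length(motifs_a) || !length(motifs_b)) stop("empty motif set")
  ca <- vapply(motifs_a, `[[`, "", "consensus")
  cb <- vapply(motifs_b, `[[`, "", "consensus")
  ra <- vapply(seq_along(motifs_a), function(i)
    as.numeric(motifs_a[[i]]$rank %||% NA), 0)
  rb <- vapply(seq_along(motifs_b), function(i)
    as.numeric(motifs_b[[i]]$rank %||% NA), 0)
  ra[is.na(ra)] <- seq_along(ca)[is.na(ra)]
  rb[is.na(rb)] <- seq_along(cb)[is.na(rb)]
  grid <- expand.grid(i = seq_along(ca), j = seq_along(cb))
  score <- mapply(function(i, j) motif_align_score(ca[i], cb[j]),
                  grid$i, grid$j)
  ord <- order(-score, ra[grid$i], rb[grid$j])
  take <- ord[seq_len(min(top_n, length(ord)))]
  aligned <- lapply(take, function(t)
    motif_align_strings(ca[grid$i[t]], cb[grid$j[t]]))
  data.frame(rank_a = ra[grid$i[take]], rank_b = rb[grid$j[take]],
             consensus_a = ca[grid$i[take]], consensus_b = cb[grid$j[take]],
             score = score[take],
             aligned_a = vapply(aligned, `[[`, "", 1),
             aligned_b = vapply(aligned, `[[`, "", 2),
             stringsAsFactors = FALSE)
}

motif_align_score <- function(a, b) {
  Biostrings::pairwiseAlignment(Biostrings::AAString(a),
                                Biostrings::AAString(b),
                                type = "overlap",
                                substitutionMatrix = blosum62(),
                                gapOpening = 11, gapExtension = 1,
                                scoreOnly = TRUE)
}

motif_align_strings <- function(a, b) {
  al <- Biostrings::pairwiseAlignment(Biostrings::AAString(a),
                                      Biostrings::AAString(b),
                                      type = "overlap",
                                      substitutionMatrix = blosum62(),
                                      gapOpening = 11, gapExtension = 1)
  c(as.character(Biostrings::alignedPattern(al)),
    as.character(Biostrings::alignedSubject(al)))
}

# Modal residue per motif column among a family's hit windows
family_site_consensus <- function(m, fam, hits) {
  W <- m$width
  if (nrow(hits) == 0) return(rep(NA_integer_, W))
  wins <- lapply(seq_len(nrow(hits)), function(q) {
    s <- fam$seqs[[hits$id[q]]]
    encode_seq(substr(s, hits$start[q], hits$start[q] + W - 1L))
  })
  M <- do.call(rbind, wins)
  vapply(seq_len(W), function(t) {
    tb <- tabulate(M[, t], nbins = 20)
    which.max(tb) # alphabetical on ties
  }, 0L)
}

#' Search for motifs shared across families
#'
#' Pools the sequences of the given families (and, optionally, of every
#' unordered family pair), runs masked motif discovery on each pooled set,
#' and judges each discovered motif "shared" when it (a) covers at least
#' `c_min` of the sequences of EVERY family in the pooled set (coverage =
#' fraction of sequences with a scan hit), (b) is coherent across families —
#' the per-family modal residues of the hit windows agree, for every family
#' pair, in at least `coherence_min` of the motif columns — and (c) reaches
#' permutation E-value `<= alpha`. The coherence requirement guards against
#' a degeneracy of mixture-model motif discovery on pooled homologous
#' families: EM can converge to a "blend" whose bimodal columns superimpose
#' two families' private conserved windows; such a blend covers both
#' families without any residue-level agreement between them. The E-value is
#' only computed for motifs passing (a) and (b) (the verdict cannot change
#' for the others).
#'
#' @param families list of `seq_family` objects, each already reduced to its
#'   representative set.
#' @param n_motifs motifs discovered per pooled set.
#' @param c_min minimum per-family sequence coverage for a shared verdict.
#' @param coherence_min minimum fraction of motif columns on which the modal
#'   hit-window residues of every family pair must agree.
#' @param alpha E-value threshold for a shared verdict.
#' @param B permutation replicates for the E-value.
#' @param seed integer seed.
#' @param pairs also search every unordered family pair (as well as the full
#'   pooled set).
#' @param scan_threshold passed to [scan_motif()].
#' @param ... width grid and EM settings passed to [discover_motifs()]
#'   (e.g. `w_min`, `w_max`, `widths`, `n_starts`).
#' @return data frame of verdicts: scope, rank, width, consensus, coverage
#'   per family (semicolon-separated `family=fraction`), min_coverage,
#'   coherence, evalue, shared. The discovered motifs are attached as
#'   attribute `"motifs"` (a list named by scope).
#' @export
shared_motif_search <- function(families, n_motifs = 3, c_min = 0.25,
                                coherence_min = 0.5, alpha = 0.01, B = 99,
                                seed = 1L, pairs = TRUE,
                                scan_threshold = NULL, ...) {
  stopifnot(length(families) >= 2)
  nm <- vapply(families, `[[`, "", "name")
  scopes <- list(nm)
  if (pairs && length(nm) > 2) {
    fp <- family_pairs(families)
    for (q in seq_len(nrow(fp))) scopes[[length(scopes) + 1]] <-
      c(fp$a[q], fp$b[q])
  }
  rows <- list()
  all_motifs <- list()
  for (sc in scopes) {
    scope_name <- paste(sc, collapse = "+")
    members <- families[match(sc, nm)]
    pooled <- merge_families(members, name = scope_name)
    motifs <- discover_motifs(pooled, n_motifs = n_motifs,
                              seed = (seed + sum(utf8ToInt(scope_name))) %%
                                2147483647L, B = 0, ...)
    all_motifs[[scope_name]] <- motifs
    for (m in motifs) {
      hitlist <- lapply(members, function(f)
        scan_motif(m, f, threshold = scan_threshold))
      cov <- vapply(seq_along(members), function(q)
        length(unique(hitlist[[q]]$id)) / length(members[[q]]$ids), 0)
      names(cov) <- sc
      covpass <- min(cov) >= c_min
      # cross-family coherence of the hit windows
      coh <- NA_real_
      if (covpass) {
        cons <- lapply(seq_along(members), function(q)
          family_site_consensus(m, members[[q]], hitlist[[q]]))
        agree <- combn(length(members), 2, function(pr)
          mean(cons[[pr[1]]] == cons[[pr[2]]]))
        coh <- min(agree)
      }
      cohpass <- covpass && !is.na(coh) && coh >= coherence_min
      ev <- NA_real_
      if (cohpass && B > 0)
        ev <- as.numeric(permutation_evalue(m, pooled, B = B,
                                            seed = (seed + 31L * m$rank +
                                                    sum(utf8ToInt(scope_name))) %%
                                              2147483647L))
      rows[[length(rows) + 1]] <- data.frame(
        scope = scope_name, rank = m$rank, width = m$width,
        consensus = m$consensus,
        coverage = paste(sprintf("%s=%.3f", sc, cov), collapse = ";"),
        min_coverage = min(cov), coherence = coh, evalue = ev,
        shared = cohpass && !is.na(ev) && ev <= alpha,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "motifs") <- all_motifs
  out
}

#' Run the full cross-family pipeline
#'
#' Executes both analysis branches end to end on a list of families (from
#' FASTA via [read_fasta_family()] or simulated via [simulate_families()]):
#' per-family reduction to representatives, merge, neighbor-joining tree on
#' the merged set (branch 1); per-family progressive realignment,
#' conservation profiles, per-family motif discovery, pooled and pairwise
#' shared-motif search, and cross-family motif-set comparison (branch 2).
#' All artifacts are written under `out_dir` and listed in a run manifest
#' that records seeds, parameters and the package version.
#'
#' @param families list of `seq_family` objects.
#' @param out_dir output directory (created if needed).
#' @param n_representatives representatives kept per family before motif
#'   work.
#' @param n_motifs motifs discovered per family.
#' @param top_n top comparisons reported per family pair.
#' @param c_min,alpha,B shared-motif verdict parameters (see
#'   [shared_motif_search()]).
#' @param k k-mer size for distances.
#' @param seed integer seed.
#' @param ... width grid / EM settings passed to [discover_motifs()] and
#'   [shared_motif_search()].
#' @return the manifest data frame (stage, artifact, detail), invisibly;
#'   written as `manifest.tsv`.
#' @export
run_pipeline <- function(families, out_dir, n_representatives = 400,
                         n_motifs = 30, top_n = 10, c_min = 0.25,
                         alpha = 0.01, B = 99, k = 3, seed = 1L, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, artifact, detail = "") {
    manifest[[length(manifest) + 1]] <<- data.frame(
      stage = stage, artifact = artifact, detail = detail,
      stringsAsFactors = FALSE)
  }
  fail <- function(stage, e) {
    write.table(do.call(rbind, manifest),
                file.path(out_dir, "manifest.partial.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  note("config", "parameters",
       sprintf("seed=%d n_representatives=%d n_motifs=%d top_n=%d c_min=%g alpha=%g B=%d k=%d version=%s",
               seed, n_representatives, n_motifs, top_n, c_min, alpha, B, k,
               as.character(packageVersion("crossmotif"))))

  reduced <- tryCatch({
    lapply(families, function(f) {
      if (length(f$ids) > n_representatives) {
        dm <- distance_matrix(f, k = k)
        red <- reduce_representatives(dm, n_representatives)
        f <- subset_family(f, red$kept)
      }
      p <- file.path(out_dir, sprintf("%s.kept.fasta", f$name))
      write_fasta(f, p)
      note("reduce", basename(p), sprintf("n=%d", length(f$ids)))
      f
    })
  }, error = function(e) fail("reduce", e))

  tryCatch({
    merged <- merge_families(reduced)
    dm <- distance_matrix(merged, k = k)
    tr <- nj_tree(dm)
    p <- file.path(out_dir, "merged.nj.nwk")
    ape::write.tree(tr, p)
    note("tree", basename(p), sprintf("tips=%d", length(tr$tip.label)))
  }, error = function(e) fail("tree", e))

  alns <- tryCatch({
    lapply(reduced, function(f) {
      aln <- progressive_align(f, k = k)
      pa <- file.path(out_dir, sprintf("%s.aln.fasta", f$name))
      write_alignment(aln, pa)
      note("align", basename(pa), sprintf("columns=%d", aln$n_columns))
      prof <- conservation_profile(aln)
      pp <- file.path(out_dir, sprintf("%s.conservation.tsv", f$name))
      write_profile(prof, pp)
      note("conserve", basename(pp),
           sprintf("mean_S=%.4f", mean(prof$S, na.rm = TRUE)))
      aln
    })
  }, error = function(e) fail("align", e))

  fam_motifs <- tryCatch({
    lapply(reduced, function(f) {
      ms <- discover_motifs(f, n_motifs = n_motifs,
                            seed = (seed + sum(utf8ToInt(f$name))) %%
                              2147483647L, B = 0, ...)
      pm <- file.path(out_dir, sprintf("%s.motifs.meme", f$name))
      write_meme(ms, pm)
      note("motifs", basename(pm), sprintf("n=%d", length(ms)))
      occ <- do.call(rbind, lapply(ms, function(m)
        cbind(rank = m$rank, m$occurrences)))
      po <- file.path(out_dir, sprintf("%s.occurrences.tsv", f$name))
      write.table(occ, po, sep = "\t", quote = FALSE, row.names = FALSE)
      note("motifs", basename(po), "")
      ms
    })
  }, error = function(e) fail("motifs", e))

  tryCatch({
    fp <- family_pairs(reduced)
    comp <- do.call(rbind, lapply(seq_len(nrow(fp)), function(q) {
      ia <- match(fp$a[q], vapply(reduced, `[[`, "", "name"))
      ib <- match(fp$b[q], vapply(reduced, `[[`, "", "name"))
      cbind(family_a = fp$a[q], family_b = fp$b[q],
            compare_motif_sets(fam_motifs[[ia]], fam_motifs[[ib]],
                               top_n = top_n))
    }))
    pc <- file.path(out_dir, "motif_comparisons.tsv")
    write.table(comp, pc, sep = "\t", quote = FALSE, row.names = FALSE)
    note("compare", basename(pc), sprintf("rows=%d", nrow(comp)))
  }, error = function(e) fail("compare", e))

  tryCatch({
    verdicts <- shared_motif_search(reduced, c_min = c_min, alpha = alpha,
                                    B = B, seed = seed, ...)
    pv <- file.path(out_dir, "shared_verdicts.tsv")
    write.table(verdicts, pv, sep = "\t", quote = FALSE, row.names = FALSE)
    note("verdict", basename(pv), sprintf("shared=%d", sum(verdicts$shared)))
  }, error = function(e) fail("verdict", e))

  manifest <- do.call(rbind, manifest)
  write.table(manifest, file.path(out_dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

# best sliding-window Pearson correlation between two PPMs (no gaps): the
# secondary, matrix-level comparison mode
ppm_correlation <- function(ppm_a, ppm_b) {
  wa <- ncol(ppm_a); wb <- ncol(ppm_b)
  best <- -1
  for (off in -(wb - 1):(wa - 1)) {
    ja <- max(1, 1 + off):min(wa, wb + off)
    jb <- ja - off
    if (length(ja) < 4) next # require a meaningful overlap
    r <- stats::cor(as.vector(ppm_a[, ja]), as.vector(ppm_b[, jb]))
    if (!is.na(r) && r > best) best <- r
  }
  best
}

#' Best sliding-window correlation between two motifs' probability matrices
#'
#' Maximal Pearson correlation of the overlapping PPM columns over all
#' ungapped offsets (at least 4 overlapping columns). A matrix-level
#' alternative to the consensus-string alignment of [compare_motif_sets()].
#'
#' @param motif_a,motif_b `motif` objects.
#' @return correlation in `[-1, 1]`.
#' @export
compare_motif_ppms <- function(motif_a, motif_b) {
  ppm_correlation(motif_a$ppm, motif_b$ppm)
}
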