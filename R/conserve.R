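#' Normalized Shannon entropy of a column distribution
#'
#' Per-column variability `S = -sum(p_a * log20(p_a))` over the 20 amino-acid
#' types, with `0 * log 0 := 0`. The base-20 logarithm normalizes S to
#' `[0, 1]`: 0 for a fully conserved column (one residue type), 1 for the
#' uniform distribution over all 20 types.
#'
#' @param p probabilities (or counts, which are normalized) over the 20
#'   residue types.
#' @return entropy in `[0, 1]`; `NA` when all entries are zero (no residues).
#' @export
column_entropy <- function(p) {
  p <- as.numeric(p)
  stopifnot(length(p) == 20, all(p >= 0))
  tot <- sum(p)
  if (tot == 0) return(NA_real_)
  p <- p[p > 0] / tot
  -sum(p * log(p)) / log(20)
}

#' Per-column conservation profile of an alignment
#'
#' For every alignment column, the residue distribution `p_a` over the 20
#' amino-acid types and its normalized Shannon entropy. Under the default gap
#' policy, gaps are excluded and `p_a` is normalized over the non-gap
#' residues; the gap fraction is reported separately. Ambiguity codes
#' (B, Z, X, U, ...) are excluded from the distributions (with a message).
#' All-gap columns get `NA` entropy. Columns with less than 20% residue
#' occupancy are flagged low-coverage.
#'
#' @param alignment a `protein_msa`.
#' @param gap_policy `"exclude"` (default): normalize over non-gap residues.
#' @return object of class `conservation_profile`: list with `S` (per-column
#'   entropy), `dist` (20 x n_columns probability matrix), `n_residues`,
#'   `gap_fraction`, `low_coverage` and `n_rows`.
#' @export
conservation_profile <- function(alignment, gap_policy = "exclude") {
  gap_policy <- match.arg(gap_policy, "exclude")
  stopifnot(inherits(alignment, "protein_msa"), length(alignment$ids) > 0)
  M <- do.call(rbind, strsplit(alignment$rows, "", fixed = TRUE))
  nr <- nrow(M); nc <- ncol(M)
  codes <- matrix(match(M, AA20), nr, nc)  # NA = gap or ambiguity
  n_amb <- sum(!is.na(M) & is.na(codes) & M != "-")
  if (n_amb > 0)
    message(n_amb, " non-canonical residue(s) excluded from distributions")
  counts <- vapply(seq_len(nc), function(j)
    tabulate(codes[, j], nbins = 20), numeric(20))
  n_res <- colSums(counts)
  gap_fraction <- colSums(M == "-") / nr
  dist <- sweep(counts, 2, pmax(n_res, 1), "/")
  dist[, n_res == 0] <- NA_real_
  S <- apply(counts, 2, column_entropy)
  structure(list(S = S, dist = dist, n_residues = n_res,
                 gap_fraction = gap_fraction,
                 low_coverage = n_res / nr < 0.2, n_rows = nr),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("<conservation_profile> %d columns, mean S = %.3f (%d undefined)\n",
              length(x$S), mean(x$S, na.rm = TRUE), sum(is.na(x$S))))
  invisible(x)
}

#' Write a conservation profile as TSV
#'
#' Columns: column index, entropy, gap fraction, residue count, low-coverage
#' flag and the most frequent residue.
#'
#' @param profile a `conservation_profile`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  top <- apply(profile$dist, 2, function(p)
    if (all(is.na(p))) NA_character_ else AA20[which.max(p)])
  df <- data.frame(column = seq_along(profile$S), S = profile$S,
                   gap_fraction = profile$gap_fraction,
                   n_residues = profile$n_residues,
                   low_coverage = profile$low_coverage,
                   top_residue = top)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mask an alignment to the columns present in a reference sequence
#'
#' Keeps exactly the columns where the reference row carries a residue, as
#' when displaying conservation along one protein's own coordinates.
#'
#' @param alignment a `protein_msa`.
#' @param reference_id ID of the reference row.
#' @return a `protein_msa` over the kept columns, with attribute
#'   `"column_map"`: the original column index of each kept column (a
#'   bijection onto the reference residue numbers 1..n).
#' @export
mask_to_reference <- function(alignment, reference_id) {
  if (!(reference_id %in% alignment$ids))
    stop("unknown reference: ", reference_id)
  ref <- strsplit(alignment$rows[[reference_id]], "", fixed = TRUE)[[1]]
  keep <- which(ref != "-")
  rows <- vapply(alignment$rows, function(r)
    paste(strsplit(r, "", fixed = TRUE)[[1]][keep], collapse = ""), "")
  out <- new_msa(alignment$ids, setNames(rows, alignment$ids), alignment$family)
  attr(out, "column_map") <- keep
  out
}

#' Map a reference residue span to alignment columns
#'
#' @param alignment a `protein_msa`.
#' @param reference_id ID of the reference row.
#' @param start,end 1-based inclusive residue coordinates on the ungapped
#'   reference sequence.
#' @return integer vector of alignment columns holding reference residues
#'   `start..end`, in order (length `end - start + 1`).
#' @export
map_reference_span <- function(alignment, reference_id, start, end) {
  if (!(reference_id %in% alignment$ids))
    stop("unknown reference: ", reference_id)
  ref <- strsplit(alignment$rows[[reference_id]], "", fixed = TRUE)[[1]]
  respos <- which(ref != "-")
  if (start < 1 || end > length(respos) || start > end)
    stop("span ", start, "-", end, " outside reference of length ",
         length(respos))
  respos[start:end]
}

#' Degenerate consensus pattern over a column span
#'
#' Per column: if the most frequent residue reaches `t_fix`, a fixed letter;
#' otherwise if the 2 or 3 most frequent residues jointly reach `t_class`, a
#' bracket class (members in descending frequency, alphabetical on ties);
#' otherwise the wildcard `X`. Frequencies are over non-gap residues.
#'
#' @param profile a `conservation_profile`.
#' @param columns column indices to summarize (in order).
#' @param t_fix frequency threshold for a fixed letter, in `[0.5, 1]`.
#' @param t_class joint-frequency threshold for a bracket class
#'   (`>= t_fix`).
#' @return object of class `consensus_pattern`: list with `pattern` (string)
#'   and `positions` (data frame column, rule, residues, frequency).
#' @export
consensus_pattern <- function(profile, columns, t_fix = 0.7, t_class = 0.8) {
  stopifnot(inherits(profile, "conservation_profile"),
            t_fix >= 0.5, t_fix <= 1, t_class >= t_fix)
  if (length(columns) == 0) stop("empty column span")
  parts <- character(length(columns))
  prov <- vector("list", length(columns))
  for (ii in seq_along(columns)) {
    j <- columns[ii]
    p <- profile$dist[, j]
    if (all(is.na(p))) stop("all-gap column ", j, " in consensus span")
    # descending frequency, alphabetical residue on ties
    ord <- order(-p, AA20)
    if (p[ord[1]] >= t_fix) {
      parts[ii] <- AA20[ord[1]]
      prov[[ii]] <- list(rule = "fixed", residues = AA20[ord[1]],
                         frequency = p[ord[1]])
    } else if (sum(p[ord[1:2]]) >= t_class) {
      parts[ii] <- paste0("[", paste(AA20[ord[1:2]], collapse = ""), "]")
      prov[[ii]] <- list(rule = "class", residues = paste(AA20[ord[1:2]],
                                                          collapse = ""),
                         frequency = sum(p[ord[1:2]]))
    } else if (sum(p[ord[1:3]]) >= t_class) {
      parts[ii] <- paste0("[", paste(AA20[ord[1:3]], collapse = ""), "]")
      prov[[ii]] <- list(rule = "class", residues = paste(AA20[ord[1:3]],
                                                          collapse = ""),
                         frequency = sum(p[ord[1:3]]))
    } else {
      parts[ii] <- "X"
      prov[[ii]] <- list(rule = "wildcard", residues = "",
                         frequency = p[ord[1]])
    }
  }
  positions <- data.frame(column = columns,
                          rule = vapply(prov, `[[`, "", "rule"),
                          residues = vapply(prov, `[[`, "", "residues"),
                          frequency = vapply(prov, `[[`, 0, "frequency"))
  structure(list(pattern = paste(parts, collapse = ""), positions = positions,
                 t_fix = t_fix, t_class = t_class),
            class = "consensus_pattern")
}

#' @export
print.consensus_pattern <- function(x, ...) {
  cat(x$pattern, "\n")
  invisible(x)
}

#' Position probability matrix for a sequence logo
#'
#' @param profile a `conservation_profile`.
#' @param span column indices.
#' @return 20 x length(span) matrix of residue probabilities (columns sum
#'   to 1), rows named by residue.
#' @export
logo_matrix <- function(profile, span) {
  stopifnot(inherits(profile, "conservation_profile"),
            all(span >= 1), all(span <= length(profile$S)))
  m <- profile$dist[, span, drop = FALSE]
  rownames(m) <- AA20
  colnames(m) <- as.character(span)
  m
}
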