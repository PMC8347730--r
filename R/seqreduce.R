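#' k-mer set dissimilarity between two protein sequences
#'
#' Distance between the sets of distinct k-mers:
#' `d = 1 - |Ka ∩ Kb| / min(|Ka|, |Kb|)`, a fast alignment-free surrogate for
#' pairwise sequence similarity, in `[0, 1]` and symmetric.
#'
#' @param a,b protein sequence strings.
#' @param k word length (both sequences must be at least `k` residues).
#' @return dissimilarity in `[0, 1]`.
#' @export
kmer_distance <- function(a, b, k = 3) {
  if (nchar(a) < k || nchar(b) < k) stop("sequence shorter than k = ", k)
  ka <- unique(substring(a, 1:(nchar(a) - k + 1), k:nchar(a)))
  kb <- unique(substring(b, 1:(nchar(b) - k + 1), k:nchar(b)))
  1 - length(intersect(ka, kb)) / min(length(ka), length(kb))
}

#' All-pairs k-mer distance matrix for a sequence set
#'
#' Computes [kmer_distance()] for every pair via a sparse sequence-by-k-mer
#' incidence matrix, so thousands of sequences are practical.
#'
#' @param x a `seq_family` or named character vector of sequences.
#' @param k word length.
#' @return symmetric numeric matrix with zero diagonal and ID dimnames.
#' @export
distance_matrix <- function(x, k = 3) {
  seqs <- as_seq_vector(x)
  n <- length(seqs)
  if (n < 2) stop("need at least two sequences")
  if (anyDuplicated(names(seqs))) stop("duplicate sequence IDs")
  if (any(nchar(seqs) < k)) stop("sequence shorter than k = ", k)
  kms <- lapply(seqs, function(s)
    unique(substring(s, 1:(nchar(s) - k + 1), k:nchar(s))))
  sizes <- lengths(kms)
  vocab <- unique(unlist(kms, use.names = FALSE))
  A <- Matrix::sparseMatrix(i = rep.int(seq_len(n), sizes),
                            j = match(unlist(kms, use.names = FALSE), vocab),
                            x = 1, dims = c(n, length(vocab)))
  shared <- as.matrix(Matrix::tcrossprod(A))
  d <- 1 - shared / outer(sizes, sizes, pmin)
  diag(d) <- 0
  dimnames(d) <- list(names(seqs), names(seqs))
  d
}

#' Diversity-preserving reduction of a set to k representatives
#'
#' Sorts all pairwise dissimilarities ascending and visits the list starting
#' from the most similar pairs; from each pair whose members are both still
#' present, one member is removed, until the requested number of
#' representatives remains. The removed member is the one with the smaller
#' total distance to all currently kept sequences (the more central one, so
#' outliers survive and the spread of representatives stays even); ties remove
#' the lexicographically larger ID. Pair visiting order breaks distance ties
#' by the lexicographic ID pair.
#'
#' @param dm symmetric distance matrix with ID dimnames.
#' @param target_size number of representatives to keep (>= 1). If
#'   `target_size >= n` everything is kept.
#' @return object of class `reduction`: list with `kept` (IDs in input order)
#'   and `removed` (data frame id, partner, distance, in removal order).
#' @export
reduce_representatives <- function(dm, target_size) {
  n <- nrow(dm)
  if (is.null(n) || n == 0) stop("empty distance matrix")
  stopifnot(target_size >= 1)
  ids <- rownames(dm)
  alive <- rep(TRUE, n)
  removed <- list()
  if (target_size < n) {
    lexrank <- rank(ids, ties.method = "first")
    tot <- colSums(dm)
    repeat {
      up <- which(upper.tri(dm) & outer(alive, alive, `&`), arr.ind = TRUE)
      i <- up[, 1]; j <- up[, 2]
      # order pairs by (distance, lexicographic id pair)
      r1 <- pmin(lexrank[i], lexrank[j]); r2 <- pmax(lexrank[i], lexrank[j])
      ord <- order(dm[up], r1, r2)
      i <- i[ord]; j <- j[ord]
      exhausted <- TRUE
      for (p in seq_along(i)) {
        a <- i[p]; b <- j[p]
        if (!(alive[a] && alive[b])) next
        # remove the more central member; tie -> lexicographically larger ID
        drop <- if (tot[a] < tot[b]) a
                else if (tot[b] < tot[a]) b
                else if (lexrank[a] > lexrank[b]) a else b
        alive[drop] <- FALSE
        tot <- tot - dm[, drop]
        removed[[length(removed) + 1]] <-
          data.frame(id = ids[drop], partner = ids[if (drop == a) b else a],
                     distance = dm[a, b], stringsAsFactors = FALSE)
        if (sum(alive) == target_size) { exhausted <- FALSE; break }
      }
      if (!exhausted || sum(alive) <= target_size) break
      message("pair list exhausted; recomputing over ", sum(alive), " survivors")
    }
  }
  removed <- if (length(removed)) do.call(rbind, removed) else
    data.frame(id = character(), partner = character(), distance = numeric(),
               stringsAsFactors = FALSE)
  structure(list(kept = ids[alive], removed = removed), class = "reduction")
}

#' @export
print.reduction <- function(x, ...) {
  cat(sprintf("<reduction> kept %d, removed %d\n",
              length(x$kept), nrow(x$removed)))
  invisible(x)
}

#' Select the n sequences nearest to a reference
#'
#' Returns the `n` IDs with the smallest distance to the reference, the
#' reference itself included and counted (its self-distance 0 is minimal).
#' Distance ties are broken lexicographically by ID.
#'
#' @param dm symmetric distance matrix with ID dimnames.
#' @param reference_id the reference sequence ID.
#' @param n number of IDs to return (including the reference).
#' @return character vector of `n` IDs, nearest first.
#' @export
select_nearest <- function(dm, reference_id, n) {
  ids <- rownames(dm)
  if (!(reference_id %in% ids)) stop("unknown reference: ", reference_id)
  stopifnot(n >= 1, n <= length(ids))
  d <- dm[reference_id, ]
  ord <- order(d, ids)
  sel <- ids[ord]
  sel <- c(reference_id, setdiff(sel, reference_id)) # reference always first
  sel[seq_len(n)]
}

#' Merge several (reduced) families into one tagged set
#'
#' Concatenates families while preserving per-record family tags. Colliding
#' IDs are namespaced as `family.id` (with a message).
#'
#' @param families list of `seq_family` objects.
#' @param name name for the merged set.
#' @return a `seq_family` whose `family` field keeps the original tags.
#' @export
merge_families <- function(families, name = "merged") {
  families <- Filter(function(f) length(f$ids) > 0, families)
  ids <- unlist(lapply(families, `[[`, "ids"), use.names = FALSE)
  if (anyDuplicated(ids)) {
    message("ID collisions on merge; namespacing by family")
    ids <- unlist(lapply(families, function(f) paste(f$name, f$ids, sep = ".")),
                  use.names = FALSE)
  }
  seqs <- unlist(lapply(families, function(f) unname(f$seqs)), use.names = FALSE)
  fam <- unlist(lapply(families, `[[`, "family"), use.names = FALSE)
  truth <- do.call(rbind, lapply(families, `[[`, "truth"))
  structure(list(name = name, ids = ids, seqs = setNames(seqs, ids),
                 family = fam, truth = truth),
            class = "seq_family")
}

#' Subset a family to a set of IDs
#'
#' @param fam a `seq_family`.
#' @param ids IDs to keep (e.g. the `kept` field of a [reduce_representatives()]
#'   result); order follows `fam`.
#' @return a `seq_family`.
#' @export
subset_family <- function(fam, ids) {
  keep <- fam$ids %in% ids
  structure(list(name = fam$name, ids = fam$ids[keep],
                 seqs = fam$seqs[keep], family = fam$family[keep],
                 truth = fam$truth[fam$truth$id %in% fam$ids[keep], ,
                                   drop = FALSE]),
            class = "seq_family")
}
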