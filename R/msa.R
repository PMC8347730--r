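#' Neighbor-joining tree from a distance matrix
#'
#' Saitou–Nei neighbor joining (via \pkg{ape}); negative branch lengths are
#' clamped to zero with a message. The two-taxon case yields a single edge of
#' the pairwise distance (split evenly around the internal node).
#'
#' @param dm symmetric distance matrix with ID dimnames, `n >= 2`.
#' @return an unrooted `phylo` tree with non-negative branch lengths.
#' @export
nj_tree <- function(dm) {
  n <- nrow(dm)
  if (is.null(n) || n < 2) stop("need at least two sequences for a tree")
  if (n == 2) {
    d <- dm[1, 2]
    txt <- sprintf("(%s:%.10g,%s:%.10g);", rownames(dm)[1], d / 2,
                   rownames(dm)[2], d / 2)
    return(ape::read.tree(text = txt))
  }
  tr <- ape::nj(stats::as.dist(dm))
  neg <- tr$edge.length < 0
  if (any(neg)) {
    message(sum(neg), " negative branch length(s) clamped to 0")
    tr$edge.length[neg] <- 0
  }
  tr
}

# column frequency profile of an integer alignment matrix (rows = sequences,
# 0 = gap, 1..20 = residues): 21 x n_columns, rows 1..20 residues, row 21 gap.
profile_of <- function(M) {
  nb <- 21L
  f <- vapply(seq_len(ncol(M)), function(j) {
    tb <- tabulate(M[, j] + 1L, nbins = nb)
    c(tb[2:21], tb[1])
  }, numeric(21))
  f / nrow(M)
}

merge_alignments <- function(A, B, gap_open, gap_extend) {
  pa <- profile_of(A)
  pb <- profile_of(B)
  S <- t(pa[1:20, , drop = FALSE]) %*% blosum62() %*% pb[1:20, , drop = FALSE]
  res <- cpp_profile_align(S, gap_open, gap_extend)
  expand <- function(M, idx) {
    out <- matrix(0L, nrow(M), length(idx))
    nz <- idx > 0
    out[, nz] <- M[, idx[nz], drop = FALSE]
    out
  }
  list(m = rbind(expand(A, res$a_idx), expand(B, res$b_idx)),
       score = res$score)
}

#' Progressive multiple alignment along a guide tree
#'
#' Profile–profile progressive alignment: sequences are merged in post-order
#' along a (midpoint-rooted) guide tree; each merge aligns the two column
#' frequency profiles by affine-gap dynamic programming under BLOSUM62, with
#' the profile–profile score being the expected pairwise substitution score
#' (gap frequencies score zero). A gap of length L costs
#' `gap_open + L * gap_extend`.
#'
#' @param x a `seq_family` or named character vector of sequences.
#' @param guide optional `phylo` guide tree whose tips are exactly the
#'   sequence IDs; when `NULL` a neighbor-joining tree on the k-mer distance
#'   matrix is used.
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @param k k-mer size for the default guide-tree distances. Any other
#'   distance matrix (e.g. alignment-derived fractional identity) can be used
#'   by passing its [nj_tree()] as `guide`.
#' @return object of class `protein_msa`: list with `ids`, `rows` (named,
#'   equal-length gapped strings), `family` tags and `n_columns`; the score of
#'   the final profile merge is attached as attribute `"score"`.
#' @export
progressive_align <- function(x, guide = NULL, gap_open = 11, gap_extend = 1,
                              k = 3) {
  seqs <- as_seq_vector(x)
  fams <- seq_families_of(x)
  ids <- names(seqs)
  if (length(seqs) == 1) {
    return(new_msa(ids, setNames(seqs, ids), fams))
  }
  if (is.null(guide)) {
    if (length(seqs) == 2) {
      guide <- nj_tree(matrix(c(0, 1, 1, 0), 2, dimnames = list(ids, ids)))
    } else {
      guide <- nj_tree(distance_matrix(seqs, k = k))
    }
  }
  if (!setequal(guide$tip.label, ids))
    stop("guide tree tips do not match the sequence IDs")
  if (!ape::is.rooted(guide)) guide <- phangorn::midpoint(guide)

  nt <- length(guide$tip.label)
  aligns <- vector("list", nt + guide$Nnode)
  rowids <- vector("list", nt + guide$Nnode)
  for (t in seq_len(nt)) {
    aligns[[t]] <- matrix(encode_seq(seqs[[guide$tip.label[t]]]), nrow = 1)
    rowids[[t]] <- guide$tip.label[t]
  }
  edge <- ape::reorder.phylo(guide, "postorder")$edge
  score <- NA_real_
  for (node in unique(edge[, 1])) {
    children <- edge[edge[, 1] == node, 2]
    cur <- aligns[[children[1]]]
    curids <- rowids[[children[1]]]
    for (ch in children[-1]) {
      mg <- merge_alignments(cur, aligns[[ch]], gap_open, gap_extend)
      cur <- mg$m
      score <- mg$score
      curids <- c(curids, rowids[[ch]])
    }
    aligns[[node]] <- cur
    rowids[[node]] <- curids
  }
  root <- edge[nrow(edge), 1]
  M <- aligns[[root]]
  ordr <- match(ids, rowids[[root]])
  M <- M[ordr, , drop = FALSE]
  stopifnot(!any(colSums(M > 0) == 0)) # no all-gap columns by construction
  rows <- vapply(seq_len(nrow(M)), function(i) {
    ch <- rep("-", ncol(M))
    nz <- M[i, ] > 0
    ch[nz] <- AA20[M[i, nz]]
    paste(ch, collapse = "")
  }, "")
  out <- new_msa(ids, setNames(rows, ids), fams)
  attr(out, "score") <- score
  out
}

new_msa <- function(ids, rows, family = NULL) {
  structure(list(ids = ids, rows = rows,
                 family = family %||% rep(NA_character_, length(ids)),
                 n_columns = if (length(rows)) nchar(rows[[1]]) else 0L),
            class = "protein_msa")
}

#' @export
print.protein_msa <- function(x, ...) {
  cat(sprintf("<protein_msa> %d sequences x %d columns\n",
              length(x$ids), x$n_columns))
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' @param path aligned FASTA; all records must have equal length.
#' @return a `protein_msa`.
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  w <- Biostrings::width(set)
  if (length(unique(w)) > 1) {
    bad <- ids[w != max(w)]
    stop("ragged alignment rows for record(s): ", paste(bad, collapse = ", "))
  }
  new_msa(ids, setNames(as.character(set), ids))
}

#' Write an alignment as aligned FASTA
#'
#' @param alignment a `protein_msa`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  write_fasta(setNames(alignment$rows, alignment$ids), path)
}

# ungapped sequence of one row
ungap_row <- function(alignment, id) {
  gsub("-", "", alignment$rows[[id]], fixed = TRUE)
}

#' Fractional-identity distances from an alignment
#'
#' `1 - identity` over columns where both rows have residues, as an
#' alignment-derived alternative to k-mer distances for tree building.
#'
#' @param alignment a `protein_msa`.
#' @return symmetric distance matrix with ID dimnames; pairs sharing no
#'   residue columns get distance 1.
#' @export
identity_distance <- function(alignment) {
  M <- do.call(rbind, strsplit(alignment$rows, "", fixed = TRUE))
  n <- nrow(M)
  d <- matrix(0, n, n, dimnames = list(alignment$ids, alignment$ids))
  res <- M != "-"
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- res[i, ] & res[j, ]
      nb <- sum(both)
      d[i, j] <- d[j, i] <- if (nb == 0) 1 else
        1 - sum(M[i, both] == M[j, both]) / nb
    }
  }
  d
}
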