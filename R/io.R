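#' Write sequences to FASTA
#'
#' Canonical writer used throughout the package: 60-column wrapping, LF line
#' endings, no trailing blank line, so identical inputs give byte-identical
#' files.
#'
#' @param x a `seq_family`, named character vector or `AAStringSet`.
#' @param path output file.
#' @param width wrap width in residues per line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60) {
  seqs <- as_seq_vector(x)
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con, sep = "\n")
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))),
               con, sep = "\n")
  }
  invisible(path)
}

#' Read a FASTA file as a sequence family
#'
#' @param path FASTA file.
#' @param name family name; defaults to the file name without extension.
#' @return a `seq_family`.
#' @export
read_fasta_family <- function(path, name = NULL) {
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) stop("duplicate sequence IDs in ", path)
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  structure(list(name = name, ids = ids,
                 seqs = setNames(as.character(set), ids),
                 family = rep(name, length(ids)),
                 truth = data.frame(id = character(), family = character(),
                                    motif = integer(), start = integer(),
                                    end = integer(), n_degraded = integer(),
                                    stringsAsFactors = FALSE)),
            class = "seq_family")
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param dm symmetric numeric matrix with IDs as dimnames.
#' @param path output file.
#' @param digits decimal places written.
#' @return `path`, invisibly.
#' @export
write_phylip_dist <- function(dm, path, digits = 6) {
  ids <- rownames(dm)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(dm)), con, sep = "\n")
  fmt <- paste0("%.", digits, "f")
  for (i in seq_len(nrow(dm))) {
    writeLines(paste(c(format(ids[i], width = 10),
                       sprintf(fmt, dm[i, ])), collapse = " "),
               con, sep = "\n")
  }
  invisible(path)
}

#' Read a square PHYLIP distance matrix
#'
#' @param path file written by [write_phylip_dist()] or compatible.
#' @return symmetric numeric matrix with ID dimnames.
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  ids <- character(n)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    ids[i] <- parts[1]
    d[i, ] <- as.numeric(parts[-1])
  }
  dimnames(d) <- list(ids, ids)
  d
}

# flat key=value echo of a configuration list
write_config_echo <- function(config, path) {
  flat <- unlist(config)
  writeLines(paste0(names(flat), "=", as.character(flat)), path)
  invisible(path)
}
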