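#' Read a rooted tree with branch lengths
#'
#' Thin wrapper over \code{ape::read.tree} that enforces the contract the
#' delimitation functions rely on: unique leaf names and non-negative branch
#' lengths (substitutions/site). The tree is used as given; no re-rooting.
#'
#' @param path Newick file.
#' @return An \code{ape} \code{phylo} object.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick file: ", path, call. = FALSE)
  validate_tree(tr)
}

validate_tree <- function(tr) {
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf names in tree", call. = FALSE)
  if (is.null(tr$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  if (anyNA(tr$edge.length) || any(tr$edge.length < 0))
    stop("tree has missing or negative branch lengths", call. = FALSE)
  tr
}

#' Read an aligned FASTA file
#'
#' @param path FASTA file of aligned sequences over \{A,C,G,T,-,N\} (case
#'   insensitive; sequences are uppercased).
#' @return A character matrix (rows = sequences, columns = sites) with
#'   rownames carrying the sequence names.
#' @export
read_fasta <- function(path) {
  seqs <- ape::read.FASTA(path)
  if (length(seqs) == 0L) stop("no sequences in ", path, call. = FALSE)
  chars <- lapply(as.character(seqs), function(s) toupper(s))
  lens <- vapply(chars, length, integer(1))
  if (length(unique(lens)) != 1L)
    stop(sprintf("ragged alignment: sequence lengths %s",
                 paste(unique(lens), collapse = ", ")), call. = FALSE)
  if (anyDuplicated(names(chars)))
    stop("duplicate sequence names", call. = FALSE)
  m <- do.call(rbind, chars)
  rownames(m) <- names(chars)
  m
}

#' @rdname read_fasta
#' @param aln Character matrix alignment (rows = sequences).
#' @export
write_fasta <- function(aln, path) {
  stopifnot(is.matrix(aln), !is.null(rownames(aln)))
  con <- file(path, "w"); on.exit(close(con))
  for (k in seq_len(nrow(aln))) {
    writeLines(paste0(">", rownames(aln)[k]), con)
    writeLines(paste(aln[k, ], collapse = ""), con)
  }
  invisible(path)
}
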