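PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

retained_sites <- function(a, b) {
  ok <- a %in% c(PURINES, PYRIMIDINES) & b %in% c(PURINES, PYRIMIDINES)
  which(ok)
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Sites with a gap or ambiguity (anything outside A, C, G, T) in either
#' sequence are excluded pairwise.
#'
#' @param a,b Character vectors of equal length (one site per element).
#' @return Proportion of differing sites among retained sites.
#' @export
p_distance <- function(a, b) {
  if (length(a) != length(b)) stop("sequences differ in length", call. = FALSE)
  keep <- retained_sites(a, b)
  if (!length(keep)) stop("no retained sites (all gap/ambiguous)", call. = FALSE)
  mean(a[keep] != b[keep])
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' With P the proportion of transition differences (A-G, C-T) and Q the
#' proportion of transversion differences among pairwise-retained sites,
#' \deqn{d = -\tfrac12 \log\left((1-2P-Q)\sqrt{1-2Q}\right).}
#' Saturated pairs (logarithm argument <= 0) raise an error reporting P and Q.
#'
#' @inheritParams p_distance
#' @return Distance in substitutions/site.
#' @export
k2p_distance <- function(a, b) {
  if (length(a) != length(b)) stop("sequences differ in length", call. = FALSE)
  keep <- retained_sites(a, b)
  if (!length(keep)) stop("no retained sites (all gap/ambiguous)", call. = FALSE)
  a <- a[keep]; b <- b[keep]
  diff <- a != b
  ts <- diff & ((a %in% PURINES & b %in% PURINES) |
                  (a %in% PYRIMIDINES & b %in% PYRIMIDINES))
  P <- mean(ts)
  Q <- mean(diff & !ts)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop(sprintf("K2P saturation: log argument <= 0 (P = %.4f, Q = %.4f)", P, Q),
         call. = FALSE)
  -0.5 * log(w1 * sqrt(w2))
}

#' Pairwise distance matrix for an alignment
#'
#' @param aln Character matrix (rows = sequences) as from
#'   \code{\link{read_fasta}}.
#' @param method "p" or "k2p".
#' @return Symmetric matrix with zero diagonal (substitutions/site).
#' @export
alignment_distances <- function(aln, method = c("p", "k2p")) {
  method <- match.arg(method)
  f <- if (method == "p") p_distance else k2p_distance
  n <- nrow(aln)
  m <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n)
    m[i, j] <- m[j, i] <- f(aln[i, ], aln[j, ])
  m
}

#' Patristic distance matrix of a tree
#'
#' Entry (i, j) is the sum of branch lengths on the path between leaves i
#' and j.
#'
#' @param tree A rooted \code{phylo} with branch lengths.
#' @return Symmetric leaf-by-leaf matrix (substitutions/site).
#' @export
patristic_matrix <- function(tree) {
  validate_tree(tree)
  m <- stats::cophenetic(tree)
  m[tree$tip.label, tree$tip.label]
}

#' Mean cross-clade distance
#'
#' @param m Symmetric distance matrix with taxon dimnames.
#' @param partition Named character vector mapping taxon to clade label;
#'   every matrix taxon must be labelled.
#' @param a,b Clade labels.
#' @return Arithmetic mean over all cross-clade entries.
#' @export
clade_mean_distance <- function(m, partition, a, b) {
  taxa <- rownames(m)
  miss <- setdiff(taxa, names(partition))
  if (length(miss))
    stop("unlabelled taxa: ", paste(miss, collapse = ", "), call. = FALSE)
  ta <- taxa[partition[taxa] == a]
  tb <- taxa[partition[taxa] == b]
  if (!length(ta)) stop("empty clade: ", a, call. = FALSE)
  if (!length(tb)) stop("empty clade: ", b, call. = FALSE)
  mean(m[ta, tb, drop = FALSE])
}

#' Distance-based species delimitation
#'
#' Applies the two-criterion rule used for crustacean COI data: a clade pair
#' is \emph{split} into two species iff (i) both clades are monophyletic on
#' the rooted input tree and (ii) their mean cross-clade patristic distance
#' meets the threshold (default 0.16 substitutions/site, a conservative
#' crustacean delimitation threshold); otherwise it is \emph{lumped}. All
#' three facts are reported per pair. If an alignment is supplied, mean
#' cross-clade K2P and p-distances are appended.
#'
#' @param tree Rooted \code{phylo} with branch lengths; no re-rooting is done.
#' @param partition Named vector mapping every leaf to a clade label.
#' @param threshold Patristic distance threshold (subs/site).
#' @param alignment Optional character-matrix alignment over the same leaves.
#' @return Data.frame with one row per unordered clade pair: labels,
#'   monophyly flags, mean patristic distance, decision, and (with an
#'   alignment) mean K2P and p-distance.
#' @export
delimit <- function(tree, partition, threshold = 0.16, alignment = NULL) {
  validate_tree(tree)
  miss <- setdiff(tree$tip.label, names(partition))
  if (length(miss))
    stop("unlabelled leaves: ", paste(miss, collapse = ", "), call. = FALSE)
  labs <- unique(partition[tree$tip.label])
  if (length(labs) < 2L) stop("need >= 2 clade labels", call. = FALSE)
  pat <- patristic_matrix(tree)
  mono <- vapply(labs, function(l) {
    tips <- tree$tip.label[partition[tree$tip.label] == l]
    if (length(tips) == 1L) TRUE else ape::is.monophyletic(tree, tips)
  }, logical(1))
  names(mono) <- labs
  kd <- pd <- NULL
  if (!is.null(alignment)) {
    kd <- alignment_distances(alignment, "k2p")
    pd <- alignment_distances(alignment, "p")
  }
  prs <- utils::combn(labs, 2)
  out <- data.frame(clade_a = prs[1, ], clade_b = prs[2, ],
                    mono_a = mono[prs[1, ]], mono_b = mono[prs[2, ]],
                    mean_patristic = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(alignment)) out$mean_k2p <- out$mean_p <- NA_real_
  for (r in seq_len(ncol(prs))) {
    out$mean_patristic[r] <- clade_mean_distance(pat, partition,
                                                 prs[1, r], prs[2, r])
    if (!is.null(alignment)) {
      out$mean_k2p[r] <- clade_mean_distance(kd, partition, prs[1, r], prs[2, r])
      out$mean_p[r] <- clade_mean_distance(pd, partition, prs[1, r], prs[2, r])
    }
  }
  out$decision <- ifelse(out$mono_a & out$mono_b &
                           out$mean_patristic >= threshold, "split", "lump")
  attr(out, "threshold") <- threshold
  rownames(out) <- NULL
  out
}
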