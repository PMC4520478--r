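K2P_BASES <- c("A", "G", "C", "T")  # 1-2 purines, 3-4 pyrimidines

# one substitution step along a branch of length d (subs/site) under K2P
k2p_evolve <- function(parent, d, kappa) {
  if (d <= 0) return(parent)
  bt <- d / (kappa + 2)          # beta * t
  at <- kappa * d / (kappa + 2)  # alpha * t
  p_ts <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
  p_tv <- 0.25 - 0.25 * exp(-4 * bt)  # each of the two transversions
  partner <- c(2L, 1L, 4L, 3L)
  tv1 <- c(3L, 3L, 1L, 1L)
  tv2 <- c(4L, 4L, 2L, 2L)
  r <- stats::runif(length(parent))
  child <- parent
  m <- r < p_ts
  child[m] <- partner[parent[m]]
  m <- r >= p_ts & r < p_ts + p_tv
  child[m] <- tv1[parent[m]]
  m <- r >= p_ts + p_tv & r < p_ts + 2 * p_tv
  child[m] <- tv2[parent[m]]
  child
}

#' Simulate two-clade sequence divergence under the K2P model
#'
#' Evolves sequences on a symmetric two-clade tree whose between-clade
#' tip-to-tip path length equals \code{target_k2p} substitutions/site, under
#' the Kimura two-parameter process (transition/transversion ratio
#' \code{kappa}). Within-clade tips hang on short terminal branches so the
#' within-clade divergence is much smaller than the between-clade divergence.
#'
#' @param n_per_clade Tips per clade (>= 1).
#' @param seq_len Alignment length in sites (>= 100).
#' @param target_k2p Between-clade path length (subs/site, >= 0; 0 gives
#'   identical sequences).
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param seed Integer seed.
#' @param tip_len Terminal branch length within clades; defaults to
#'   \code{min(0.005, target_k2p/20)}.
#' @return List with \code{alignment} (character matrix, tips
#'   \code{A1..An, B1..Bn}), \code{tree} (\code{phylo}, true tree) and
#'   \code{partition} (named vector mapping tip to clade label).
#' @export
simulate_divergence <- function(n_per_clade = 5, seq_len = 600,
                                target_k2p = 0.16, kappa = 2, seed = 1,
                                tip_len = NULL) {
  stopifnot(n_per_clade >= 1, seq_len >= 100, target_k2p >= 0, kappa > 0)
  if (is.null(tip_len)) tip_len <- min(0.005, target_k2p / 20)
  stem <- (target_k2p - 2 * tip_len) / 2
  if (stem < 0) stop("target_k2p too small for the chosen tip_len", call. = FALSE)
  tipsA <- paste0("A", seq_len(n_per_clade))
  tipsB <- paste0("B", seq_len(n_per_clade))
  mk <- function(tips) paste0(
    if (length(tips) == 1L) sprintf("%s:%.10f", tips, tip_len)
    else sprintf("(%s)", paste(sprintf("%s:%.10f", tips, tip_len), collapse = ",")),
    "")
  nwk <- sprintf("(%s:%.10f,%s:%.10f);", mk(tipsA), stem, mk(tipsB), stem)
  tree <- ape::read.tree(text = nwk)
  aln <- with_substream(seed, "divergence", {
    root <- sample.int(4L, seq_len, replace = TRUE)
    ancA <- k2p_evolve(root, stem, kappa)
    ancB <- k2p_evolve(root, stem, kappa)
    rows <- c(lapply(seq_len(n_per_clade), function(k) k2p_evolve(ancA, tip_len, kappa)),
              lapply(seq_len(n_per_clade), function(k) k2p_evolve(ancB, tip_len, kappa)))
    m <- matrix(K2P_BASES[do.call(rbind, rows)], nrow = 2 * n_per_clade)
    rownames(m) <- c(tipsA, tipsB)
    m
  })
  part <- c(rep("A", n_per_clade), rep("B", n_per_clade))
  names(part) <- c(tipsA, tipsB)
  list(alignment = aln, tree = tree, partition = part)
}
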