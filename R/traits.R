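#' Binary feeding-trait matrix
#'
#' Feeding morphology is scored as binary traits whose derived state is the
#' filtration-associated one (e.g. single-nail maxilliped dactylus, extra
#' setal groups enlarging the filtering basket). Which state counts as
#' filtration is data, not code: the \code{states} matrix must already be
#' coded 1 = filtration-associated state, 0 = predation-associated state.
#'
#' @param states Species x trait matrix or data.frame of 0/1 states
#'   (rownames = species).
#' @return A \code{trait_matrix}.
#' @export
trait_matrix <- function(states) {
  m <- as.matrix(states)
  if (is.null(rownames(m))) stop("rownames must give species", call. = FALSE)
  storage.mode(m) <- "integer"
  if (anyNA(m) || !all(m %in% c(0L, 1L)))
    stop("trait states must be 0/1 with no missing values", call. = FALSE)
  structure(m, class = c("trait_matrix", "matrix"))
}

#' Feeding index of a species
#'
#' The count of traits in the filtration-associated state, ranging from 0
#' (predator) to the number of traits (filtrator; 3 in the amphipod study
#' system).
#'
#' @param traits A \code{\link{trait_matrix}}.
#' @param species Species name (a rowname of \code{traits}).
#' @return Integer index.
#' @export
feeding_index <- function(traits, species) {
  if (!species %in% rownames(traits))
    stop("species not in trait matrix: ", species, call. = FALSE)
  sum(traits[species, ])
}

#' Feeding-axis similarity of a species pair
#'
#' \eqn{1 - |index(a) - index(b)| / T} with T the number of traits, so the
#' most different possible pair scores 0 and identical indices score 1.
#'
#' @inheritParams feeding_index
#' @param a,b Species names.
#' @return Similarity in \{0, 1/T, ..., 1\}.
#' @export
feeding_similarity <- function(traits, a, b) {
  1 - abs(feeding_index(traits, a) - feeding_index(traits, b)) / ncol(traits)
}

#' Epi-hypogean similarity of a species pair
#'
#' Each species' preference is summarized as the proportion of its records
#' from surface habitats among surface + subterranean records (transitional
#' habitats, i.e. springs and sinks, are excluded as uninformative about the
#' gradient); similarity is one minus the absolute difference in
#' proportions.
#'
#' @param occ An \code{\link{occurrence_table}} with habitat types.
#' @param a,b Species names.
#' @return Similarity in [0, 1].
#' @export
epi_similarity <- function(occ, a, b) {
  prop <- function(sp) {
    h <- occ$habitat[occ$species == sp]
    ns <- sum(h == "surface"); nu <- sum(h == "subterranean")
    if (ns + nu == 0L)
      stop("species ", sp, " has no surface or subterranean records", call. = FALSE)
    ns / (ns + nu)
  }
  1 - abs(prop(a) - prop(b))
}

#' Joint three-dimensional niche similarity
#'
#' Combines the three per-axis similarities (feeding, epi-hypogean,
#' bioclimatic Schoener's D), each weighted equally, as the Euclidean
#' magnitude of the similarity vector scaled to [0, 1]:
#' \eqn{\|(s_{feed}, s_{epi}, s_D)\|_2 / \sqrt{3}}. Monotone nondecreasing
#' in every axis and invariant to axis order.
#'
#' @param s_feed,s_epi,s_d Per-axis similarities in [0, 1] (vectorized).
#' @return Joint similarity in [0, 1].
#' @export
joint_similarity <- function(s_feed, s_epi, s_d) {
  v <- cbind(s_feed, s_epi, s_d)
  if (anyNA(v) || any(v < 0) || any(v > 1))
    stop("axis similarities must be in [0, 1]", call. = FALSE)
  sqrt(rowSums(v^2) / 3)
}

#' Per-pair niche axis table
#'
#' Assembles the three-axis similarity triple and the joint similarity for
#' every species pair, in the layout of a per-pair niche report (one row per
#' unordered pair, one joint column per supplied D variant).
#'
#' @param traits A \code{\link{trait_matrix}}.
#' @param occ An \code{\link{occurrence_table}} with habitat types.
#' @param d_values Named list (one element per D variant, e.g. per
#'   correlation threshold) of symmetric species-by-species Schoener's D
#'   matrices, or a single matrix.
#' @param species Species to include; defaults to trait matrix rownames.
#' @return Data.frame with pair, \code{s_feed}, \code{s_epi}, one \code{D_*}
#'   and one \code{joint_*} column per variant.
#' @export
niche_axes_table <- function(traits, occ, d_values, species = rownames(traits)) {
  if (is.matrix(d_values)) d_values <- list(D = d_values)
  prs <- utils::combn(species, 2)
  out <- data.frame(pair = paste(prs[1, ], prs[2, ], sep = "-"),
                    s_feed = NA_real_, s_epi = NA_real_,
                    stringsAsFactors = FALSE)
  for (r in seq_len(ncol(prs))) {
    out$s_feed[r] <- feeding_similarity(traits, prs[1, r], prs[2, r])
    out$s_epi[r] <- epi_similarity(occ, prs[1, r], prs[2, r])
  }
  for (nm in names(d_values)) {
    d <- vapply(seq_len(ncol(prs)),
                function(r) d_values[[nm]][prs[1, r], prs[2, r]], numeric(1))
    out[[paste0("D_", nm)]] <- d
    out[[paste0("joint_", nm)]] <- joint_similarity(out$s_feed, out$s_epi, d)
  }
  out
}
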