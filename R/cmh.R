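#' Build the species x habitat x geology contingency table
#'
#' Each record contributes one count; records with unknown habitat or
#' unknown geology are excluded (their counts are reported as attributes,
#' mirroring field datasets where locality descriptions are uninformative).
#'
#' @param occ An \code{\link{occurrence_table}}.
#' @return A 3-d integer array \code{[species, habitat, geology]} of class
#'   \code{three_way_table} with attributes \code{excluded_habitat} and
#'   \code{excluded_geology}.
#' @export
build_3way <- function(occ) {
  stopifnot(inherits(occ, "occurrence_table"))
  drop_h <- occ$habitat == "unknown"
  drop_g <- !drop_h & occ$geology == "unknown"
  keep <- occ[!(drop_h | drop_g), , drop = FALSE]
  if (!nrow(keep)) stop("no records with known habitat and geology", call. = FALSE)
  tab <- table(species = keep$species,
               habitat = factor(keep$habitat,
                                levels = c("surface", "transitional", "subterranean")),
               geology = factor(keep$geology, levels = c("flysch", "limestone")))
  tab <- unclass(tab)
  # drop strata entirely absent from the data
  present <- apply(tab, 3L, sum) > 0
  tab <- tab[, , present, drop = FALSE]
  structure(tab, class = "three_way_table",
            excluded_habitat = sum(drop_h), excluded_geology = sum(drop_g))
}

# generalized nominal CMH statistic from a list of I x J stratum tables;
# strata with fewer than 2 observations carry no information and are skipped
cmh_from_strata <- function(strata) {
  I <- nrow(strata[[1L]]); J <- ncol(strata[[1L]])
  d <- (I - 1L) * (J - 1L)
  G <- numeric(d)
  V <- matrix(0, d, d)
  used <- 0L
  for (tab in strata) {
    n <- sum(tab)
    if (n < 2) next
    r <- rowSums(tab); cc <- colSums(tab)
    if (all(r == 0) || all(cc == 0)) next
    used <- used + 1L
    E <- outer(r, cc) / n
    u <- as.vector(tab[-I, -J, drop = FALSE]) - as.vector(E[-I, -J, drop = FALSE])
    G <- G + u
    ri <- r[-I]; cj <- cc[-J]
    # Cov(n_ij, n_i'j') under the multiple hypergeometric
    Vr <- (diag(ri, nrow = I - 1L) * n - outer(ri, ri))
    Vc <- (diag(cj, nrow = J - 1L) * n - outer(cj, cj))
    V <- V + kronecker(Vc, Vr) / (n^2 * (n - 1))
  }
  if (used == 0L)
    stop("all strata degenerate: CMH statistic undefined", call. = FALSE)
  singular <- FALSE
  Vi <- tryCatch(solve(V), error = function(e) NULL)
  if (is.null(Vi) || !all(is.finite(Vi))) {
    singular <- TRUE
    Vi <- MASS::ginv(V)
  }
  m2 <- as.numeric(t(G) %*% Vi %*% G)
  structure(m2, df = d, singular = singular)
}

#' Generalized Cochran-Mantel-Haenszel statistic
#'
#' The nominal I x J x K generalization: within each geology stratum the cell
#' counts are compared with their expectations under species-habitat
#' independence conditional on the stratum margins, with the multiple
#' hypergeometric covariance; the quadratic form
#' \eqn{M^2 = G^\top (\sum_k V_k)^{-1} G} over the (I-1)(J-1) free cells is
#' asymptotically chi-squared with (I-1)(J-1) degrees of freedom. A singular
#' covariance falls back to the Moore-Penrose pseudo-inverse (flagged in the
#' \code{singular} attribute).
#'
#' @param t A \code{three_way_table} (or plain 3-d array, strata last).
#' @return \code{M^2} with attributes \code{df} and \code{singular}.
#' @export
cmh_statistic <- function(t) {
  stopifnot(length(dim(t)) == 3L)
  strata <- lapply(seq_len(dim(t)[3L]), function(k) t[, , k])
  cmh_from_strata(strata)
}

#' Permutation p-value for the CMH statistic
#'
#' Because sparse tables make the chi-squared approximation unreliable, the
#' null distribution is generated by randomization: within each stratum the
#' habitat labels are permuted across records while the species labels stay
#' fixed (preserving both sets of stratum margins), and
#' \eqn{p = (1 + \#\{M^2_{perm} \ge M^2_{obs}\})/(n_{perm}+1)}.
#'
#' @param t A \code{three_way_table}.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return A list with \code{statistic}, \code{df}, \code{p_value},
#'   \code{n_perm}.
#' @export
cmh_permutation_p <- function(t, n_perm = 10000, seed = 1) {
  obs <- cmh_statistic(t)
  I <- dim(t)[1L]; J <- dim(t)[2L]; K <- dim(t)[3L]
  # expand each stratum to record-level species/habitat label vectors
  strata_rec <- lapply(seq_len(K), function(k) {
    tab <- t[, , k]
    idx <- which(tab > 0, arr.ind = TRUE)
    n <- tab[idx]
    list(sp = rep(idx[, 1L], n), hab = rep(idx[, 2L], n))
  })
  count <- with_substream(seed, "cmh", {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      perm <- lapply(strata_rec, function(s) {
        if (length(s$hab) < 2L) hab <- s$hab else hab <- sample(s$hab)
        matrix(tabulate(s$sp + I * (hab - 1L), I * J), I, J)
      })
      m2 <- cmh_from_strata(perm)
      if (m2 >= obs - 1e-12) hits <- hits + 1L
    }
    hits
  })
  list(statistic = as.numeric(obs), df = attr(obs, "df"),
       p_value = (1 + count) / (n_perm + 1), n_perm = n_perm)
}
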