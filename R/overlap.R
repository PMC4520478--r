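#' Schoener's D overlap between two normalized suitability maps
#'
#' \deqn{D = 1 - \tfrac12 \sum_c |p_a(c) - p_b(c)|,} ranging from 0 (disjoint
#' potential distributions) to 1 (identical).
#'
#' @param a,b Normalized \code{suitability_map}s on the same grid.
#' @return D in [0, 1].
#' @export
schoener_d <- function(a, b) {
  stopifnot(inherits(a, "suitability_map"), inherits(b, "suitability_map"),
            isTRUE(a$normalized), isTRUE(b$normalized))
  if (!same_grid(a$grid, b$grid)) stop("grid mismatch", call. = FALSE)
  pa <- a$values; pb <- b$values
  pa[is.na(pa)] <- 0; pb[is.na(pb)] <- 0
  1 - 0.5 * sum(abs(pa - pb))
}

#' Niche equivalency randomization test
#'
#' Asks whether the suitability models of two species are more different
#' than expected if their presence cells were drawn from one underlying
#' distribution. The observed D comes from per-species fits; each replicate
#' pools the two presence-cell sets, re-partitions them at random into the
#' original sample sizes, refits both models and records D. The one-tailed
#' p-value for lower-than-null overlap is
#' \eqn{(1 + \#\{D_{null} \le D_{obs}\})/(n_{reps} + 1)}. Replicates whose
#' refit fails to converge are discarded (an error is raised if more than
#' 10\% are lost).
#'
#' @param pres_a,pres_b Two-column presence-cell matrices (>= 3 rows each).
#' @param stack Environmental \code{\link{raster_stack}}.
#' @param variables Layer names used by the models.
#' @param reg L1 penalty passed to \code{\link{fit_maxent_lite}}.
#' @param n_reps Number of randomization replicates (default 100).
#' @param seed Integer seed.
#' @return An \code{overlap_result}: observed \code{D}, \code{null_Ds},
#'   \code{p_value}, \code{n_reps} (retained), \code{n_discarded},
#'   \code{seed}.
#' @export
equivalency_test <- function(pres_a, pres_b, stack, variables, reg = 0.1,
                             n_reps = 100, seed = 1) {
  stopifnot(nrow(pres_a) >= 3L, nrow(pres_b) >= 3L)
  fit_d <- function(pa, pb) {
    ma <- fit_maxent_lite(pa, stack, variables, reg)
    mb <- fit_maxent_lite(pb, stack, variables, reg)
    schoener_d(predict_map(ma, stack), predict_map(mb, stack))
  }
  d_obs <- fit_d(pres_a, pres_b)
  pool <- rbind(pres_a, pres_b)
  na <- nrow(pres_a)
  nulls <- rep(NA_real_, n_reps)
  with_substream(seed, "equivalency", {
    for (r in seq_len(n_reps)) {
      idx <- sample.int(nrow(pool), na)
      nulls[r] <- tryCatch(fit_d(pool[idx, , drop = FALSE],
                                 pool[-idx, , drop = FALSE]),
                           error = function(e) NA_real_)
    }
  })
  discarded <- sum(is.na(nulls))
  if (discarded > 0.1 * n_reps)
    stop(sprintf("%d of %d equivalency replicates failed to converge",
                 discarded, n_reps), call. = FALSE)
  nulls <- nulls[!is.na(nulls)]
  p <- (1 + sum(nulls <= d_obs)) / (length(nulls) + 1)
  structure(list(D = d_obs, null_Ds = nulls, p_value = p,
                 n_reps = length(nulls), n_discarded = discarded, seed = seed),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> D = %.4f, p = %.4f (%d null replicates)\n",
              x$D, x$p_value, x$n_reps))
  invisible(x)
}
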