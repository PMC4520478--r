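#' Sympatry zone of two binary range maps
#'
#' Cell-wise AND of the two predicted ranges: the area where the species come
#' into contact according to their (thresholded) niche-envelope predictions,
#' to which the competition tests are constrained.
#'
#' @param bin_a,bin_b \code{binary_range_map}s on the same grid.
#' @return A \code{sympatry_zone}: grid plus 0/1 cell matrix.
#' @export
sympatry_zone <- function(bin_a, bin_b) {
  stopifnot(inherits(bin_a, "binary_range_map"), inherits(bin_b, "binary_range_map"))
  if (!same_grid(bin_a$grid, bin_b$grid)) stop("grid mismatch", call. = FALSE)
  structure(list(grid = bin_a$grid, cells = bin_a$cells * bin_b$cells),
            class = "sympatry_zone")
}

#' Occupancy counts of a species pair inside a sympatry zone
#'
#' The site universe is every distinct locality in the dataset whose grid
#' cell lies in the zone (restricted to \code{habitat == "transitional"},
#' i.e. springs, when \code{springs_only}). Each site is classified by which
#' of the two focal species occur there: A only, B only, both (syntopy), or
#' neither (the site is occupied only by other focal species — true absences
#' are unobservable in presence-only sampling).
#'
#' @param occ The full \code{\link{occurrence_table}}.
#' @param zone A \code{\link{sympatry_zone}}.
#' @param pair Character vector of the two species names.
#' @param springs_only Restrict the site universe to transitional habitats.
#' @return A \code{cooccurrence_counts} list: \code{n_a_only},
#'   \code{n_b_only}, \code{n_both}, \code{n_neither}, \code{N}.
#' @export
zone_counts <- function(occ, zone, pair, springs_only = FALSE) {
  stopifnot(inherits(zone, "sympatry_zone"), length(pair) == 2L)
  g <- zone$grid
  cells <- cell_of(g, occ$x, occ$y)
  inside <- !is.na(cells[, 1]) & zone$cells[cbind(cells[, 2], cells[, 1])] == 1
  if (springs_only) inside <- inside & occ$habitat == "transitional"
  sub <- occ[inside, , drop = FALSE]
  if (!nrow(sub))
    stop("empty site universe", if (springs_only) " (no transitional sites in zone)",
         call. = FALSE)
  sites <- split(sub$species, sub$locality_id)
  has_a <- vapply(sites, function(s) pair[1] %in% s, logical(1))
  has_b <- vapply(sites, function(s) pair[2] %in% s, logical(1))
  structure(list(n_a_only = sum(has_a & !has_b),
                 n_b_only = sum(!has_a & has_b),
                 n_both = sum(has_a & has_b),
                 n_neither = sum(!has_a & !has_b),
                 N = length(sites), pair = pair),
            class = "cooccurrence_counts")
}

#' @export
print.cooccurrence_counts <- function(x, ...) {
  cat(sprintf("<cooccurrence_counts> %s: A only %d, B only %d, both %d, neither %d (N = %d)\n",
              paste(x$pair, collapse = "-"), x$n_a_only, x$n_b_only,
              x$n_both, x$n_neither, x$N))
  invisible(x)
}

#' Independence null for syntopy frequencies
#'
#' Under no competition the two species occur independently, so with
#' marginal occurrence probabilities \eqn{p_A, p_B} (estimated from the zone
#' counts) the chance of syntopy is the product \eqn{p_A p_B} and the four
#' occupancy categories follow the multinomial null
#' \eqn{(p_A(1-p_B),\,(1-p_A)p_B,\,p_A p_B,\,(1-p_A)(1-p_B))}.
#' A marginal probability of exactly 0 or 1 makes the test degenerate (the
#' corresponding table cell is reported NA downstream).
#'
#' @param counts A \code{\link{zone_counts}} result.
#' @return Named probability 4-vector (a_only, b_only, both, neither) with
#'   attributes \code{p_a}, \code{p_b}, \code{degenerate}.
#' @export
independence_null <- function(counts) {
  stopifnot(inherits(counts, "cooccurrence_counts"), counts$N >= 1)
  p_a <- (counts$n_a_only + counts$n_both) / counts$N
  p_b <- (counts$n_b_only + counts$n_both) / counts$N
  null <- c(a_only = p_a * (1 - p_b), b_only = (1 - p_a) * p_b,
            both = p_a * p_b, neither = (1 - p_a) * (1 - p_b))
  structure(null, p_a = p_a, p_b = p_b,
            degenerate = p_a %in% c(0, 1) || p_b %in% c(0, 1))
}

# all compositions of N into k nonnegative parts, as a (k x n_comp) matrix
# (stars and bars over the k-1 bar positions)
compositions <- function(N, k) {
  if (k == 1L) return(matrix(N, 1L, 1L))
  bars <- utils::combn(N + k - 1L, k - 1L)
  if (!is.matrix(bars)) bars <- matrix(bars, nrow = k - 1L)
  top <- rbind(bars, rep(N + k, ncol(bars)))
  bot <- rbind(rep(0L, ncol(bars)), bars)
  top - bot - 1L
}

n_compositions <- function(N, k) choose(N + k - 1, k - 1)

#' Exact multinomial goodness-of-fit test
#'
#' The probability-ordering two-sided exact test: the p-value is the total
#' null probability of every outcome vector whose multinomial probability is
#' no larger than that of the observed vector (ties included, with relative
#' tolerance 1e-12). All \eqn{\binom{N+k-1}{k-1}} outcomes are enumerated
#' when their number does not exceed \code{mc_cutoff}; beyond that a
#' Monte-Carlo estimate with \code{n_mc} draws and the add-one correction
#' \eqn{(1 + \#\{\le\})/(n_{mc}+1)} is used.
#'
#' @param observed Nonnegative integer k-vector of counts.
#' @param null Probability k-vector summing to 1.
#' @param mc_cutoff Enumeration limit on the number of outcomes.
#' @param n_mc Monte-Carlo sample size.
#' @param seed Integer seed (Monte-Carlo mode only).
#' @return p-value in (0, 1], with attribute \code{method} ("enumeration"
#'   or "monte-carlo").
#' @export
exact_multinomial_test <- function(observed, null, mc_cutoff = 1e6,
                                   n_mc = 1e5, seed = 1) {
  observed <- as.integer(round(observed))
  if (any(observed < 0)) stop("negative counts", call. = FALSE)
  if (length(observed) != length(null) || abs(sum(null) - 1) > 1e-9)
    stop("null must be a probability vector matching `observed`", call. = FALSE)
  N <- sum(observed)
  k <- length(observed)
  logp <- function(m) {
    # column-wise multinomial log-probability; 0 * log(0) = 0
    lg <- lgamma(N + 1) - colSums(lgamma(m + 1))
    lp <- log(null); lp[null == 0] <- 0
    contrib <- m * lp
    contrib[m == 0] <- 0
    bad <- colSums(m[null == 0, , drop = FALSE]) > 0
    out <- lg + colSums(contrib)
    out[bad] <- -Inf
    out
  }
  lp_obs <- logp(matrix(observed))
  if (!is.finite(lp_obs)) stop("observed outcome has zero null probability",
                               call. = FALSE)
  tol <- 1e-12
  if (n_compositions(N, k) <= mc_cutoff) {
    comp <- compositions(N, k)
    lp <- logp(comp)
    p <- sum(exp(lp[lp <= lp_obs + tol]))
    structure(min(p, 1), method = "enumeration")
  } else {
    draws <- with_substream(seed, "emt", stats::rmultinom(n_mc, N, null))
    lp <- logp(draws)
    structure((1 + sum(lp <= lp_obs + tol)) / (n_mc + 1), method = "monte-carlo")
  }
}

#' Run the full co-occurrence competition suite
#'
#' For every species pair, threshold set and restriction level: intersect
#' the two binary range maps into a sympatry zone, classify the zone's
#' localities into the four occupancy categories, form the independence
#' null, and apply the exact multinomial test. Degenerate cells (a marginal
#' occurrence probability of 0 or 1, mirroring pairs for which the
#' probability cannot be estimated) and empty site universes yield NA.
#'
#' @param occ The full \code{\link{occurrence_table}}.
#' @param binary_maps Nested named list: \code{binary_maps[[set]][[species]]}
#'   is a \code{binary_range_map}; one set per threshold variant.
#' @param pairs Two-row character matrix of species pairs (default: all
#'   pairs of species with maps).
#' @param springs_only Logical vector of restriction levels to run.
#' @param global_marginals If TRUE, estimate the marginal occurrence
#'   probabilities from the full dataset rather than within each zone
#'   (the within-zone default matches constraining the whole test to the
#'   contact area); the choice is recorded in the output.
#' @param seed Integer seed (used only if a test falls back to Monte-Carlo).
#' @return Data.frame with one row per pair x set x restriction: counts,
#'   expected counts under the null, and the p-value (NA where degenerate),
#'   with attribute \code{marginals} naming the estimation choice.
#' @export
run_competition_suite <- function(occ, binary_maps, pairs = NULL,
                                  springs_only = c(FALSE, TRUE),
                                  global_marginals = FALSE, seed = 1) {
  sets <- names(binary_maps)
  spp <- names(binary_maps[[1L]])
  if (is.null(pairs)) pairs <- utils::combn(spp, 2)
  rows <- list()
  for (set in sets) for (r in seq_len(ncol(pairs))) for (sp_only in springs_only) {
    a <- pairs[1, r]; b <- pairs[2, r]
    zone <- sympatry_zone(binary_maps[[set]][[a]], binary_maps[[set]][[b]])
    res <- data.frame(pair = paste(a, b, sep = "-"), set = set,
                      springs_only = sp_only, N = NA_integer_,
                      n_a_only = NA_integer_, n_b_only = NA_integer_,
                      n_both = NA_integer_, n_neither = NA_integer_,
                      e_a_only = NA_real_, e_b_only = NA_real_,
                      e_both = NA_real_, e_neither = NA_real_,
                      p_value = NA_real_, stringsAsFactors = FALSE)
    cts <- tryCatch(zone_counts(occ, zone, c(a, b), springs_only = sp_only),
                    error = function(e) NULL)
    if (!is.null(cts)) {
      res$N <- cts$N
      res[c("n_a_only", "n_b_only", "n_both", "n_neither")] <-
        c(cts$n_a_only, cts$n_b_only, cts$n_both, cts$n_neither)
      null <- if (global_marginals) {
        full <- structure(list(
          n_a_only = sum(tapply(occ$species == a, occ$locality_id, any) &
                           !tapply(occ$species == b, occ$locality_id, any)),
          n_b_only = sum(!tapply(occ$species == a, occ$locality_id, any) &
                           tapply(occ$species == b, occ$locality_id, any)),
          n_both = sum(tapply(occ$species == a, occ$locality_id, any) &
                         tapply(occ$species == b, occ$locality_id, any)),
          n_neither = 0L, N = length(unique(occ$locality_id)), pair = c(a, b)),
          class = "cooccurrence_counts")
        full$n_neither <- full$N - full$n_a_only - full$n_b_only - full$n_both
        independence_null(full)
      } else independence_null(cts)
      res[c("e_a_only", "e_b_only", "e_both", "e_neither")] <-
        as.list(cts$N * as.numeric(null))
      if (!attr(null, "degenerate")) {
        obs <- c(cts$n_a_only, cts$n_b_only, cts$n_both, cts$n_neither)
        res$p_value <- as.numeric(exact_multinomial_test(obs, as.numeric(null),
                                                         seed = seed))
      }
    }
    rows[[length(rows) + 1L]] <- res
  }
  out <- do.call(rbind, rows)
  attr(out, "marginals") <- if (global_marginals) "global" else "within-zone"
  rownames(out) <- NULL
  out
}
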