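# cell (i,j) -> position in the column-major [j,i] value matrix
cell_index <- function(grid, cells) (cells[, 1] - 1L) * grid$nrows + cells[, 2]

# Linear + quadratic features, standardized over the background (all
# non-nodata cells). Returns the background feature matrix, the background
# cell positions and the standardization constants needed to reproduce the
# features on any stack.
maxent_features <- function(stack, variables, std = NULL) {
  g <- stack$grid
  miss <- setdiff(variables, names(stack$layers))
  if (length(miss)) stop("variable(s) not in stack: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  vals <- lapply(variables, function(v) as.vector(stack$layers[[v]]))
  bg <- which(!Reduce(`|`, lapply(vals, is.na)))
  if (!length(bg)) stop("no background cells with data", call. = FALSE)
  compute <- is.null(std)
  if (compute) std <- list()
  F <- matrix(0, length(bg), 2L * length(variables))
  fn <- character(2L * length(variables))
  for (k in seq_along(variables)) {
    v <- vals[[k]][bg]
    if (compute) {
      mu <- mean(v); sd1 <- stats::sd(v)
      if (sd1 == 0) sd1 <- 1
      z <- (v - mu) / sd1
      m2 <- mean(z^2); s2 <- stats::sd(z^2)
      if (is.na(s2) || s2 == 0) s2 <- 1
      std[[variables[k]]] <- c(mu = mu, sd = sd1, m2 = m2, s2 = s2)
    }
    s <- std[[variables[k]]]
    z <- (v - s[["mu"]]) / s[["sd"]]
    F[, 2L * k - 1L] <- z
    F[, 2L * k] <- (z^2 - s[["m2"]]) / s[["s2"]]
    fn[2L * k - 1L] <- variables[k]
    fn[2L * k] <- paste0(variables[k], "^2")
  }
  colnames(F) <- fn
  list(F = F, bg = bg, std = std)
}

# negative penalized log-likelihood and its pieces, on the split
# w = u - v (u, v >= 0) used to make the L1 problem smooth and box-bounded
maxent_objective <- function(F, pres_rows, reg) {
  p <- ncol(F)
  fbar <- colMeans(F[pres_rows, , drop = FALSE])
  smooth_grad <- function(w) {
    u <- as.vector(F %*% w); u <- u - max(u)
    e <- exp(u); q <- e / sum(e)
    list(q = q, Eq = as.vector(crossprod(F, q)),
         logZ = log(sum(e)) + 0)
  }
  fn <- function(th) {
    w <- th[1:p] - th[(p + 1):(2 * p)]
    u <- as.vector(F %*% w); mx <- max(u)
    -sum(fbar * w) + mx + log(sum(exp(u - mx))) + reg * sum(th)
  }
  gr <- function(th) {
    w <- th[1:p] - th[(p + 1):(2 * p)]
    sg <- smooth_grad(w)
    g <- sg$Eq - fbar               # d(-loglik)/dw
    c(g + reg, -g + reg)
  }
  list(fn = fn, gr = gr, fbar = fbar, smooth_grad = smooth_grad, p = p)
}

#' Fit a penalized maximum-entropy suitability model
#'
#' A presence-background suitability model in the MaxEnt family, restricted
#' to linear and quadratic features of the standardized environmental
#' variables (the smallest feature class able to represent a Gaussian niche
#' optimum). The fitted cell distribution is
#' \eqn{q(c) \propto \exp(\sum_k w_k f_k(c))} over all non-nodata cells
#' (the full background; no background sampling), with weights maximizing
#' the mean log-probability of the presence cells minus an L1 penalty
#' \eqn{\lambda \sum_k |w_k|}. The concave problem is solved as a
#' box-constrained smooth problem via L-BFGS-B on the positive/negative part
#' split; convergence requires the generalized-gradient max-norm to drop
#' below 1e-6 (at \eqn{\lambda = 0} this is exact moment matching of the
#' feature means to 1e-6).
#'
#' @param presences Two-column matrix of presence cells \code{(i, j)} (or one
#'   element of a \code{presence_cells} object); >= 3 distinct cells with
#'   environmental data.
#' @param stack A \code{\link{raster_stack}}.
#' @param variables Continuous layer names to use.
#' @param reg Penalty \eqn{\lambda} per feature (default 0.1).
#' @param seed Stored in the model metadata (the optimizer itself is
#'   deterministic).
#' @return A \code{maxent_lite} model.
#' @export
fit_maxent_lite <- function(presences, stack, variables, reg = 0.1, seed = 0) {
  stopifnot(is.matrix(presences), ncol(presences) == 2L)
  if (reg < 0) stop("reg must be >= 0", call. = FALSE)
  feats <- maxent_features(stack, variables)
  pidx <- cell_index(stack$grid, presences)
  rows <- match(pidx, feats$bg)
  if (anyNA(rows))
    stop("presence cell(s) on nodata", call. = FALSE)
  if (length(unique(pidx)) < 2L)
    stop("degenerate fit: all presences in a single cell", call. = FALSE)
  if (nrow(presences) < 3L)
    stop("need >= 3 presence cells", call. = FALSE)
  obj <- maxent_objective(feats$F, rows, reg)
  p <- obj$p
  th <- rep(0, 2 * p)
  norm <- Inf
  for (try in 1:5) {
    fit <- stats::optim(th, obj$fn, obj$gr, method = "L-BFGS-B",
                        lower = 0, control = list(maxit = 10000,
                                                  factr = 10, pgtol = 0))
    th <- fit$par
    w <- th[1:p] - th[(p + 1):(2 * p)]
    g <- obj$smooth_grad(w)$Eq - obj$fbar  # smooth part of d(obj)/dw
    norm <- max(ifelse(w > 0, abs(g + reg),
                       ifelse(w < 0, abs(g - reg), pmax(0, abs(g) - reg))))
    if (norm < 1e-6) break
  }
  if (norm >= 1e-6)
    stop(sprintf("maxent fit did not converge: generalized gradient max-norm %.3g",
                 norm), call. = FALSE)
  w <- stats::setNames(w, colnames(feats$F))
  structure(list(variables = variables, weights = w, std = feats$std,
                 reg = reg, presence_cells = presences,
                 n_background = length(feats$bg), seed = seed,
                 grad_norm = norm),
            class = "maxent_lite")
}

#' @export
print.maxent_lite <- function(x, ...) {
  cat(sprintf(
    "<maxent_lite> %d presences, %d background cells, lambda = %g\n",
    nrow(x$presence_cells), x$n_background, x$reg))
  print(round(x$weights, 4))
  invisible(x)
}

#' Predict a normalized suitability map
#'
#' @param model A \code{maxent_lite} model.
#' @param stack A \code{\link{raster_stack}} containing the model's
#'   variables (any layer storage order).
#' @return A \code{suitability_map}: per-cell probabilities summing to 1
#'   over non-nodata cells (\code{NA} at nodata).
#' @export
predict_map <- function(model, stack) {
  stopifnot(inherits(model, "maxent_lite"))
  feats <- maxent_features(stack, model$variables, std = model$std)
  u <- as.vector(feats$F %*% model$weights)
  u <- u - max(u)
  q <- exp(u); q <- q / sum(q)
  g <- stack$grid
  vals <- matrix(NA_real_, g$nrows, g$ncols)
  vals[feats$bg] <- q
  structure(list(grid = g, values = vals, normalized = TRUE),
            class = "suitability_map")
}

#' @export
print.suitability_map <- function(x, ...) {
  cat(sprintf("<suitability_map> %d x %d grid, %s, %d data cells\n",
              x$grid$ncols, x$grid$nrows,
              if (isTRUE(x$normalized)) "normalized" else "raw",
              sum(!is.na(x$values))))
  invisible(x)
}

#' Average several normalized suitability maps
#'
#' Cell-wise mean of maps on a common grid (the mean of probability maps is
#' again a probability map).
#'
#' @param maps List of normalized \code{suitability_map}s.
#' @return A normalized \code{suitability_map}.
#' @export
average_suitability <- function(maps) {
  stopifnot(length(maps) >= 1L)
  g <- maps[[1L]]$grid
  for (m in maps) {
    stopifnot(inherits(m, "suitability_map"), isTRUE(m$normalized))
    if (!same_grid(g, m$grid)) stop("grid mismatch", call. = FALSE)
  }
  vals <- Reduce(`+`, lapply(maps, `[[`, "values")) / length(maps)
  structure(list(grid = g, values = vals, normalized = TRUE),
            class = "suitability_map")
}

#' Train/test splitting of presence cells
#'
#' \code{split_train_test} draws a disjoint, exhaustive random split with
#' \code{round(fraction * n)} training cells. \code{jackknife_splits} returns
#' the n leave-one-out splits used when the sample is too small for a single
#' holdout.
#'
#' @param presences Two-column matrix of presence cells.
#' @param fraction Training fraction (default 0.75).
#' @param seed Integer seed.
#' @return \code{split_train_test}: list with \code{train} and \code{test}
#'   matrices; \code{jackknife_splits}: list of such lists.
#' @export
split_train_test <- function(presences, fraction = 0.75, seed = 1) {
  n <- nrow(presences)
  if (n < 4L)
    stop("need >= 4 presence cells for a holdout split; use jackknife_splits()",
         call. = FALSE)
  n_train <- round(fraction * n)
  idx <- with_substream(seed, "split", sample.int(n, n_train))
  list(train = presences[idx, , drop = FALSE],
       test = presences[-idx, , drop = FALSE])
}

#' @rdname split_train_test
#' @export
jackknife_splits <- function(presences) {
  n <- nrow(presences)
  if (n < 3L) stop("need >= 3 presence cells", call. = FALSE)
  lapply(seq_len(n), function(k)
    list(train = presences[-k, , drop = FALSE],
         test = presences[k, , drop = FALSE]))
}

#' ROC-AUC of a suitability model (exact Mann-Whitney)
#'
#' The probability that a random test presence outscores a random background
#' cell, ties counted 1/2, computed exactly over all pairs via average ranks.
#'
#' @param model A \code{maxent_lite} model.
#' @param stack The environmental \code{\link{raster_stack}}.
#' @param test_presences Two-column matrix of test presence cells.
#' @param background_cells Optional two-column matrix; defaults to all
#'   non-nodata cells.
#' @return AUC in [0, 1].
#' @export
auc <- function(model, stack, test_presences, background_cells = NULL) {
  map <- predict_map(model, stack)
  ps <- map$values[cell_index(stack$grid, test_presences)]
  if (anyNA(ps)) stop("test presence on nodata cell", call. = FALSE)
  bs <- if (is.null(background_cells)) {
    as.vector(map$values[!is.na(map$values)])
  } else map$values[cell_index(stack$grid, background_cells)]
  auc_exact(ps, bs)
}

auc_exact <- function(pres_scores, bg_scores) {
  m <- length(pres_scores); n <- length(bg_scores)
  stopifnot(m >= 1L, n >= 1L)
  r <- rank(c(pres_scores, bg_scores))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Binarize a suitability map by minimum training presence (LPT)
#'
#' The threshold is the lowest predicted suitability over the training
#' presences, so every training presence lies inside the predicted range.
#'
#' @param map A \code{suitability_map}.
#' @param training_presences Two-column matrix of training presence cells
#'   (all on non-nodata cells).
#' @return A \code{binary_range_map}: 0/1 cell matrix (nodata cells 0) with
#'   the threshold recorded.
#' @export
lpt_binary <- function(map, training_presences) {
  stopifnot(inherits(map, "suitability_map"))
  s <- map$values[cell_index(map$grid, training_presences)]
  if (anyNA(s)) stop("training presence on nodata cell", call. = FALSE)
  thr <- min(s)
  cells <- ifelse(!is.na(map$values) & map$values >= thr, 1L, 0L)
  structure(list(grid = map$grid, cells = cells, threshold = thr),
            class = "binary_range_map")
}
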