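#' Clark-Evans nearest-neighbour analysis
#'
#' Classifies a point pattern as clumped, random or evenly dispersed from the
#' ratio of the observed mean nearest-neighbour distance to its expectation
#' under complete spatial randomness:
#' \deqn{\bar r_{exp} = 0.5 / \sqrt{n / A}, \qquad
#'       SE = 0.26136 / \sqrt{n^2 / A},}
#' with \eqn{z = (\bar r_{obs} - \bar r_{exp}) / SE} referred to the
#' standard normal (two-sided). A ratio below 1 indicates clumping, above 1
#' even dispersion. No edge correction is applied; for calibration against
#' CSR the distances can instead be computed on a torus
#' (\code{torus = TRUE}), which removes the edge-effect bias.
#'
#' @param points Two-column matrix of coordinates (km); duplicates allowed
#'   (nearest-neighbour distance 0).
#' @param area Study-area size in the squared coordinate unit (km^2).
#' @param torus Wrap distances on a torus; requires \code{xrange},
#'   \code{yrange}.
#' @param xrange,yrange Domain extents \code{c(min, max)} for torus wrapping.
#' @return An \code{nn_result} list: \code{n}, \code{area}, \code{r_obs},
#'   \code{r_exp}, \code{ratio}, \code{z}, \code{p}.
#' @export
clark_evans <- function(points, area, torus = FALSE, xrange = NULL,
                        yrange = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2L) stop("need >= 2 points", call. = FALSE)
  if (!is.numeric(area) || area <= 0) stop("area must be > 0", call. = FALSE)
  dx <- abs(outer(points[, 1], points[, 1], "-"))
  dy <- abs(outer(points[, 2], points[, 2], "-"))
  if (torus) {
    if (is.null(xrange) || is.null(yrange))
      stop("torus wrapping needs xrange and yrange", call. = FALSE)
    w <- diff(xrange); h <- diff(yrange)
    dx <- pmin(dx, w - dx)
    dy <- pmin(dy, h - dy)
  }
  d <- sqrt(dx^2 + dy^2)
  diag(d) <- Inf
  r_obs <- mean(apply(d, 1L, min))
  r_exp <- 0.5 / sqrt(n / area)
  se <- 0.26136 / sqrt(n^2 / area)
  z <- (r_obs - r_exp) / se
  structure(list(n = n, area = area, r_obs = r_obs, r_exp = r_exp,
                 ratio = r_obs / r_exp, z = z,
                 p = 2 * stats::pnorm(-abs(z))),
            class = "nn_result")
}

#' @export
print.nn_result <- function(x, ...) {
  cat(sprintf("<nn_result> n = %d, ratio = %.3f (obs %.3f / exp %.3f), z = %.3f, p = %.4g\n",
              x$n, x$ratio, x$r_obs, x$r_exp, x$z, x$p))
  invisible(x)
}
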