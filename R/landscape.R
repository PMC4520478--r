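#' Simulate a smooth environmental landscape
#'
#' Builds continuous environmental layers as a linear spatial trend plus a
#' small number of random-phase sinusoids, giving smooth, spatially
#' autocorrelated fields reminiscent of interpolated climate surfaces, and
#' one categorical \code{geology} layer that splits the domain into two
#' contiguous blocks (codes 1 = flysch, 2 = limestone).
#'
#' At \code{roughness = 0} each continuous layer is a pure linear gradient;
#' increasing roughness adds sinusoidal structure of shorter wavelength.
#'
#' @param grid A \code{\link{grid_spec}}.
#' @param n_layers Number of continuous layers (named \code{env1}, ...).
#' @param roughness Scalar in [0, 1].
#' @param seed Integer seed; same seed, same stack.
#' @return A \code{\link{raster_stack}} with \code{n_layers} continuous
#'   layers plus a categorical \code{geology} layer.
#' @export
make_landscape <- function(grid, n_layers = 3, roughness = 0.3, seed = 1) {
  stopifnot(inherits(grid, "grid_spec"), n_layers >= 1,
            roughness >= 0, roughness <= 1)
  with_substream(seed, "landscape", {
    # cell-centre coordinates scaled to [0, 1]
    xs <- (seq_len(grid$ncols) - 0.5) / grid$ncols
    ys <- (seq_len(grid$nrows) - 0.5) / grid$nrows
    X <- matrix(xs, nrow = grid$nrows, ncol = grid$ncols, byrow = TRUE)
    Y <- matrix(ys, nrow = grid$nrows, ncol = grid$ncols)
    layers <- vector("list", n_layers)
    for (k in seq_len(n_layers)) {
      a <- stats::rnorm(2)
      m <- a[1] * X + a[2] * Y
      if (roughness > 0) {
        for (h in 1:3) {
          fx <- stats::runif(1, 0.25, 0.5 + 2.5 * roughness)
          fy <- stats::runif(1, 0.25, 0.5 + 2.5 * roughness)
          ph <- stats::runif(1, 0, 2 * pi)
          amp <- roughness * stats::runif(1, 0.3, 1)
          m <- m + amp * sin(2 * pi * (fx * X + fy * Y) + ph)
        }
      }
      layers[[k]] <- m
    }
    names(layers) <- paste0("env", seq_len(n_layers))
    # geology: split across the longer axis at a random interior line
    geol <- matrix(1, grid$nrows, grid$ncols)
    if (grid$ncols >= grid$nrows) {
      cut <- sample(seq(max(1L, floor(grid$ncols * 0.3)),
                        max(1L, ceiling(grid$ncols * 0.7))), 1L)
      geol[, seq_len(grid$ncols) > cut] <- 2
    } else {
      cut <- sample(seq(max(1L, floor(grid$nrows * 0.3)),
                        max(1L, ceiling(grid$nrows * 0.7))), 1L)
      geol[seq_len(grid$nrows) > cut, ] <- 2
    }
    layers$geology <- geol
    raster_stack(grid, layers, categorical = "geology")
  })
}
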