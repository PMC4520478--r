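#' Define a planar analysis grid
#'
#' The grid convention used throughout the package: planar kilometre
#' coordinates, lower-left origin, cell \code{(i, j)} (column \code{i} counted
#' from the west, row \code{j} from the south, both 1-based) covering the
#' half-open square
#' \eqn{[x_0 + (i-1)c,\; x_0 + ic) \times [y_0 + (j-1)c,\; y_0 + jc)}.
#' A point on a shared edge therefore belongs to exactly one cell.
#'
#' @param x0,y0 Lower-left corner of the grid (km).
#' @param cell Cell side length (km), > 0.
#' @param ncols,nrows Number of columns / rows, >= 1.
#' @return An object of class \code{grid_spec}.
#' @examples
#' g <- grid_spec(0, 0, cell = 3, ncols = 20, nrows = 20)
#' cell_of(g, x = 4.5, y = 0)   # column 2, row 1
#' @export
grid_spec <- function(x0, y0, cell, ncols, nrows) {
  stopifnot(is.numeric(x0), is.numeric(y0), is.finite(x0), is.finite(y0))
  if (!is.numeric(cell) || length(cell) != 1L || cell <= 0)
    stop("`cell` must be a single positive number (km)", call. = FALSE)
  ncols <- as.integer(ncols); nrows <- as.integer(nrows)
  if (ncols < 1L || nrows < 1L)
    stop("`ncols` and `nrows` must be >= 1", call. = FALSE)
  structure(list(x0 = as.numeric(x0), y0 = as.numeric(y0),
                 cell = as.numeric(cell), ncols = ncols, nrows = nrows),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g km, origin (%g, %g)\n",
              x$ncols, x$nrows, x$cell, x$x0, x$y0))
  invisible(x)
}

#' Map points to grid cells
#'
#' Applies the half-open cell rule of \code{\link{grid_spec}}.
#'
#' @param grid A \code{grid_spec}.
#' @param x,y Point coordinates (km), equal length.
#' @return A two-column integer matrix with columns \code{i}, \code{j};
#'   points outside the grid extent yield \code{NA} in both columns.
#' @export
cell_of <- function(grid, x, y) {
  stopifnot(inherits(grid, "grid_spec"), length(x) == length(y))
  i <- floor((x - grid$x0) / grid$cell) + 1
  j <- floor((y - grid$y0) / grid$cell) + 1
  out <- i < 1 | i > grid$ncols | j < 1 | j > grid$nrows
  i[out] <- NA_integer_; j[out] <- NA_integer_
  cbind(i = as.integer(i), j = as.integer(j))
}

same_grid <- function(a, b, tol = 1e-9) {
  abs(a$x0 - b$x0) < tol && abs(a$y0 - b$y0) < tol &&
    abs(a$cell - b$cell) < tol && a$ncols == b$ncols && a$nrows == b$nrows
}

#' Assemble a raster stack
#'
#' A raster stack bundles one or more per-cell layers sharing a single
#' \code{grid_spec}. Layers are matrices indexed \code{[j, i]} (row = grid row
#' from the south, column = grid column from the west); \code{NA} marks
#' nodata. Missing cells must coincide across continuous layers.
#'
#' @param grid A \code{grid_spec}.
#' @param layers Named list of numeric matrices, each \code{nrows x ncols}.
#' @param categorical Character vector naming layers that hold category codes
#'   (excluded from the shared-nodata check and from standardization).
#' @return An object of class \code{raster_stack}.
#' @export
raster_stack <- function(grid, layers, categorical = character()) {
  stopifnot(inherits(grid, "grid_spec"), is.list(layers), length(layers) >= 1L)
  if (is.null(names(layers)) || anyNA(names(layers)) || any(names(layers) == ""))
    stop("all layers must be named", call. = FALSE)
  for (nm in names(layers)) {
    m <- layers[[nm]]
    if (!is.matrix(m) || nrow(m) != grid$nrows || ncol(m) != grid$ncols)
      stop(sprintf("layer '%s' is not a %d x %d matrix", nm, grid$nrows, grid$ncols),
           call. = FALSE)
  }
  cont <- setdiff(names(layers), categorical)
  if (length(cont) > 1L) {
    na0 <- is.na(layers[[cont[1L]]])
    for (nm in cont[-1L])
      if (!identical(na0, is.na(layers[[nm]])))
        stop("nodata cells differ between continuous layers", call. = FALSE)
  }
  structure(list(grid = grid, layers = layers, categorical = categorical),
            class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf("<raster_stack> %d layer(s) [%s] on a %d x %d grid (%g km cells)\n",
              length(x$layers), paste(names(x$layers), collapse = ", "),
              x$grid$ncols, x$grid$nrows, x$grid$cell))
  invisible(x)
}

#' Read / write a single layer in ESRI ASCII grid format
#'
#' The dialect expected is the six-line header (\code{ncols}, \code{nrows},
#' \code{xllcorner}, \code{yllcorner}, \code{cellsize}, \code{NODATA_value})
#' followed by \code{nrows} whitespace-separated rows running from the
#' northern edge. Internally rows are re-ordered so that row 1 is the
#' southern edge, matching the \code{grid_spec} convention;
#' \code{write_ascii_grid} restores the on-disk order, so write then read is
#' an identity.
#'
#' @param path File path.
#' @return \code{read_ascii_grid}: a list with elements \code{grid}
#'   (a \code{grid_spec}) and \code{values} (matrix, \code{NA} = nodata).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 7L) stop("not an ESRI ASCII grid: too few lines", call. = FALSE)
  hdr <- list()
  for (k in 1:6) {
    parts <- strsplit(trimws(lines[k]), "[[:space:]]+")[[1L]]
    if (length(parts) != 2L)
      stop(sprintf("malformed header line %d: '%s'", k, lines[k]), call. = FALSE)
    hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("ESRI ASCII header must contain ", paste(need, collapse = ", "), call. = FALSE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  vals <- suppressWarnings(as.numeric(unlist(
    strsplit(trimws(lines[-(1:6)]), "[[:space:]]+"))))
  if (length(vals) != nc * nr)
    stop(sprintf("expected %d values, found %d", nc * nr, length(vals)), call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA
  m <- m[nr:1, , drop = FALSE]  # row 1 = south
  list(grid = grid_spec(hdr$xllcorner, hdr$yllcorner, hdr$cellsize, nc, nr),
       values = m)
}

#' @rdname read_ascii_grid
#' @param layer List with \code{grid} and \code{values} as returned by
#'   \code{read_ascii_grid}.
#' @param nodata Value written for \code{NA} cells.
#' @export
write_ascii_grid <- function(layer, path, nodata = -9999) {
  g <- layer$grid; m <- layer$values
  stopifnot(inherits(g, "grid_spec"), is.matrix(m),
            nrow(m) == g$nrows, ncol(m) == g$ncols)
  m <- m[g$nrows:1, , drop = FALSE]  # back to north-first
  m[is.na(m)] <- nodata
  hdr <- c(sprintf("ncols %d", g$ncols), sprintf("nrows %d", g$nrows),
           sprintf("xllcorner %.10g", g$x0), sprintf("yllcorner %.10g", g$y0),
           sprintf("cellsize %.10g", g$cell), sprintf("NODATA_value %.10g", nodata))
  body <- apply(m, 1L, function(r) paste(format(r, digits = 15, trim = TRUE,
                                                scientific = FALSE),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
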