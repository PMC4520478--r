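#' Deduplicate occurrence records to grid cells
#'
#' Collapses records to one presence per species per occupied cell using the
#' half-open cell rule, the standard preparation step before
#' presence-background modelling on a coarse analysis grid.
#'
#' @param occ An \code{\link{occurrence_table}}.
#' @param grid A \code{\link{grid_spec}}; all points must fall inside it.
#' @return A \code{presence_cells} object: named list (one element per
#'   species) of two-column integer matrices \code{(i, j)}, with a
#'   \code{counts} attribute giving presences per species. Idempotent.
#' @export
grid_deduplicate <- function(occ, grid) {
  stopifnot(inherits(occ, "occurrence_table"), inherits(grid, "grid_spec"))
  cells <- cell_of(grid, occ$x, occ$y)
  if (anyNA(cells[, 1])) {
    bad <- unique(occ$locality_id[is.na(cells[, 1])])
    stop("point(s) outside grid extent at localities: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- lapply(split(seq_len(nrow(occ)), occ$species), function(idx) {
    m <- cells[idx, , drop = FALSE]
    m <- m[!duplicated(paste(m[, 1], m[, 2])), , drop = FALSE]
    m[order(m[, 1], m[, 2]), , drop = FALSE]
  })
  attr(out, "counts") <- vapply(out, nrow, integer(1))
  class(out) <- "presence_cells"
  out
}

#' @export
print.presence_cells <- function(x, ...) {
  n <- attr(x, "counts")
  cat("<presence_cells>", paste(sprintf("%s: %d", names(n), n), collapse = ", "), "\n")
  invisible(x)
}

#' Prune correlated environmental variables (greedy Spearman scan)
#'
#' Scans variables in a declared keep-order and keeps a variable iff its
#' absolute Spearman rank correlation with every already-kept variable is
#' strictly below the threshold. Rank correlations use average ranks for
#' ties. Constant variables are excluded with a warning (rho undefined).
#' A stricter (smaller) threshold never retains more variables than a looser
#' one. To force a pre-specified subset instead (e.g. a published variable
#' list), pass it as \code{keep}.
#'
#' @param env Data.frame or matrix, localities x variables (>= 2 rows).
#' @param threshold Absolute-correlation threshold in (0, 1].
#' @param order Variable names in scan order; defaults to column order.
#' @param keep Optional explicit character vector overriding the scan.
#' @return Character vector of retained variable names.
#' @export
spearman_prune <- function(env, threshold = 0.7, order = colnames(env),
                           keep = NULL) {
  env <- as.data.frame(env)
  if (nrow(env) < 2L) stop("need >= 2 localities", call. = FALSE)
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]", call. = FALSE)
  if (!is.null(keep)) {
    miss <- setdiff(keep, colnames(env))
    if (length(miss)) stop("unknown variable(s): ", paste(miss, collapse = ", "),
                           call. = FALSE)
    return(keep)
  }
  stopifnot(all(order %in% colnames(env)))
  const <- order[vapply(env[order], function(v) stats::sd(v) == 0, logical(1))]
  if (length(const)) {
    warning("constant variable(s) excluded (Spearman rho undefined): ",
            paste(const, collapse = ", "))
    order <- setdiff(order, const)
  }
  kept <- character()
  for (v in order) {
    if (!length(kept)) { kept <- v; next }
    rho <- abs(stats::cor(env[[v]], env[kept], method = "spearman"))
    if (all(rho < threshold)) kept <- c(kept, v)
  }
  kept
}
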