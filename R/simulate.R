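#' Species niche parameters for the occurrence simulator
#'
#' @param optimum Named numeric vector: the species' optimum for each
#'   environmental layer it responds to (layer units).
#' @param tolerance Named numeric vector, same names: Gaussian niche breadth
#'   per layer (layer units, > 0).
#' @param prevalence Scalar in (0, 1]: retention probability applied to the
#'   generated points (controls how common the species is).
#' @return A \code{niche_params} list.
#' @export
niche_params <- function(optimum, tolerance, prevalence = 1) {
  stopifnot(is.numeric(optimum), is.numeric(tolerance),
            length(optimum) == length(tolerance),
            !is.null(names(optimum)),
            identical(sort(names(optimum)), sort(names(tolerance))))
  if (any(tolerance <= 0)) stop("tolerances must be > 0", call. = FALSE)
  if (prevalence <= 0 || prevalence > 1)
    stop("prevalence must be in (0, 1]", call. = FALSE)
  structure(list(optimum = optimum, tolerance = tolerance[names(optimum)],
                 prevalence = prevalence), class = "niche_params")
}

# Gaussian suitability exp(-sum(((e - opt)/tol)^2)/2) per cell; NA -> 0
gaussian_suitability <- function(stack, params) {
  g <- stack$grid
  s <- matrix(0, g$nrows, g$ncols)
  for (nm in names(params$optimum)) {
    if (!nm %in% names(stack$layers))
      stop("layer '", nm, "' not in stack", call. = FALSE)
    z <- (stack$layers[[nm]] - params$optimum[[nm]]) / params$tolerance[[nm]]
    s <- s + z^2
  }
  out <- exp(-s / 2)
  na <- Reduce(`|`, lapply(stack$layers[setdiff(names(stack$layers),
                                                stack$categorical)], is.na),
               matrix(FALSE, g$nrows, g$ncols))
  out[na] <- 0
  out
}

#' Simulate clumped species occurrences (Thomas cluster process)
#'
#' Parent points are drawn over grid cells with intensity proportional to the
#' Gaussian niche suitability \eqn{\exp(-\sum((e-opt)/tol)^2/2)} and placed
#' uniformly within their cell; each parent spawns a Poisson number of
#' offspring displaced by an isotropic normal kernel. Parents and offspring
#' together form the point set, mimicking the clumped spatial pattern of
#' spring-dwelling amphipod records.
#'
#' Points are snapped to a fine sampling lattice (\code{locality_res} km) that
#' models revisitable field localities: points of different species falling
#' on the same lattice node share a \code{locality_id}, which is what makes
#' syntopy observable downstream; within-species duplicates collapse to one
#' record.
#'
#' @param stack A \code{\link{raster_stack}}.
#' @param params A single \code{\link{niche_params}} or a named list of them
#'   (one per species).
#' @param n_parents Mean number of parent points (per species, recycled).
#' @param offspring_per_parent Mean offspring per parent (recycled).
#' @param spread Isotropic displacement SD in km (recycled).
#' @param seed Integer seed.
#' @param species Species name(s); defaults to the names of \code{params}.
#' @param locality_res Sampling-lattice resolution in km.
#' @return An \code{\link{occurrence_table}} (habitat/geology = "unknown").
#' @export
simulate_occurrences <- function(stack, params, n_parents = 25,
                                 offspring_per_parent = 5, spread = 1,
                                 seed = 1, species = NULL,
                                 locality_res = 0.5) {
  if (inherits(params, "niche_params")) {
    params <- list(params)
    names(params) <- if (is.null(species)) "sp1" else species[1L]
  }
  if (is.null(names(params))) stop("`params` must be a named list", call. = FALSE)
  spp <- names(params)
  n_parents <- rep_len(n_parents, length(spp))
  offspring_per_parent <- rep_len(offspring_per_parent, length(spp))
  spread <- rep_len(spread, length(spp))
  g <- stack$grid
  xmax <- g$x0 + g$ncols * g$cell
  ymax <- g$y0 + g$nrows * g$cell

  rows <- list()
  for (si in seq_along(spp)) {
    sp <- spp[si]
    pts <- with_substream(seed, paste0("occ:", sp), {
      s <- gaussian_suitability(stack, params[[sp]])
      tot <- sum(s)
      if (tot <= 0) stop("zero total suitability for species ", sp, call. = FALSE)
      prob <- as.vector(s) / tot
      idx <- sample.int(length(prob), n_parents[si], replace = TRUE, prob = prob)
      j <- ((idx - 1L) %% g$nrows) + 1L
      i <- ((idx - 1L) %/% g$nrows) + 1L
      px <- g$x0 + (i - 1L + stats::runif(length(i))) * g$cell
      py <- g$y0 + (j - 1L + stats::runif(length(j))) * g$cell
      noff <- stats::rpois(length(px), offspring_per_parent[si])
      ox <- rep(px, noff) + stats::rnorm(sum(noff), 0, spread[si])
      oy <- rep(py, noff) + stats::rnorm(sum(noff), 0, spread[si])
      x <- c(px, ox); y <- c(py, oy)
      keep <- x >= g$x0 & x < xmax & y >= g$y0 & y < ymax
      x <- x[keep]; y <- y[keep]
      pv <- params[[sp]]$prevalence
      if (pv < 1) {
        keep <- stats::runif(length(x)) < pv
        x <- x[keep]; y <- y[keep]
      }
      cbind(x, y)
    })
    if (nrow(pts) == 0L) next
    # snap to sampling lattice; lattice node centre becomes the locality
    li <- floor((pts[, 1] - g$x0) / locality_res)
    lj <- floor((pts[, 2] - g$y0) / locality_res)
    key <- paste(li, lj, sep = "_")
    dup <- duplicated(key)
    rows[[sp]] <- data.frame(
      locality_id = paste0("L", key[!dup]),
      species = sp,
      x = g$x0 + (li[!dup] + 0.5) * locality_res,
      y = g$y0 + (lj[!dup] + 0.5) * locality_res,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no points generated", call. = FALSE)
  occurrence_table(do.call(rbind, rows))
}

#' Inject competitive exclusion at grid-cell scale
#'
#' For every grid cell occupied by both species, with probability
#' \code{gamma} one species (fair coin) loses all its records in that cell —
#' the generator of a "fewer syntopies than chance" signal. \code{gamma = 0}
#' returns the inputs unchanged; \code{gamma = 1} leaves no shared cell.
#'
#' @param a,b \code{occurrence_table}s of the two species.
#' @param grid A \code{\link{grid_spec}}.
#' @param gamma Exclusion probability per shared cell, in [0, 1].
#' @param seed Integer seed.
#' @return A list with thinned tables \code{a} and \code{b}.
#' @export
apply_competitive_thinning <- function(a, b, grid, gamma, seed = 1) {
  stopifnot(gamma >= 0, gamma <= 1)
  if (gamma == 0) return(list(a = a, b = b))
  ca <- cell_of(grid, a$x, a$y)
  cb <- cell_of(grid, b$x, b$y)
  ka <- paste(ca[, 1], ca[, 2]); kb <- paste(cb[, 1], cb[, 2])
  shared <- intersect(unique(ka), unique(kb))
  if (!length(shared)) return(list(a = a, b = b))
  with_substream(seed, "thinning", {
    hit <- shared[stats::runif(length(shared)) < gamma]
    loser_is_a <- stats::runif(length(hit)) < 0.5
    drop_a <- ka %in% hit[loser_is_a]
    drop_b <- kb %in% hit[!loser_is_a]
    list(a = occurrence_table(as.data.frame(a)[!drop_a, , drop = FALSE]),
         b = occurrence_table(as.data.frame(b)[!drop_b, , drop = FALSE]))
  })
}

#' Species-by-geology habitat profiles
#'
#' @param probs A 3-d array \code{[species, geology, habitat]} with
#'   \code{dimnames}: geology in \code{c("flysch", "limestone")}, habitat in
#'   \code{c("surface", "transitional", "subterranean")}. Each probability
#'   vector must sum to 1.
#' @return A \code{habitat_profile}.
#' @export
habitat_profile <- function(probs) {
  stopifnot(is.array(probs), length(dim(probs)) == 3L)
  dn <- dimnames(probs)
  if (is.null(dn) || is.null(dn[[1L]]))
    stop("probs needs dimnames [species, geology, habitat]", call. = FALSE)
  stopifnot(identical(dn[[2L]], c("flysch", "limestone")),
            identical(dn[[3L]], c("surface", "transitional", "subterranean")))
  sums <- apply(probs, c(1, 2), sum)
  if (any(abs(sums - 1) > 1e-12))
    stop("habitat probability vectors must sum to 1", call. = FALSE)
  structure(probs, class = "habitat_profile")
}

#' Assign habitat types and geology to occurrence records
#'
#' Geology is looked up from the categorical geology layer at each record's
#' grid cell (1 = flysch, 2 = limestone); the habitat type is then drawn from
#' the record's species-by-geology probability vector.
#'
#' @param occ An \code{occurrence_table}.
#' @param profile A \code{\link{habitat_profile}} covering all species in
#'   \code{occ}.
#' @param geology_layer Matrix of geology codes on the same grid.
#' @param grid The \code{\link{grid_spec}} of \code{geology_layer}.
#' @param seed Integer seed.
#' @return The table with \code{habitat} and \code{geology} filled in.
#' @export
assign_habitat_types <- function(occ, profile, geology_layer, grid, seed = 1) {
  stopifnot(inherits(occ, "occurrence_table"), inherits(profile, "habitat_profile"))
  spp <- unique(occ$species)
  missing_sp <- setdiff(spp, dimnames(profile)[[1L]])
  if (length(missing_sp))
    stop("species missing from profile: ", paste(missing_sp, collapse = ", "),
         call. = FALSE)
  cells <- cell_of(grid, occ$x, occ$y)
  if (anyNA(cells))
    stop("records outside the geology layer extent", call. = FALSE)
  gcode <- geology_layer[cbind(cells[, 2], cells[, 1])]
  geol <- c("flysch", "limestone")[gcode]
  hab <- character(nrow(occ))
  with_substream(seed, "habitats", {
    for (k in seq_len(nrow(occ))) {
      p <- profile[occ$species[k], geol[k], ]
      hab[k] <- sample(c("surface", "transitional", "subterranean"), 1L, prob = p)
    }
  })
  occ$habitat <- hab
  occ$geology <- geol
  occ
}
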