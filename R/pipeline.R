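#' Build a demo run configuration on synthetic data
#'
#' Writes a complete synthetic study system (occurrences CSV, one ESRI ASCII
#' grid per environmental layer, a geology grid, a trait table) into
#' \code{dir} and returns a validated configuration for
#' \code{\link{run_pipeline}}, sized to run end to end in a few minutes.
#'
#' @param dir Directory for the generated inputs and outputs.
#' @param seed Integer seed.
#' @param gamma Competitive-exclusion strength injected into the synthetic
#'   world (see \code{\link{synth_community}}).
#' @return A configuration list.
#' @export
demo_config <- function(dir = tempfile("nicheclone_demo"), seed = 1,
                        gamma = 0.5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  world <- synth_community(seed = seed, gamma = gamma)
  occ_path <- file.path(dir, "occurrences.csv")
  write_occurrences(world$occ, occ_path)
  layer_paths <- character()
  for (nm in names(world$stack$layers)) {
    p <- file.path(dir, paste0(nm, ".asc"))
    write_ascii_grid(list(grid = world$grid,
                          values = world$stack$layers[[nm]]), p)
    layer_paths[nm] <- p
  }
  traits_path <- file.path(dir, "traits.csv")
  tr <- niphargus_traits()
  utils::write.csv(data.frame(species = rownames(tr), unclass(tr)),
                   traits_path, row.names = FALSE)
  list(occurrences = occ_path,
       layers = as.list(layer_paths),
       categorical = "geology",
       traits = traits_path,
       thresholds = c(0.7, 0.8, 0.9),
       variable_order = setdiff(names(layer_paths), "geology"),
       reg = 0.1,
       train_fraction = 0.75,
       equivalency_reps = 19,
       cmh_permutations = 499,
       seed = seed,
       out_dir = file.path(dir, "out"))
}

validate_config <- function(cfg) {
  need <- c("occurrences", "layers", "traits", "thresholds", "reg",
            "equivalency_reps", "cmh_permutations", "seed", "out_dir")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("config is missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (f in c(cfg$occurrences, unlist(cfg$layers), cfg$traits))
    if (is.character(f) && !file.exists(f))
      stop("config references a missing file: ", f, call. = FALSE)
  if (is.null(cfg$categorical)) cfg$categorical <- character()
  if (is.null(cfg$variable_order))
    cfg$variable_order <- setdiff(names(cfg$layers), cfg$categorical)
  if (is.null(cfg$train_fraction)) cfg$train_fraction <- 0.75
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full niche-reconstruction and co-occurrence pipeline
#'
#' Executes the analysis end to end: grid deduplication, correlation pruning
#' of the environmental variables at each threshold, suitability model fits
#' per species and threshold set with AUC evaluation (holdout split, or
#' jackknife when a species has fewer than 4 presence cells), LPT range
#' maps, Schoener's D and niche equivalency per pair, the
#' species x habitat x geology CMH permutation test, the per-pair niche-axis
#' table with joint similarities, Clark-Evans nearest-neighbour analysis per
#' species, and the co-occurrence competition suite. All report tables are
#' written as CSV into \code{cfg$out_dir} along with the resolved
#' configuration (\code{config_used.yaml}) and a per-stage log; reruns with
#' the same configuration are deterministic.
#'
#' @param cfg Configuration list (see \code{\link{demo_config}}); may be a
#'   path to a YAML file.
#' @return Invisibly, a named list with every report table.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  cfg <- validate_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  occ <- stage("read_occurrences", {
    if (is.character(cfg$occurrences)) read_occurrences(cfg$occurrences)
    else occurrence_table(cfg$occurrences)
  })
  stk <- stage("read_layers", {
    layers <- list()
    grid <- NULL
    for (nm in names(cfg$layers)) {
      l <- read_ascii_grid(cfg$layers[[nm]])
      if (is.null(grid)) grid <- l$grid
      else if (!same_grid(grid, l$grid)) stop("layer grids differ: ", nm)
      layers[[nm]] <- l$values
    }
    raster_stack(grid, layers, categorical = cfg$categorical)
  })
  grid <- stk$grid
  traits <- stage("read_traits", {
    if (is.character(cfg$traits)) {
      df <- utils::read.csv(cfg$traits)
      trait_matrix(`rownames<-`(as.matrix(df[, -1L]), df[[1L]]))
    } else cfg$traits
  })
  note("inputs: %d records, %d species, %d layers", nrow(occ),
       length(unique(occ$species)), length(stk$layers))

  pres <- stage("grid_deduplicate", grid_deduplicate(occ, grid))
  counts <- attr(pres, "counts")
  note("gridded presences: %s",
       paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))

  env_vars <- cfg$variable_order
  env_at_occ <- stage("extract_env", {
    cells <- cell_of(grid, occ$x, occ$y)
    as.data.frame(lapply(stk$layers[env_vars],
                         function(m) m[cbind(cells[, 2], cells[, 1])]))
  })
  pruned <- stage("spearman_prune", {
    lapply(stats::setNames(cfg$thresholds, paste0("t", cfg$thresholds)),
           function(th) spearman_prune(env_at_occ, threshold = th,
                                       order = env_vars))
  })

  spp <- names(pres)
  sdm <- stage("sdm_fits", {
    out <- list()
    for (set in names(pruned)) {
      out[[set]] <- list()
      for (sp in spp) {
        cells <- pres[[sp]]
        fit <- fit_maxent_lite(cells, stk, pruned[[set]], reg = cfg$reg,
                               seed = cfg$seed)
        map <- predict_map(fit, stk)
        if (nrow(cells) >= 4L) {
          sp_split <- split_train_test(cells, cfg$train_fraction,
                                       seed = cfg$seed)
          fit_tr <- fit_maxent_lite(sp_split$train, stk, pruned[[set]],
                                    reg = cfg$reg, seed = cfg$seed)
          a <- auc(fit_tr, stk, sp_split$test)
          method <- "holdout"
        } else {
          a <- mean(vapply(jackknife_splits(cells), function(s) {
            f <- fit_maxent_lite(s$train, stk, pruned[[set]], reg = cfg$reg,
                                 seed = cfg$seed)
            auc(f, stk, s$test)
          }, numeric(1)))
          method <- "jackknife"
        }
        out[[set]][[sp]] <- list(fit = fit, map = map, auc = a,
                                 auc_method = method,
                                 binary = lpt_binary(map, cells))
      }
    }
    out
  })
  auc_tab <- do.call(rbind, lapply(names(sdm), function(set)
    data.frame(set = set, species = spp,
               n_presences = as.integer(counts[spp]),
               auc = vapply(spp, function(sp) sdm[[set]][[sp]]$auc, numeric(1)),
               method = vapply(spp, function(sp) sdm[[set]][[sp]]$auc_method,
                               character(1)))))

  overlap <- stage("niche_overlap", {
    prs <- utils::combn(spp, 2)
    rows <- list()
    d_mats <- list()
    for (set in names(sdm)) {
      dm <- matrix(NA_real_, length(spp), length(spp),
                   dimnames = list(spp, spp))
      for (r in seq_len(ncol(prs))) {
        a <- prs[1, r]; b <- prs[2, r]
        d <- schoener_d(sdm[[set]][[a]]$map, sdm[[set]][[b]]$map)
        dm[a, b] <- dm[b, a] <- d
        eq <- equivalency_test(pres[[a]], pres[[b]], stk, pruned[[set]],
                               reg = cfg$reg, n_reps = cfg$equivalency_reps,
                               seed = cfg$seed + r)
        rows[[length(rows) + 1L]] <- data.frame(
          set = set, pair = paste(a, b, sep = "-"), D = d,
          equivalency_p = eq$p_value, n_reps = eq$n_reps)
      }
      diag(dm) <- 1
      d_mats[[set]] <- dm
    }
    list(table = do.call(rbind, rows), d_mats = d_mats)
  })

  cmh <- stage("habitat_cmh", {
    tab <- build_3way(occ)
    note("CMH exclusions: %d unknown habitat, %d unknown geology",
         attr(tab, "excluded_habitat"), attr(tab, "excluded_geology"))
    cmh_permutation_p(tab, n_perm = cfg$cmh_permutations, seed = cfg$seed)
  })
  cmh_tab <- data.frame(statistic = cmh$statistic, df = cmh$df,
                        p_value = cmh$p_value, n_perm = cmh$n_perm)

  axes <- stage("niche_axes",
                niche_axes_table(traits, occ, overlap$d_mats,
                                 species = intersect(rownames(traits), spp)))

  nn_tab <- stage("clark_evans", {
    area <- sum(!is.na(stk$layers[[env_vars[1]]])) * grid$cell^2
    do.call(rbind, lapply(spp, function(sp) {
      cells <- pres[[sp]]
      if (nrow(cells) < 2L) return(NULL)
      centres <- cbind(grid$x0 + (cells[, 1] - 0.5) * grid$cell,
                       grid$y0 + (cells[, 2] - 0.5) * grid$cell)
      r <- clark_evans(centres, area)
      data.frame(species = sp, n = r$n, area = r$area, ratio = r$ratio,
                 z = r$z, p = r$p)
    }))
  })

  competition <- stage("competition_suite", {
    maps <- lapply(sdm, function(set) lapply(set, `[[`, "binary"))
    run_competition_suite(occ, maps, seed = cfg$seed)
  })

  reports <- list(presence_counts = data.frame(species = names(counts),
                                               n_cells = as.integer(counts)),
                  pruned_variables = data.frame(
                    set = rep(names(pruned), lengths(pruned)),
                    variable = unlist(pruned), row.names = NULL),
                  sdm_auc = auc_tab, niche_overlap = overlap$table,
                  habitat_cmh = cmh_tab, niche_axes = axes,
                  clark_evans = nn_tab, competition = competition)
  for (nm in names(reports))
    utils::write.csv(format(reports[[nm]], digits = 6),
                     file.path(cfg$out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  cfg_out <- cfg
  cfg_out$layers <- as.list(unlist(cfg$layers))
  yaml::write_yaml(cfg_out, file.path(cfg$out_dir, "config_used.yaml"))
  note("competition marginals: %s", attr(competition, "marginals"))
  writeLines(log, file.path(cfg$out_dir, "pipeline_log.txt"))
  invisible(reports)
}
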