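test_that("landscapes are deterministic, smooth, and degenerate to gradients", {
  g <- grid_spec(0, 0, 1, 30, 30)
  s1 <- make_landscape(g, n_layers = 2, roughness = 0.3, seed = 5)
  s2 <- make_landscape(g, n_layers = 2, roughness = 0.3, seed = 5)
  expect_identical(s1, s2)
  expect_false(identical(s1$layers$env1,
                         make_landscape(g, 2, 0.3, seed = 6)$layers$env1))

  # roughness 0: a pure linear gradient has zero second differences
  flat <- make_landscape(g, n_layers = 1, roughness = 0, seed = 3)$layers$env1
  expect_lt(max(abs(diff(t(diff(flat))))), 1e-10)
  expect_lt(max(abs(apply(flat, 1, function(r) max(abs(diff(diff(r))))))), 1e-10)

  # geology layer splits the grid into exactly two contiguous blocks
  geol <- s1$layers$geology
  expect_setequal(unique(as.vector(geol)), c(1, 2))
  expect_true(all(apply(geol, 1, function(r) sum(diff(r) != 0) <= 1)))
})

test_that("landscape layers are spatially autocorrelated at moderate roughness", {
  g <- grid_spec(0, 0, 1, 50, 50)
  ac <- vapply(1:20, function(s) {
    m <- make_landscape(g, n_layers = 1, roughness = 0.3, seed = s)$layers$env1
    stats::cor(as.vector(m[, -1]), as.vector(m[, -ncol(m)]))
  }, numeric(1))
  expect_true(all(ac > 0.5))
})

test_that("occurrence simulation is deterministic and validates downstream", {
  g <- grid_spec(0, 0, 3, 20, 20)
  stk <- make_landscape(g, 1, 0.2, seed = 2)
  prm <- list(A = niche_params(c(env1 = 0), c(env1 = 2)))
  o1 <- simulate_occurrences(stk, prm, seed = 9)
  o2 <- simulate_occurrences(stk, prm, seed = 9)
  expect_identical(o1, o2)
  expect_s3_class(occurrence_table(as.data.frame(o1)), "occurrence_table")
  expect_error(simulate_occurrences(
    raster_stack(g, list(env1 = matrix(NA_real_, 20, 20))), prm, seed = 1),
    "zero total suitability")
})

test_that("wide-niche parents without offspring approximate spatial randomness", {
  g <- grid_spec(0, 0, 3, 20, 20)
  ratios <- vapply(1:50, function(s) {
    stk <- make_landscape(g, 1, 0.2, seed = s)
    occ <- simulate_occurrences(stk, list(A = niche_params(c(env1 = 0),
                                                           c(env1 = 1e6))),
                                n_parents = 150, offspring_per_parent = 0,
                                seed = s, locality_res = 0.25)
    clark_evans(cbind(occ$x, occ$y), 3600, torus = TRUE,
                xrange = c(0, 60), yrange = c(0, 60))$ratio
  }, numeric(1))
  expect_gt(mean(ratios), 0.9)
  expect_lt(mean(ratios), 1.1)
})

test_that("tight offspring clusters produce clumped patterns", {
  g <- grid_spec(0, 0, 3, 20, 20)
  clumped <- vapply(1:50, function(s) {
    stk <- make_landscape(g, 1, 0.2, seed = s)
    occ <- simulate_occurrences(stk, list(A = niche_params(c(env1 = 0),
                                                           c(env1 = 1e6))),
                                n_parents = 25, offspring_per_parent = 5,
                                spread = 0.1, seed = s, locality_res = 0.05)
    clark_evans(cbind(occ$x, occ$y), 3600)$ratio < 1
  }, logical(1))
  expect_gte(mean(clumped), 0.95)
})

test_that("a narrow niche concentrates occurrences near the optimum", {
  g <- grid_spec(0, 0, 1, 40, 40)
  hits <- vapply(1:10, function(s) {
    stk <- make_landscape(g, 1, roughness = 0, seed = s)  # pure gradient
    opt <- stats::median(as.vector(stk$layers$env1))
    tol <- 0.1 * stats::sd(as.vector(stk$layers$env1))
    occ <- simulate_occurrences(stk, list(A = niche_params(c(env1 = opt),
                                                           c(env1 = tol))),
                                n_parents = 200, offspring_per_parent = 0,
                                seed = s)
    cells <- cell_of(g, occ$x, occ$y)
    vals <- stk$layers$env1[cbind(cells[, 2], cells[, 1])]
    abs(mean(vals) - opt) < 0.5 * tol
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("competitive thinning removes shared cells at the requested rate", {
  g <- grid_spec(0, 0, 1, 20, 20)
  # one record of each species in each of 200 cells
  cells <- which(matrix(TRUE, 20, 20))[1:200]
  i <- ((cells - 1) %/% 20) + 1; j <- ((cells - 1) %% 20) + 1
  a <- occ_df(paste0("A", 1:200), "A", i - 0.5, j - 0.5)
  b <- occ_df(paste0("B", 1:200), "B", i - 0.5, j - 0.5)

  th0 <- apply_competitive_thinning(a, b, g, gamma = 0, seed = 1)
  expect_identical(th0$a, a)
  expect_identical(th0$b, b)

  th1 <- apply_competitive_thinning(a, b, g, gamma = 1, seed = 1)
  ca <- paste(cell_of(g, th1$a$x, th1$a$y)[, 1], cell_of(g, th1$a$x, th1$a$y)[, 2])
  cb <- paste(cell_of(g, th1$b$x, th1$b$y)[, 1], cell_of(g, th1$b$x, th1$b$y)[, 2])
  expect_length(intersect(ca, cb), 0)

  th5 <- apply_competitive_thinning(a, b, g, gamma = 0.5, seed = 3)
  shared <- length(intersect(
    paste(cell_of(g, th5$a$x, th5$a$y)[, 1], cell_of(g, th5$a$x, th5$a$y)[, 2]),
    paste(cell_of(g, th5$b$x, th5$b$y)[, 1], cell_of(g, th5$b$x, th5$b$y)[, 2])))
  # Binomial(200, 0.5) band wide enough (99.9%) that only a broken
  # thinning rate can fail a fixed seed
  expect_gte(shared, stats::qbinom(0.0005, 200, 0.5))
  expect_lte(shared, stats::qbinom(0.9995, 200, 0.5))
})

test_that("habitat assignment follows the species-by-geology profile", {
  g <- grid_spec(0, 0, 1, 10, 10)
  geol <- matrix(rep(c(1, 2), each = 50), 10, 10)
  mk_profile <- function(p) {
    probs <- array(rep(p, each = 2), c(1, 2, 3),
                   dimnames = list("A", c("flysch", "limestone"),
                                   c("surface", "transitional", "subterranean")))
    habitat_profile(probs)
  }
  set.seed(1)
  occ <- occ_df(paste0("L", 1:3000), "A", runif(3000, 0, 10), runif(3000, 0, 10))

  conc <- assign_habitat_types(occ, mk_profile(c(0, 1, 0)), geol, g, seed = 2)
  expect_true(all(conc$habitat == "transitional"))
  expect_setequal(unique(conc$geology), c("flysch", "limestone"))

  unif <- assign_habitat_types(occ, mk_profile(rep(1, 3) / 3), geol, g, seed = 2)
  freqs <- table(unif$habitat) / nrow(unif)
  expect_true(all(abs(freqs - 1 / 3) < 0.03))
  expect_identical(unif, assign_habitat_types(occ, mk_profile(rep(1, 3) / 3),
                                              geol, g, seed = 2))
  expect_error(assign_habitat_types(occ_df("L1", "B", 1, 1),
                                    mk_profile(rep(1, 3) / 3), geol, g),
               "species missing from profile: B")
})

test_that("divergent habitat profiles are detected by the CMH permutation test", {
  probs <- array(NA_real_, c(2, 2, 3),
                 dimnames = list(c("A", "B"), c("flysch", "limestone"),
                                 c("surface", "transitional", "subterranean")))
  probs["A", , ] <- rep(c(0.7, 0.2, 0.1), each = 2)
  probs["B", , ] <- rep(c(0.1, 0.2, 0.7), each = 2)
  prof <- habitat_profile(probs)
  g <- grid_spec(0, 0, 1, 10, 10)
  geol <- matrix(rep(c(1, 2), each = 50), 10, 10)
  reject <- vapply(1:20, function(s) {
    set.seed(s + 100)
    occ <- occ_df(paste0("L", 1:200), rep(c("A", "B"), 100),
                  runif(200, 0, 10), runif(200, 0, 10))
    occ <- assign_habitat_types(occ, prof, geol, g, seed = s)
    cmh_permutation_p(build_3way(occ), n_perm = 400, seed = s)$p_value <= 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.9)
})

test_that("simulated divergence hits its target distance and clade structure", {
  d0 <- simulate_divergence(3, 500, target_k2p = 0, seed = 4)
  expect_true(all(apply(d0$alignment, 2, function(col) length(unique(col)) == 1)))

  d <- simulate_divergence(4, 2000, target_k2p = 0.14, kappa = 2, seed = 8)
  km <- alignment_distances(d$alignment, "k2p")
  within <- c(km[1:4, 1:4][upper.tri(diag(4))], km[5:8, 5:8][upper.tri(diag(4))])
  between <- km[1:4, 5:8]
  expect_lt(mean(within), mean(between))

  est <- vapply(1:20, function(s) {
    sim <- simulate_divergence(3, 10000, target_k2p = 0.14, kappa = 2, seed = s)
    clade_mean_distance(alignment_distances(sim$alignment, "k2p"),
                        sim$partition, "A", "B")
  }, numeric(1))
  expect_gte(mean(est), 0.12)
  expect_lte(mean(est), 0.16)
})
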