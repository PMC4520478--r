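make_world <- function(seed = 1, n = 25, roughness = 0.3) {
  g <- grid_spec(0, 0, 1, n, n)
  make_landscape(g, n_layers = 2, roughness = roughness, seed = seed)
}

test_that("unpenalized fits satisfy moment matching (maximum-entropy stationarity)", {
  stk <- make_world(2)
  pres <- sample_presence_cells(stk, opt = 0.3, tol = 0.5, n = 60, seed = 4)
  fit <- fit_maxent_lite(pres, stk, c("env1", "env2"), reg = 0)
  # E_q[f] must equal the presence mean of every feature
  feats <- nicheclone:::maxent_features(stk, c("env1", "env2"))
  map <- predict_map(fit, stk)
  q <- map$values[feats$bg]
  Eq <- as.vector(crossprod(feats$F, q))
  pidx <- match(nicheclone:::cell_index(stk$grid, pres), feats$bg)
  fbar <- colMeans(feats$F[pidx, ])
  expect_lt(max(abs(Eq - fbar)), 1e-4)
})

test_that("the linear weight is recovered on an exponential gradient", {
  stk <- make_world(51)
  v <- as.vector(stk$layers$env1)
  z <- (v - mean(v)) / stats::sd(v)
  beta <- 1.2
  set.seed(6)
  idx <- sample(length(v), 500, replace = TRUE, prob = exp(beta * z))
  cells <- cbind(((idx - 1) %/% 25) + 1, ((idx - 1) %% 25) + 1)
  fit <- fit_maxent_lite(cells, stk, "env1", reg = 0)
  expect_lt(abs(fit$weights[["env1"]] - beta) / beta, 0.15)
})

test_that("strong regularization shrinks the map toward uniform", {
  stk <- make_world(3)
  set.seed(9)
  pres <- cbind(sample(25, 40, TRUE), sample(25, 40, TRUE))
  fit <- fit_maxent_lite(pres, stk, c("env1", "env2"), reg = 50)
  expect_true(all(abs(fit$weights) < 1e-6))
  map <- predict_map(fit, stk)
  expect_lt(max(map$values, na.rm = TRUE) / min(map$values, na.rm = TRUE), 1.1)
})

test_that("predicted maps normalize and ignore layer storage order", {
  stk <- make_world(4)
  pres <- sample_presence_cells(stk, 0, 0.6, 30, seed = 2)
  fit <- fit_maxent_lite(pres, stk, c("env1", "env2"))
  map <- predict_map(fit, stk)
  expect_equal(sum(map$values, na.rm = TRUE), 1, tolerance = 1e-9)

  shuffled <- raster_stack(stk$grid, stk$layers[c("geology", "env2", "env1")],
                           categorical = "geology")
  expect_equal(predict_map(fit, shuffled)$values, map$values)

  flat <- raster_stack(stk$grid, list(env1 = matrix(1, 25, 25) * 0 +
                                        stk$layers$env1 * 0 + 2,
                                      env2 = matrix(2, 25, 25)))
  # constant landscape: every cell identical -> uniform map
  map_flat <- predict_map(fit, flat)
  expect_lt(diff(range(map_flat$values)), 1e-12)
})

test_that("train/test splitting is disjoint, exhaustive and reproducible", {
  pres <- cbind(1:8, 1:8)
  sp <- split_train_test(pres, seed = 5)
  expect_equal(nrow(sp$train), 6L)
  expect_equal(nrow(sp$test), 2L)
  expect_equal(nrow(unique(rbind(sp$train, sp$test))), 8L)
  expect_identical(sp, split_train_test(pres, seed = 5))
  expect_error(split_train_test(pres[1:3, ]), "jackknife")

  jk <- jackknife_splits(pres[1:6, ])
  expect_length(jk, 6L)
  expect_true(all(vapply(jk, function(s) nrow(s$train) == 5L, logical(1))))
})

test_that("AUC is the exact pairwise win rate and is rank-invariant", {
  expect_equal(nicheclone:::auc_exact(c(0.9, 0.8), c(0.1, 0.2)), 1)
  expect_equal(nicheclone:::auc_exact(c(0.5, 0.5), c(0.5, 0.5, 0.5)), 0.5)
  set.seed(8)
  ps <- runif(15); bs <- runif(40)
  brute <- mean(outer(ps, bs, function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(nicheclone:::auc_exact(ps, bs), brute)
  # invariant under a strictly monotone transform of the scores
  expect_equal(nicheclone:::auc_exact(exp(3 * ps), exp(3 * bs)), brute)
})

test_that("LPT thresholding keeps every training presence inside the range", {
  stk <- make_world(7)
  pres <- sample_presence_cells(stk, 0.2, 0.5, 25, seed = 3)
  fit <- fit_maxent_lite(pres, stk, c("env1", "env2"))
  map <- predict_map(fit, stk)
  bin <- lpt_binary(map, pres)
  expect_equal(bin$threshold,
               min(map$values[nicheclone:::cell_index(stk$grid, pres)]))
  expect_true(all(bin$cells[cbind(pres[, 2], pres[, 1])] == 1))

  uniform <- structure(list(grid = stk$grid,
                            values = matrix(1 / 625, 25, 25),
                            normalized = TRUE), class = "suitability_map")
  expect_true(all(lpt_binary(uniform, pres)$cells == 1))
})
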