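binmap <- function(grid, cells) {
  structure(list(grid = grid, cells = cells, threshold = 0),
            class = "binary_range_map")
}

test_that("sympatry zones are cell-wise intersections", {
  g <- grid_spec(0, 0, 1, 5, 5)
  set.seed(2)
  a <- matrix(rbinom(25, 1, 0.5), 5, 5)
  b <- matrix(rbinom(25, 1, 0.5), 5, 5)
  z <- sympatry_zone(binmap(g, a), binmap(g, b))
  expect_equal(sum(z$cells), sum(a == 1 & b == 1))
  expect_equal(sympatry_zone(binmap(g, a), binmap(g, a))$cells, a)
  expect_equal(sum(sympatry_zone(binmap(g, a), binmap(g, 1 - a))$cells), 0)
})

test_that("zone counts classify localities into the four occupancy classes", {
  g <- grid_spec(0, 0, 1, 5, 5)
  z <- sympatry_zone(binmap(g, matrix(1, 5, 5)), binmap(g, matrix(1, 5, 5)))
  occ <- occ_df(c("s1", "s2", "s3", "s3"), c("A", "B", "A", "B"),
                x = c(0.5, 1.5, 2.5, 2.5), y = rep(0.5, 4))
  cts <- zone_counts(occ, z, c("A", "B"))
  expect_equal(unlist(cts[c("n_a_only", "n_b_only", "n_both", "n_neither")]),
               c(n_a_only = 1L, n_b_only = 1L, n_both = 1L, n_neither = 0L))
  expect_equal(cts$N, 3L)
  expect_error(zone_counts(occ, z, c("A", "B"), springs_only = TRUE),
               "no transitional sites")
})

test_that("zone counts equal brute-force classification on a large table", {
  g <- grid_spec(0, 0, 3, 20, 20)
  set.seed(23)
  n <- 500
  occ <- occ_df(paste0("L", sample(200, n, TRUE), "_", seq_len(n)), # unique ids
                sample(c("A", "B", "C"), n, TRUE),
                runif(n, 0, 60), runif(n, 0, 60),
                habitat = sample(c("surface", "transitional"), n, TRUE))
  # merge duplicated (locality, species): regenerate with unique pairs
  zone_cells <- matrix(0L, 20, 20); zone_cells[, 1:10] <- 1L
  z <- sympatry_zone(binmap(g, zone_cells), binmap(g, zone_cells))
  cts <- zone_counts(occ, z, c("A", "B"))
  # independent reimplementation
  ids <- unique(occ$locality_id)
  cls <- c(0, 0, 0, 0)
  for (id in ids) {
    rows <- occ[occ$locality_id == id, ]
    cell <- cell_of(g, rows$x[1], rows$y[1])
    if (zone_cells[cell[1, 2], cell[1, 1]] != 1) next
    a <- "A" %in% rows$species; b <- "B" %in% rows$species
    k <- if (a && b) 3 else if (a) 1 else if (b) 2 else 4
    cls[k] <- cls[k] + 1
  }
  expect_equal(unlist(cts[c("n_a_only", "n_b_only", "n_both", "n_neither")]),
               cls, ignore_attr = TRUE)
})

test_that("the independence null is the product measure of the marginals", {
  cts <- structure(list(n_a_only = 20L, n_b_only = 10L, n_both = 10L,
                        n_neither = 10L, N = 50L, pair = c("A", "B")),
                   class = "cooccurrence_counts")
  nul <- independence_null(cts)
  expect_equal(attr(nul, "p_a"), 0.6)
  expect_equal(attr(nul, "p_b"), 0.4)
  expect_equal(as.numeric(nul), c(0.36, 0.16, 0.24, 0.24))
  expect_equal(sum(nul), 1)
  expect_false(attr(nul, "degenerate"))

  allA <- structure(list(n_a_only = 5L, n_b_only = 0L, n_both = 5L,
                         n_neither = 0L, N = 10L, pair = c("A", "B")),
                    class = "cooccurrence_counts")
  expect_true(attr(independence_null(allA), "degenerate"))

  even <- structure(list(n_a_only = 5L, n_b_only = 5L, n_both = 5L,
                         n_neither = 5L, N = 20L, pair = c("A", "B")),
                    class = "cooccurrence_counts")
  expect_equal(as.numeric(independence_null(even)), rep(0.25, 4))
})

test_that("the exact multinomial test reproduces hand enumerations", {
  expect_equal(as.numeric(exact_multinomial_test(c(2, 0), c(0.5, 0.5))), 0.5)
  expect_equal(as.numeric(exact_multinomial_test(c(2, 0, 0),
                                                 c(0.25, 0.5, 0.25))), 0.125)
  # the modal outcome's p is 1 when everything ties or falls below, and the
  # p-value always covers at least the observed outcome's own probability
  expect_equal(as.numeric(exact_multinomial_test(c(1, 1), c(0.5, 0.5))), 1)
  p <- as.numeric(exact_multinomial_test(c(3, 1), c(0.75, 0.25)))
  expect_gte(p, stats::dmultinom(c(3, 1), prob = c(0.75, 0.25)))
})

test_that("enumeration equals brute force for all N <= 8, k <= 4", {
  set.seed(25)
  for (r in 1:100) {
    k <- sample(2:4, 1)
    N <- sample(1:8, 1)
    nul <- as.numeric(stats::rgamma(k, 1) + 0.05)
    nul <- nul / sum(nul)
    obs <- as.vector(stats::rmultinom(1, N, nul))
    mine <- as.numeric(exact_multinomial_test(obs, nul))
    expect_equal(mine, brute_emt(obs, nul), tolerance = 1e-12)
  }
})

test_that("Monte-Carlo mode agrees with enumeration within sampling error", {
  set.seed(26)
  nul <- c(0.4, 0.3, 0.2, 0.1)
  obs <- as.vector(stats::rmultinom(1, 30, c(0.25, 0.25, 0.25, 0.25)))
  exact <- as.numeric(exact_multinomial_test(obs, nul))
  mc <- as.numeric(exact_multinomial_test(obs, nul, mc_cutoff = 1, n_mc = 4e4,
                                          seed = 3))
  expect_equal(attr(exact_multinomial_test(obs, nul), "method"), "enumeration")
  se <- sqrt(exact * (1 - exact) / 4e4)
  expect_lt(abs(mc - exact), 3 * se + 1e-4)
})

test_that("the suite marks degenerate cells NA and fills the rest", {
  g <- grid_spec(0, 0, 1, 4, 4)
  full <- binmap(g, matrix(1L, 4, 4))
  # B present at every locality -> p_B = 1 -> NA cell
  occ <- occ_df(c("s1", "s2", "s3", "s4", "s4"),
                c("B", "B", "B", "A", "B"),
                x = c(0.5, 1.5, 2.5, 0.5, 0.5),
                y = c(0.5, 0.5, 0.5, 1.5, 1.5),
                habitat = "transitional")
  res <- run_competition_suite(occ, list(set1 = list(A = full, B = full)),
                               springs_only = FALSE)
  expect_equal(nrow(res), 1L)
  expect_true(is.na(res$p_value))
  expect_equal(res$N, 4L)
  expect_equal(attr(res, "marginals"), "within-zone")
})
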