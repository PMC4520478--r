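# Shared fixture builders. Everything is generated in code at test time.

# presence cells drawn iid over a stack's cells with Gaussian weight around
# `opt` on env1 (with replacement: keeps the pooled set exchangeable, which
# the equivalency permutation null assumes)
sample_presence_cells <- function(stack, opt, tol, n, seed) {
  g <- stack$grid
  v <- as.vector(stack$layers$env1)
  set.seed(seed)
  idx <- sample(length(v), n, replace = TRUE, prob = exp(-((v - opt) / tol)^2 / 2))
  cbind(((idx - 1L) %/% g$nrows) + 1L, ((idx - 1L) %% g$nrows) + 1L)
}

# one equivalency-test replicate: two species with optima `sep` tolerances
# apart (sep = 0: identical niches), n = 50 presence cells each, 99 reps
equivalency_rep <- function(seed, sep, n_reps = 99) {
  g <- grid_spec(0, 0, 1, 20, 20)
  stk <- make_landscape(g, n_layers = 1, roughness = 0.3, seed = seed)
  tol <- 0.4
  mid <- stats::median(as.vector(stk$layers$env1))
  pa <- sample_presence_cells(stk, mid - sep * tol / 2, tol, 50, seed * 7 + 1)
  pb <- sample_presence_cells(stk, mid + sep * tol / 2, tol, 50, seed * 7 + 2)
  equivalency_test(pa, pb, stk, "env1", reg = 0.1, n_reps = n_reps,
                   seed = seed)$p_value
}

# one competition-suite replicate: a 4-species community (test pair A, B plus
# two widespread filler species supplying "neither" sites), localities at the
# analysis cell scale, zone = whole grid; returns the pair's exact
# multinomial p and the zone site count
competition_rep <- function(seed, gamma) {
  g <- grid_spec(0, 0, 3, 20, 20)
  stk <- make_landscape(g, n_layers = 1, roughness = 0.2, seed = seed)
  prm <- list(A = niche_params(c(env1 = 0), c(env1 = 5)),
              B = niche_params(c(env1 = 0), c(env1 = 5)),
              C = niche_params(c(env1 = 0), c(env1 = 5)),
              D = niche_params(c(env1 = 0), c(env1 = 5)))
  occ <- simulate_occurrences(stk, prm, n_parents = c(20, 20, 40, 40),
                              offspring_per_parent = 3, spread = 2,
                              seed = seed, locality_res = 3)
  sp <- split(seq_len(nrow(occ)), occ$species)
  a <- occurrence_table(as.data.frame(occ)[sp$A, ])
  b <- occurrence_table(as.data.frame(occ)[sp$B, ])
  if (gamma > 0) {
    th <- apply_competitive_thinning(a, b, g, gamma, seed = seed)
    a <- th$a; b <- th$b
  }
  occ2 <- occurrence_table(rbind(as.data.frame(a), as.data.frame(b),
                                 as.data.frame(occ)[c(sp$C, sp$D), ]))
  allmap <- structure(list(grid = g, cells = matrix(1L, g$nrows, g$ncols),
                           threshold = 0), class = "binary_range_map")
  zone <- sympatry_zone(allmap, allmap)
  cts <- zone_counts(occ2, zone, c("A", "B"))
  nul <- independence_null(cts)
  if (attr(nul, "degenerate")) return(c(p = NA_real_, N = cts$N))
  p <- exact_multinomial_test(c(cts$n_a_only, cts$n_b_only, cts$n_both,
                                cts$n_neither), as.numeric(nul))
  c(p = as.numeric(p), N = cts$N)
}

# independent brute-force exact multinomial p: enumerate outcomes with
# expand.grid + dmultinom (a different code path from the implementation)
brute_emt <- function(observed, null) {
  k <- length(observed); N <- sum(observed)
  grids <- rep(list(0:N), k - 1L)
  m <- as.matrix(do.call(expand.grid, grids))
  last <- N - rowSums(m)
  m <- cbind(m[last >= 0, , drop = FALSE], last[last >= 0])
  probs <- apply(m, 1L, function(x) stats::dmultinom(x, prob = null))
  p_obs <- stats::dmultinom(observed, prob = null)
  sum(probs[probs <= p_obs * (1 + 1e-12)])
}

# independent patristic distance: breadth-first path search on the edge list
brute_patristic <- function(tree) {
  n <- length(tree$tip.label)
  nodes <- max(tree$edge)
  adj <- vector("list", nodes)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]; w <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  dist_from <- function(src) {
    d <- rep(NA_real_, nodes); d[src] <- 0
    queue <- src
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (r in seq_len(NROW(adj[[v]]))) {
        u <- adj[[v]][r, 1]
        if (is.na(d[u])) { d[u] <- d[v] + adj[[v]][r, 2]; queue <- c(queue, u) }
      }
    }
    d
  }
  out <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) out[i, ] <- dist_from(i)[seq_len(n)]
  out
}

# small helper: an occurrence table from bare vectors
occ_df <- function(locality_id, species, x, y,
                   habitat = "unknown", geology = "unknown") {
  occurrence_table(data.frame(locality_id = locality_id, species = species,
                              x = x, y = y, habitat = habitat,
                              geology = geology, stringsAsFactors = FALSE))
}
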