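test_that("p-distance and K2P match their closed forms", {
  ten <- strsplit("ACGTACGTAC", "")[[1]]
  expect_equal(p_distance(ten, ten), 0)
  expect_equal(p_distance(ten, strsplit("ACGTACGTGC", "")[[1]]), 0.1)

  # P = 0.1, Q = 0: d = -log(0.8)/2
  a <- rep("A", 10); b <- c("G", rep("A", 9))
  expect_equal(k2p_distance(a, b), -0.5 * log(0.8), tolerance = 1e-12)
  expect_equal(k2p_distance(a, a), 0)

  # P = Q = 0.25 is still inside the domain; P = 0.5, Q = 0 saturates
  ab <- rep(c("A"), 4)
  pq <- c("G", "C", rep("A", 2))          # 1 transition + 1 transversion in 4
  expect_silent(k2p_distance(ab, pq))
  sat <- c(rep("G", 5), rep("A", 5))      # P = 0.5, Q = 0
  expect_error(k2p_distance(rep("A", 10), sat), "saturation.*P = 0.5")
})

test_that("gap and ambiguity sites are excluded pairwise", {
  a <- c("A", "-", "C", "N", "T")
  b <- c("A", "C", "C", "G", "A")
  # retained: positions 1, 3, 5 -> one difference in three
  expect_equal(p_distance(a, b), 1 / 3)
  expect_error(p_distance(c("-", "N"), c("A", "C")), "no retained sites")
})

test_that("K2P dominates p-distance and matches an independent implementation", {
  set.seed(21)
  for (r in 1:20) {
    sim <- simulate_divergence(2, 1000, target_k2p = runif(1, 0.02, 0.3),
                               kappa = runif(1, 1, 4), seed = r)
    aln <- sim$alignment
    prs <- utils::combn(nrow(aln), 2)
    for (c_ in seq_len(ncol(prs))) {
      i <- prs[1, c_]; j <- prs[2, c_]
      expect_gte(k2p_distance(aln[i, ], aln[j, ]) + 1e-12,
                 p_distance(aln[i, ], aln[j, ]))
    }
    # cross-check against ape's distance engine
    bin <- ape::as.DNAbin(aln)
    expect_equal(as.matrix(ape::dist.dna(bin, model = "K80",
                                         pairwise.deletion = TRUE)),
                 alignment_distances(aln, "k2p"), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(as.matrix(ape::dist.dna(bin, model = "raw",
                                         pairwise.deletion = TRUE)),
                 alignment_distances(aln, "p"), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("patristic distances are additive path sums", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  pm <- patristic_matrix(tr)
  expect_equal(pm["A", "B"], 2)
  expect_equal(pm["A", "C"], 4)
  expect_equal(pm["B", "C"], 4)

  star <- ape::read.tree(text = "(A:1.5,B:1.5,C:1.5,D:1.5);")
  ps <- patristic_matrix(star)
  expect_true(all(ps[upper.tri(ps)] == 3))

  set.seed(31)
  rnd <- ape::rtree(12)
  expect_equal(patristic_matrix(rnd), brute_patristic(rnd), tolerance = 1e-9)
})

test_that("additive trees satisfy the four-point condition", {
  set.seed(5)
  for (r in 1:5) {
    tr <- ape::rtree(8)
    d <- patristic_matrix(tr)
    q <- utils::combn(8, 4)
    for (c_ in seq_len(ncol(q))) {
      s <- q[, c_]
      sums <- sort(c(d[s[1], s[2]] + d[s[3], s[4]],
                     d[s[1], s[3]] + d[s[2], s[4]],
                     d[s[1], s[4]] + d[s[2], s[3]]))
      expect_lt(sums[3] - sums[2], 1e-9)
    }
  }
})

test_that("clade mean distance equals the brute-force double loop", {
  m <- matrix(1, 3, 3); diag(m) <- 0
  dimnames(m) <- list(letters[1:3], letters[1:3])
  part <- c(a = "X", b = "Y", c = "Y")
  expect_equal(clade_mean_distance(m, part, "X", "Y"), 1)

  set.seed(13)
  taxa <- paste0("t", 1:8)
  rm_ <- matrix(0, 8, 8, dimnames = list(taxa, taxa))
  rm_[upper.tri(rm_)] <- runif(28)
  rm_ <- rm_ + t(rm_)
  part8 <- stats::setNames(rep(c("X", "Y"), c(3, 5)), taxa)
  acc <- 0; n <- 0
  for (i in taxa[1:3]) for (j in taxa[4:8]) { acc <- acc + rm_[i, j]; n <- n + 1 }
  expect_equal(clade_mean_distance(rm_, part8, "X", "Y"), acc / n)
  expect_error(clade_mean_distance(rm_, part8, "X", "Z"), "empty clade")
})

test_that("delimitation combines monophyly with the distance threshold", {
  # mean cross-clade patristic 0.34: split at the 0.16 threshold
  tr <- ape::read.tree(text = "((A1:0.01,A2:0.01):0.16,(B1:0.01,B2:0.01):0.16);")
  part <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B")
  res <- delimit(tr, part)
  expect_equal(res$mean_patristic, 0.34)
  expect_equal(res$decision, "split")

  shallow <- ape::read.tree(text = "((A1:0.01,A2:0.01):0.04,(B1:0.01,B2:0.01):0.04);")
  expect_equal(delimit(shallow, part)$decision, "lump")

  # deep but non-monophyletic labelling: lumped with the flag reported
  mixed <- c(A1 = "A", A2 = "B", B1 = "B", B2 = "A")
  res2 <- delimit(tr, mixed)
  expect_false(res2$mono_a && res2$mono_b)
  expect_equal(res2$decision, "lump")
})

test_that("delimitation on estimated trees recovers the simulated decision", {
  run <- function(target) vapply(1:20, function(s) {
    sim <- simulate_divergence(4, 1500, target_k2p = target, seed = s)
    km <- alignment_distances(sim$alignment, "k2p")
    est_tree <- phangorn::upgma(stats::as.dist(km))
    delimit(est_tree, sim$partition)$decision
  }, character(1))
  expect_gte(mean(run(0.34) == "split"), 0.95)
  expect_gte(mean(run(0.05) == "lump"), 0.95)
})
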