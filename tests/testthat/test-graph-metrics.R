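test_that("weighted clustering handles canonical graphs", {
  k4 <- matrix(1, 4, 4); diag(k4) <- 0
  expect_equal(as.numeric(weighted_clustering(k4)), 1)

  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  expect_equal(as.numeric(weighted_clustering(star)), 0)

  empty <- matrix(0, 4, 4)
  expect_equal(as.numeric(weighted_clustering(empty)), 0)
})

test_that("clustering and path length match brute-force oracles on random graphs", {
  for (s in 1:25) {
    n <- sample(8:15, 1)
    w <- random_weight_matrix(n, density = runif(1, 0.3, 0.8), seed = 1000 + s)
    if (sum(w > 0) < 4) next
    expect_equal(as.numeric(weighted_clustering(w)),
                 brute_clustering_onnela(w), tolerance = 1e-10)
    expect_equal(as.numeric(char_path_length(w)),
                 brute_path_length(w), tolerance = 1e-10)
  }
})

test_that("path length follows closed forms and the inverse-weight scale law", {
  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- 1
  path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(as.numeric(char_path_length(path3)), 4 / 3)

  k5 <- matrix(1, 5, 5); diag(k5) <- 0
  expect_equal(as.numeric(char_path_length(k5)), 1)

  w <- random_weight_matrix(10, density = 0.6, seed = 77)
  expect_equal(as.numeric(char_path_length(2 * w)),
               as.numeric(char_path_length(w)) / 2, tolerance = 1e-12)
})

test_that("disconnected pairs follow the declared policy", {
  two <- matrix(0, 4, 4)
  two[1, 2] <- two[2, 1] <- 1
  two[3, 4] <- two[4, 3] <- 0.5
  lp <- char_path_length(two)
  expect_equal(as.numeric(lp), mean(c(1, 2)))      # reachable pairs only
  expect_equal(attr(lp, "reachable_fraction"), 2 / 6)
  lph <- char_path_length(two, disconnected = "harmonic")
  expect_equal(as.numeric(lph), 1 / mean(c(1, 1 / 2, 0, 0, 0, 0)))
})

test_that("null networks preserve degrees and the weight multiset", {
  w <- threshold_proportional(random_fc_matrix(20, seed = 5), 0.25)
  deg <- rowSums(w > 0)
  wt <- sort(w[upper.tri(w)][w[upper.tri(w)] > 0])
  set.seed(1)
  g <- igraph::graph_from_adjacency_matrix((w > 0) * 1, mode = "undirected")
  for (i in 1:5) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * igraph::ecount(g)))
    expect_equal(igraph::degree(gr), igraph::degree(g))
  }
  # ensemble means are reproducible under the same seed
  n1 <- null_ensemble(w, n_nulls = 4, seed = 9)
  n2 <- null_ensemble(w, n_nulls = 4, seed = 9)
  expect_identical(n1, n2)
  expect_length(n1$cp, 4)
})

test_that("Erdos-Renyi graphs are self-similar under degree-preserving rewiring", {
  ratios <- vapply(1:10, function(s) {
    w <- threshold_proportional(random_fc_matrix(40, seed = 100 + s), 0.2)
    nul <- null_ensemble(w, n_nulls = 5, seed = s)
    c(as.numeric(weighted_clustering(w)) / nul$cp_rand,
      as.numeric(char_path_length(w)) / nul$lp_rand)
  }, numeric(2))
  expect_lt(abs(mean(ratios[1, ]) - 1), 0.1)
  expect_lt(abs(mean(ratios[2, ]) - 1), 0.1)
})

test_that("small-world point returns exact ratios with sigma = gamma/lambda", {
  w <- threshold_proportional(random_fc_matrix(24, seed = 8), 0.3)
  sw <- small_world_point(w, n_nulls = 5, seed = 3)
  expect_equal(sw$gamma, sw$cp / sw$cp_rand)
  expect_equal(sw$lambda, sw$lp / sw$lp_rand)
  expect_equal(sw$sigma, sw$gamma / sw$lambda)
})

test_that("trapezoidal AUC matches closed forms and is linear", {
  ss <- seq(0.1, 0.3, by = 0.01)
  expect_equal(curve_auc(ss, rep(1, 21)), 0.2)
  ramp <- seq(0, 1, length.out = 21)
  expect_equal(curve_auc(ss, ramp), 0.1)

  set.seed(6)
  f <- rnorm(21); g <- rnorm(21)
  hand <- sum(diff(ss) * (head(f, -1) + tail(f, -1)) / 2)
  expect_equal(curve_auc(ss, f), hand)
  expect_equal(curve_auc(ss, 2 * f + 3 * g),
               2 * curve_auc(ss, f) + 3 * curve_auc(ss, g), tolerance = 1e-12)
})

test_that("subject topology is deterministic and detects planted small-world structure", {
  w <- simulate_subject_network(48, 0.1, seed = 12)
  z <- w + random_fc_matrix(48, seed = 13) * 0.1
  diag(z) <- 0
  st1 <- subject_topology(z, n_nulls = 3, seed = 21, subject_id = "a")
  st2 <- subject_topology(z, n_nulls = 3, seed = 21, subject_id = "a")
  expect_identical(st1, st2)
  expect_gt(st1$sigma_auc, 0.2)   # mean sigma > 1 across the sweep
  expect_gt(st1$gamma_auc, 0.2)

  curves <- attr(st1, "curves")
  expect_equal(nrow(curves), 21)
  expect_equal(curves$sigma, curves$gamma / curves$lambda)
})

test_that("cohort topology is invariant to subject order", {
  nets <- list(
    a = random_fc_matrix(24, seed = 31),
    b = random_fc_matrix(24, seed = 32)
  )
  t1 <- cohort_topology(nets, s_min = 0.2, s_max = 0.3, step = 0.05,
                        n_nulls = 2, seed = 5)
  t2 <- cohort_topology(rev(nets), s_min = 0.2, s_max = 0.3, step = 0.05,
                        n_nulls = 2, seed = 5)
  expect_equal(dplyr::arrange(t1, subject_id),
               dplyr::arrange(t2, subject_id), ignore_attr = TRUE)
})
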