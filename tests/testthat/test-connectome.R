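test_that("node series extraction averages voxels and flags degenerate nodes", {
  labels <- structure(array(c(1L, 1L, 2L, 0L), c(4, 1, 1)), n_nodes = 2L)
  bold <- array(0, c(4, 1, 1, 3))
  bold[1, 1, 1, ] <- c(1, 2, 3)
  bold[2, 1, 1, ] <- c(3, 4, 5)
  bold[3, 1, 1, ] <- c(9, 7, 5)
  ts <- extract_node_series(bold, labels)
  expect_equal(unname(ts[, 1]), c(2, 3, 4))   # mean of the two voxels
  expect_equal(unname(ts[, 2]), c(9, 7, 5))   # single-voxel node passthrough

  # opposite-signed voxels cancel to a flagged zero-variance column
  bold[3, 1, 1, ] <- c(1, -2, 5)
  labels2 <- structure(array(c(1L, 0L, 1L, 2L), c(4, 1, 1)), n_nodes = 2L)
  bold[4, 1, 1, ] <- c(7, 7, 7)
  bold[1, 1, 1, ] <- c(-1, 2, -5)
  expect_warning(ts2 <- extract_node_series(bold, labels2), "zero-variance")
  expect_equal(unname(ts2[, 1]), c(0, 0, 0))
  expect_true(attr(ts2, "zero_variance")[1])

  # constant voxel value equal to the label id
  lab3 <- structure(array(c(1L, 2L, 3L, 0L), c(4, 1, 1)), n_nodes = 3L)
  bold3 <- array(rep(c(1, 2, 3, 0), 3), c(4, 1, 1, 3))
  expect_warning(ts3 <- extract_node_series(bold3, lab3), "zero-variance")
  expect_equal(unname(ts3[2, ]), c(1, 2, 3))

  lab4 <- structure(array(c(1L, 3L, 3L, 0L), c(4, 1, 1)), n_nodes = 3L)
  expect_error(extract_node_series(bold3, lab4), "empty node")
})

test_that("Fisher-z connectivity matches the closed form and clips extremes", {
  set.seed(1)
  t1 <- rnorm(50)
  # build a column pair with exact r = 0.5 via Gram-Schmidt
  x <- scale(rnorm(50))[, 1]
  e <- residuals(lm(rnorm(50) ~ x))
  y <- 0.5 * x + sqrt(1 - 0.25) * scale(e)[, 1]
  z <- fc_matrix(cbind(a = x, b = y, c = t1))
  expect_equal(z[1, 2], atanh(0.5), tolerance = 1e-8)
  expect_true(isSymmetric(z))
  expect_equal(diag(z), rep(0, 3), ignore_attr = TRUE)

  # perfectly correlated columns hit the clipped, finite maximum
  z2 <- fc_matrix(cbind(x, x + 0, t1))
  expect_equal(z2[1, 2], atanh(1 - 1e-7))
  expect_true(is.finite(z2[1, 2]))

  # long independent series give near-zero z
  set.seed(2)
  big <- matrix(rnorm(4000 * 2), 4000)
  z3 <- fc_matrix(big)
  expect_lt(abs(z3[1, 2]), 3 / sqrt(4000))

  expect_error(fc_matrix(cbind(x, rep(1, 50))), "zero-variance")
  expect_warning(z4 <- fc_matrix(cbind(x, y, rep(1, 50)),
                                 on_zero_variance = "drop"), "dropping")
  expect_equal(dim(z4), c(2, 2))
})

test_that("connectivity is equivariant under node permutation", {
  set.seed(3)
  ts <- matrix(rnorm(60 * 5), 60)
  colnames(ts) <- paste0("n", 1:5)
  perm <- c(3, 1, 5, 2, 4)
  z <- fc_matrix(ts)
  zp <- fc_matrix(ts[, perm])
  expect_equal(unname(zp), unname(z[perm, perm]), tolerance = 1e-12)
})

test_that("proportional thresholding keeps exactly the strongest edges", {
  z <- matrix(0, 4, 4)
  z[upper.tri(z)] <- c(0.9, 0.1, 0.8, 0.4, 0.2, 0.7)
  z <- z + t(z)
  g <- threshold_proportional(z, 0.5)
  kept <- sort(g[upper.tri(g)][g[upper.tri(g)] > 0], decreasing = TRUE)
  expect_equal(kept, c(0.9, 0.8, 0.7))
  expect_equal(sum(g[upper.tri(g)] > 0), 3)

  # sparsity 1 returns everything
  g1 <- threshold_proportional(z, 1)
  expect_equal(unname(g1), unname(z), ignore_attr = TRUE)

  # saturated ties still give the exact count
  ties <- matrix(1, 5, 5); diag(ties) <- 0
  gt <- threshold_proportional(ties, 0.4)
  expect_equal(sum(gt[upper.tri(gt)] > 0), round(0.4 * 10))

  # surviving negatives become magnitudes under the signed policy
  zn <- matrix(0, 3, 3)
  zn[upper.tri(zn)] <- c(0.5, -0.2, 0.3)
  zn <- zn + t(zn)
  gn <- threshold_proportional(zn, 1)
  expect_true(all(gn[upper.tri(gn)] > 0))
  expect_equal(sort(gn[upper.tri(gn)]), c(0.2, 0.3, 0.5))
})

test_that("the sparsity sweep has the documented grid and nested supports", {
  z <- random_fc_matrix(20, seed = 4)
  sweep <- sparsity_sweep(z)
  expect_length(sweep, 21)
  expect_equal(attr(sweep[[1]], "sparsity"), 0.1)
  expect_equal(attr(sweep[[21]], "sparsity"), 0.3)
  expect_length(sparsity_sweep(z, 0.2, 0.2, 0.01), 1)

  for (i in seq_len(20)) {
    a <- sweep[[i]] > 0
    b <- sweep[[i + 1]] > 0
    expect_true(all(b[a]))  # edges at s survive at s + step
  }
})
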