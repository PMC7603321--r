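test_that("residualization matches OLS geometry", {
  set.seed(1)
  n <- 50
  cov_tab <- data.frame(age = rnorm(n, 40, 10),
                        sex = sample(c("female", "male"), n, TRUE),
                        education = rnorm(n, 13, 3),
                        mean_fd = abs(rnorm(n, 0.12, 0.04)))
  v <- rnorm(n)
  res <- residualize(v, cov_tab)
  mm <- model.matrix(~ ., cov_tab)
  expect_true(all(abs(crossprod(mm, res)) < 1e-8))   # orthogonal to design
  expect_equal(residualize(res, cov_tab), res, tolerance = 1e-10)  # idempotent

  # values exactly linear in a covariate vanish
  v2 <- 2 + 0.5 * cov_tab$age
  expect_equal(residualize(v2, cov_tab), rep(0, n), tolerance = 1e-10)

  # orthogonal covariates leave centered values
  v3 <- rnorm(n)
  ortho <- data.frame(x = residuals(lm(rnorm(n) ~ v3)))
  r3 <- residualize(v3, ortho)
  expect_equal(r3, v3 - mean(v3), tolerance = 1e-8)

  expect_error(residualize(v, transform(cov_tab, dup = age)), "rank-deficient")
})

test_that("Mann-Whitney branch matches exhaustive enumeration", {
  out <- compare_groups(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3),
                        route = "mann_whitney")
  expect_equal(out$statistic, 0)
  expect_equal(out$p_raw, 2 / 20)   # both tails of the exact distribution

  set.seed(7)
  for (i in 1:20) {
    n1 <- sample(3:7, 1); n2 <- sample(3:7, 1)
    x <- round(rnorm(n1), 4); y <- round(rnorm(n2, 0.5), 4)
    if (anyDuplicated(c(x, y))) next
    out <- compare_groups(c(x, y), rep(c("a", "b"), c(n1, n2)),
                          route = "mann_whitney")
    oracle <- enumerate_mann_whitney(x, y)
    expect_equal(out$statistic, oracle$u)
    expect_equal(out$p_raw, oracle$p, tolerance = 1e-12)
  }
})

test_that("identical groups give a null Mann-Whitney result", {
  x <- seq(0.1, 2.1, by = 0.2)
  out <- compare_groups(c(x, x + 1e-9), rep(c("a", "b"), each = length(x)),
                        route = "mann_whitney")
  expect_gt(out$p_raw, 0.4)
  expect_lt(abs(out$statistic - length(x)^2 / 2), 8)
})

test_that("normality routing selects the documented branch", {
  set.seed(11)
  gx <- rnorm(30); gy <- rnorm(30, 2)
  out <- compare_groups(c(gx, gy), rep(c("a", "b"), each = 30))
  expect_equal(out$test_used, "two_sample_t")
  expect_lt(out$p_raw, 1e-3)
  expect_equal(out$p_bonferroni, min(1, 3 * out$p_raw))

  hx <- exp(rnorm(40, 0, 1.5))   # clearly non-Gaussian
  hy <- exp(rnorm(40, 0.1, 1.5))
  out2 <- compare_groups(c(hx, hy), rep(c("a", "b"), each = 40))
  expect_equal(out2$test_used, "mann_whitney_u")
})

test_that("group comparison holds its nominal type-I error", {
  set.seed(13)
  reject <- function(rdist) {
    mean(vapply(1:1000, function(i) {
      compare_groups(rdist(60), rep(c("a", "b"), each = 30))$p_raw < 0.05
    }, logical(1)))
  }
  expect_lte(reject(function(n) rnorm(n)), 0.06)
  expect_lte(reject(function(n) rt(n, df = 3)), 0.06)
})

test_that("covariate-adjusted topology comparison recovers a planted effect", {
  set.seed(17)
  n <- 60
  pheno <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:n),
    group = rep(c("patient", "control"), each = n / 2),
    age = rnorm(n, 40, 10),
    sex = sample(c("female", "male"), n, TRUE),
    education = rnorm(n, 13, 3),
    mean_fd = abs(rnorm(n, 0.12, 0.04))
  )
  topo <- tibble::tibble(
    subject_id = pheno$subject_id,
    gamma_auc = 0.35 - 0.1 * (pheno$group == "patient") +
      0.002 * pheno$age + rnorm(n, 0, 0.02),
    lambda_auc = 0.21 + 0.001 * pheno$mean_fd + rnorm(n, 0, 0.01),
    sigma_auc = 0.3 - 0.08 * (pheno$group == "patient") + rnorm(n, 0, 0.02)
  )
  cmp <- compare_topology(topo, pheno)
  expect_equal(cmp$metric, c("gamma_auc", "lambda_auc", "sigma_auc"))
  expect_lt(cmp$p_bonferroni[1], 0.01)
  expect_lt(cmp$estimate[1], 0)
  expect_gt(cmp$p_bonferroni[2], 0.05)
  adjusted <- attr(cmp, "adjusted")
  expect_equal(nrow(adjusted), 3 * n)
})

test_that("symptom correlations recover sign and significance", {
  set.seed(19)
  n <- 50
  g <- rnorm(n)
  topo <- tibble::tibble(subject_id = as.character(1:n),
                         gamma_auc = g,
                         lambda_auc = rnorm(n),
                         sigma_auc = rnorm(n))
  pheno <- tibble::tibble(subject_id = as.character(1:n),
                          hamd = round(22 - 3 * g + rnorm(n, 0, 1)))
  out <- correlate_with_symptoms(topo, pheno)
  expect_lt(out$r[1], -0.8)
  expect_lt(out$p_bonferroni[1], 0.001)
  expect_equal(out$n, rep(n, 3))

  # exact anticorrelation
  pheno2 <- tibble::tibble(subject_id = as.character(1:n), hamd = -g)
  out2 <- correlate_with_symptoms(topo, pheno2, metrics = "gamma_auc")
  expect_equal(out2$r, -1, tolerance = 1e-12)
})

test_that("interaction ANOVA calibrates under the null and detects crossed effects", {
  set.seed(23)
  # additive cell means: null p roughly uniform
  ps <- vapply(1:200, function(i) {
    g <- rep(c("a", "b"), each = 40)
    s <- rep(rep(c("x", "y"), each = 20), 2)
    v <- rnorm(80) + 0.5 * (g == "a") + 0.3 * (s == "x")
    interaction_anova(v, g, s)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)

  # crossed +d/-d pattern is detected
  g <- rep(c("a", "b"), each = 60)
  s <- rep(rep(c("x", "y"), each = 30), 2)
  d <- 1
  v <- rnorm(120) + d * ifelse(xor(g == "a", s == "x"), 1, -1)
  expect_lt(interaction_anova(v, g, s)$p, 0.01)

  expect_error(
    interaction_anova(rnorm(10), rep(c("a", "b"), each = 5),
                      rep(c("x", "y"), each = 5)),
    "non-empty"
  )
})
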