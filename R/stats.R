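# Covariate adjustment, normality-routed group tests, symptom correlation,
# two-way interaction ANOVA.

#' Residualize values against nuisance covariates
#'
#' Ordinary least-squares adjustment: returns the residuals of `values`
#' regressed on an intercept plus the covariate columns, fitted on the pooled
#' sample. Character/factor covariates (e.g. sex) are dummy-coded.
#'
#' @param values Numeric vector.
#' @param covariates Data frame of covariates, one row per value.
#' @return Numeric vector of residuals (same length and order as `values`).
#' @export
residualize <- function(values, covariates) {
  stopifnot(is.numeric(values), nrow(covariates) == length(values))
  if (anyNA(values) || anyNA(covariates)) {
    stop("missing values in inputs", call. = FALSE)
  }
  df <- as.data.frame(covariates)
  if (length(values) <= ncol(df) + 1) {
    stop("need more observations than covariates", call. = FALSE)
  }
  mm <- stats::model.matrix(~ ., data = df)
  if (qr(mm)$rank < ncol(mm)) {
    stop("covariate design is rank-deficient", call. = FALSE)
  }
  unname(stats::residuals(stats::lm.fit(mm, values)))
}

#' Normality-routed two-group comparison
#'
#' Compares two groups with a two-sample pooled-variance t-test when both
#' groups pass a Shapiro-Wilk normality check, and with the nonparametric
#' Mann-Whitney U test otherwise. The U statistic is reported in the
#' min(U1, U2) convention; p values are two-sided, exact (no ties, both
#' groups <= 20) or normal-approximate with continuity correction.
#'
#' @param values Numeric vector (typically covariate-adjusted residuals).
#' @param group Two-level factor/character vector.
#' @param route `"auto"` (default; Shapiro-Wilk at `alpha_normality`),
#'   `"t_test"` or `"mann_whitney"` to force a branch.
#' @param n_comparisons Bonferroni family size (default 3, for the three
#'   planned small-world comparisons).
#' @param alpha_normality Normality-test level for routing (default 0.05).
#' @return One-row tibble: `test_used`, `statistic`, `p_raw`,
#'   `p_bonferroni`, group means and sizes (first level minus second for
#'   `estimate`).
#' @export
compare_groups <- function(values, group,
                           route = c("auto", "t_test", "mann_whitney"),
                           n_comparisons = 3, alpha_normality = 0.05) {
  route <- match.arg(route)
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("group must have exactly 2 levels", call. = FALSE)
  x <- values[group == levels(group)[1]]
  y <- values[group == levels(group)[2]]
  if (length(x) < 3 || length(y) < 3) {
    stop("each group needs at least 3 observations", call. = FALSE)
  }
  if (route == "auto") {
    normal <- function(v) {
      if (length(v) > 5000) v <- sample(v, 5000)
      stats::shapiro.test(v)$p.value >= alpha_normality
    }
    route <- if (normal(x) && normal(y)) "t_test" else "mann_whitney"
  }
  if (route == "t_test") {
    ht <- stats::t.test(x, y, var.equal = TRUE)
    statistic <- unname(ht$statistic)
    p <- ht$p.value
    test_used <- "two_sample_t"
  } else {
    n1 <- length(x); n2 <- length(y)
    exact <- n1 <= 20 && n2 <= 20 && !anyDuplicated(c(x, y))
    ht <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = TRUE)
    )
    u1 <- unname(ht$statistic)
    statistic <- min(u1, n1 * n2 - u1)
    p <- ht$p.value
    test_used <- "mann_whitney_u"
  }
  tibble::tibble(
    test_used = test_used,
    statistic = statistic,
    p_raw = p,
    p_bonferroni = min(1, n_comparisons * p),
    mean_1 = mean(x), mean_2 = mean(y),
    estimate = mean(x) - mean(y),
    n_1 = length(x), n_2 = length(y)
  )
}

#' Covariate-adjusted group comparison of topology features
#'
#' The main group analysis: joins per-subject AUC topology features to
#' phenotypes, residualizes each metric on the nuisance covariates over the
#' pooled sample, and runs the normality-routed two-group test per metric
#' with Bonferroni correction across the planned comparisons.
#'
#' @param topology Tibble from [cohort_topology()] (`subject_id` plus metric
#'   columns).
#' @param phenotypes Phenotype tibble with `subject_id`, `group` and the
#'   covariate columns.
#' @param metrics Metric columns to test (default the three AUC features).
#' @param covariates Covariate columns (default age, sex, education,
#'   mean framewise displacement). Use `character(0)` to skip adjustment.
#' @param group_levels Order of the two groups; `estimate` is
#'   first minus second (default patient minus control).
#' @inheritParams compare_groups
#' @return Tibble with one row per metric; columns as in [compare_groups()]
#'   plus `metric`. The adjusted per-subject values are attached as attribute
#'   `adjusted` (long tibble).
#' @export
compare_topology <- function(topology, phenotypes,
                             metrics = c("gamma_auc", "lambda_auc", "sigma_auc"),
                             covariates = c("age", "sex", "education", "mean_fd"),
                             group_levels = c("patient", "control"),
                             route = c("auto", "t_test", "mann_whitney"),
                             alpha_normality = 0.05) {
  route <- match.arg(route)
  dat <- dplyr::inner_join(topology, phenotypes, by = "subject_id")
  if (!nrow(dat)) stop("no subjects shared by topology and phenotypes", call. = FALSE)
  grp <- factor(dat$group, levels = group_levels)
  adjusted <- purrr::map_dfr(metrics, function(m) {
    v <- dat[[m]]
    adj <- if (length(covariates)) {
      residualize(v, dat[covariates])
    } else {
      v - mean(v)
    }
    tibble::tibble(subject_id = dat$subject_id, group = as.character(grp),
                   metric = m, value = v, adjusted = adj)
  })
  out <- purrr::map_dfr(metrics, function(m) {
    a <- adjusted[adjusted$metric == m, ]
    dplyr::bind_cols(
      tibble::tibble(metric = m),
      compare_groups(a$adjusted, factor(a$group, levels = group_levels),
                     route = route, n_comparisons = length(metrics),
                     alpha_normality = alpha_normality)
    )
  })
  attr(out, "adjusted") <- adjusted
  out
}

#' Correlate topology features with symptom severity
#'
#' Pearson correlation between each topology metric and the symptom score in
#' patients, with Bonferroni correction over the planned correlations.
#'
#' @inheritParams compare_topology
#' @param score Phenotype column holding the symptom score (default
#'   `"hamd"`); rows with a missing score (controls) are excluded.
#' @return Tibble: `metric`, `r`, `p_raw`, `p_bonferroni`, `n`.
#' @export
correlate_with_symptoms <- function(topology, phenotypes,
                                    metrics = c("gamma_auc", "lambda_auc",
                                                "sigma_auc"),
                                    score = "hamd") {
  dat <- dplyr::inner_join(topology, phenotypes, by = "subject_id")
  dat <- dat[!is.na(dat[[score]]), ]
  if (nrow(dat) < 4) stop("need at least 4 scored subjects", call. = FALSE)
  if (stats::sd(dat[[score]]) == 0) {
    stop("symptom score has zero variance", call. = FALSE)
  }
  purrr::map_dfr(metrics, function(m) {
    if (stats::sd(dat[[m]]) == 0) {
      stop("metric ", m, " has zero variance", call. = FALSE)
    }
    ct <- stats::cor.test(dat[[m]], dat[[score]])
    tibble::tibble(metric = m, r = unname(ct$estimate),
                   p_raw = ct$p.value,
                   p_bonferroni = min(1, length(metrics) * ct$p.value),
                   n = nrow(dat))
  })
}

#' Group-by-sample interaction ANOVA
#'
#' Two-way fixed-effects ANOVA testing whether a group effect differs
#' between samples (e.g. discovery vs replication) — the auxiliary check
#' that a replicated difference is not an acquisition artifact.
#'
#' @param values Numeric vector.
#' @param group Two-level factor (e.g. patient/control).
#' @param sample Two-level factor (e.g. discovery/replication).
#' @return One-row tibble with the interaction `f`, `df1`, `df2`, `p`.
#' @export
interaction_anova <- function(values, group, sample) {
  group <- as.factor(group); sample <- as.factor(sample)
  if (nlevels(group) != 2 || nlevels(sample) != 2) {
    stop("group and sample must each have two levels", call. = FALSE)
  }
  if (any(table(group, sample) == 0)) {
    stop("every group x sample cell must be non-empty", call. = FALSE)
  }
  fit <- stats::aov(values ~ group * sample)
  tab <- summary(fit)[[1]]
  ix <- grep(":", rownames(tab))
  tibble::tibble(
    f = tab[ix, "F value"],
    df1 = tab[ix, "Df"],
    df2 = tab[nrow(tab), "Df"],
    p = tab[ix, "Pr(>F)"]
  )
}
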