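# ggplot2 figures for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Violin plot of adjusted topology features by group
#'
#' Visualizes a [compare_topology()] result: covariate-adjusted AUC values
#' per metric, split by group.
#'
#' @param comparison Result of [compare_topology()] (its `adjusted`
#'   attribute holds the per-subject values).
#' @return A ggplot object.
#' @export
plot_topology_comparison <- function(comparison) {
  adjusted <- attr(comparison, "adjusted")
  if (is.null(adjusted)) stop("comparison lacks adjusted values", call. = FALSE)
  ggplot2::ggplot(adjusted,
                  ggplot2::aes(x = .data$group, y = .data$adjusted,
                               fill = .data$group)) +
    ggplot2::geom_violin(alpha = 0.5, trim = FALSE) +
    ggplot2::geom_jitter(width = 0.12, size = 0.6, alpha = 0.5) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "adjusted AUC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Group-mean small-world curves across the sparsity sweep
#'
#' @param curves Long tibble of per-subject curves (attribute `curves` of
#'   [cohort_topology()] with `keep_curves = TRUE`), with a `subject_id`
#'   column.
#' @param phenotypes Optional phenotype tibble supplying `group` per subject.
#' @param metrics Curve columns to plot (default gamma, lambda, sigma).
#' @return A ggplot object.
#' @export
plot_sparsity_curves <- function(curves, phenotypes = NULL,
                                 metrics = c("gamma", "lambda", "sigma")) {
  if (!is.null(phenotypes)) {
    curves <- dplyr::inner_join(
      curves, dplyr::select(phenotypes, "subject_id", "group"),
      by = "subject_id"
    )
  } else {
    curves$group <- "all"
  }
  long <- tidyr::pivot_longer(curves, dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  summ <- dplyr::summarise(
    dplyr::group_by(long, .data$group, .data$metric, .data$sparsity),
    value = mean(.data$value), .groups = "drop"
  )
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$sparsity, y = .data$value,
                                     color = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        color = "grey50") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "sparsity", y = "group mean") +
    ggplot2::theme_minimal()
}

#' @rdname svr_predict_cv
#' @param object A `wm_svr_cv` object.
#' @exportS3Method ggplot2::autoplot
autoplot.wm_svr_cv <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "steelblue") +
    ggplot2::labs(
      x = "observed score", y = "predicted score",
      title = sprintf("Cross-validated prediction (r = %.2f, p = %.3g)",
                      object$r, object$p)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname svm_vote
#' @param object A `wm_svm_vote` object.
#' @exportS3Method ggplot2::autoplot
autoplot.wm_svm_vote <- function(object, ...) {
  if (is.null(object$confusion)) stop("no true labels available", call. = FALSE)
  cf <- tibble::tibble(
    truth = c("positive", "negative", "positive", "negative"),
    voted = c("positive", "negative", "negative", "positive"),
    n = unname(object$confusion[c("tp", "tn", "fn", "fp")])
  )
  ggplot2::ggplot(cf, ggplot2::aes(x = .data$truth, y = .data$voted,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), color = "white") +
    ggplot2::labs(x = "true class", y = "voted class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' @importFrom rlang .data
NULL
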