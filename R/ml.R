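# SVR severity prediction with cross-validation; balanced-subsample
# ensemble SVM classification with majority voting. Models are fit with the
# libsvm bindings in e1071.

scale_fit <- function(x) {
  center <- colMeans(x)
  spread <- apply(x, 2, stats::sd)
  spread[spread == 0] <- 1
  list(center = center, spread = spread)
}

scale_apply <- function(x, sc) {
  sweep(sweep(x, 2, sc$center, "-"), 2, sc$spread, "/")
}

#' Cross-validated SVR severity prediction
#'
#' Predicts a continuous severity score from topology features with a
#' linear-kernel support vector regression under k-fold cross-validation:
#' subjects are randomly split into k folds; each fold is predicted by a
#' model fit on the other folds only, with features standardized using
#' training-fold statistics only. Performance is the Pearson correlation
#' between observed and predicted scores over all subjects.
#'
#' @param data Tibble with one row per subject, containing `subject_id`, the
#'   feature columns and the target column (rows with a missing target are
#'   dropped).
#' @param features Feature columns (default the three AUC topology metrics).
#' @param target Target column (default `"hamd"`).
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold split.
#' @param cost,epsilon SVR hyperparameters (libsvm defaults 1 and 0.1).
#' @param standardize Standardize features per training fold (default TRUE).
#' @return Object of class `wm_svr_cv`: per-subject predictions with fold
#'   assignment, and the observed-vs-predicted `r` and `p`. Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
svr_predict_cv <- function(data,
                           features = c("gamma_auc", "lambda_auc", "sigma_auc"),
                           target = "hamd", k = 5, seed = NULL,
                           cost = 1, epsilon = 0.1, standardize = TRUE) {
  stopifnot(k >= 2)
  data <- data[!is.na(data[[target]]), ]
  n <- nrow(data)
  if (n < 2 * k) stop("need at least 2 observations per fold", call. = FALSE)
  x <- as.matrix(data[features])
  y <- data[[target]]
  fold <- with_seed_(seed, sample(rep(seq_len(k), length.out = n)))
  pred <- numeric(n)
  for (f in seq_len(k)) {
    tr <- fold != f
    xt <- x[tr, , drop = FALSE]
    sc <- if (standardize) scale_fit(xt) else list(center = rep(0, ncol(x)),
                                                   spread = rep(1, ncol(x)))
    fit <- e1071::svm(scale_apply(xt, sc), y[tr], type = "eps-regression",
                      kernel = "linear", cost = cost, epsilon = epsilon,
                      scale = FALSE)
    pred[!tr] <- stats::predict(fit, scale_apply(x[!tr, , drop = FALSE], sc))
  }
  ct <- stats::cor.test(y, pred)
  structure(list(
    predictions = tibble::tibble(
      subject_id = data$subject_id %||% as.character(seq_len(n)),
      fold = fold, observed = y, predicted = pred
    ),
    r = unname(ct$estimate), p = ct$p.value, k = k, n = n,
    features = features, target = target
  ), class = "wm_svr_cv")
}

#' @export
print.wm_svr_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV SVR (%d subjects): observed-vs-predicted r = %.3f, p = %.3g\n",
              x$k, x$n, x$r, x$p))
  invisible(x)
}

#' Balanced-subsample SVM ensemble
#'
#' Trains the imbalance-robust classifier: in each of `n_models` trials
#' (default 3), 80% of the positive class (patients) and an equal number of
#' randomly drawn controls form a class-balanced training set for a
#' sigmoid-kernel SVM. Features are standardized with each trial's training
#' statistics. The trials' subsamples are recorded.
#'
#' @param data Tibble with `subject_id`, feature columns and the class label.
#' @param features Feature columns (default the three AUC topology metrics).
#' @param label Label column (default `"group"`).
#' @param positive Positive-class value of `label` (default `"patient"`).
#' @param n_models Number of trials (default 3; odd, so majority votes cannot
#'   tie).
#' @param train_fraction Fraction of positives per trial (default 0.8).
#' @param seed Integer seed for the subsample draws.
#' @param cost,coef0 SVM hyperparameters (libsvm defaults 1 and 0).
#' @param gamma Sigmoid-kernel scale (default 1/n_features).
#' @param standardize Standardize features per trial (default TRUE).
#' @return Object of class `wm_svm_ensemble` holding the fitted models,
#'   their scalers and subsample ids.
#' @export
svm_train_ensemble <- function(data,
                               features = c("gamma_auc", "lambda_auc",
                                            "sigma_auc"),
                               label = "group", positive = "patient",
                               n_models = 3, train_fraction = 0.8,
                               seed = NULL, cost = 1, coef0 = 0,
                               gamma = NULL, standardize = TRUE) {
  stopifnot(n_models %% 2 == 1)
  lab <- data[[label]]
  pos_idx <- which(lab == positive)
  neg_idx <- which(lab != positive)
  if (length(pos_idx) < 5 || length(neg_idx) < 5) {
    stop("need at least 5 subjects per class", call. = FALSE)
  }
  n_draw <- round(train_fraction * length(pos_idx))
  if (n_draw < 1 || n_draw > length(neg_idx)) {
    stop("cannot draw ", n_draw, " controls to balance ", n_draw,
         " patients", call. = FALSE)
  }
  x <- as.matrix(data[features])
  ids <- data$subject_id %||% as.character(seq_len(nrow(data)))
  gamma <- gamma %||% (1 / length(features))
  models <- with_seed_(seed, {
    lapply(seq_len(n_models), function(i) {
      tr_pos <- sample(pos_idx, n_draw)
      tr_neg <- sample(neg_idx, n_draw)
      tr <- c(tr_pos, tr_neg)
      xt <- x[tr, , drop = FALSE]
      sc <- if (standardize) scale_fit(xt) else list(center = rep(0, ncol(x)),
                                                     spread = rep(1, ncol(x)))
      yt <- factor(ifelse(lab[tr] == positive, "positive", "negative"),
                   levels = c("negative", "positive"))
      fit <- e1071::svm(scale_apply(xt, sc), yt, type = "C-classification",
                        kernel = "sigmoid", cost = cost, gamma = gamma,
                        coef0 = coef0, scale = FALSE)
      list(fit = fit, scaler = sc, train_ids = ids[tr],
           train_positive = ids[tr_pos], train_negative = ids[tr_neg])
    })
  })
  structure(list(models = models, features = features, label = label,
                 positive = positive, n_models = n_models,
                 train_fraction = train_fraction, gamma = gamma,
                 cost = cost, coef0 = coef0),
            class = "wm_svm_ensemble")
}

#' @export
print.wm_svm_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d sigmoid-kernel SVMs (balanced %d + %d training draws)\n",
              x$n_models, length(x$models[[1]]$train_positive),
              length(x$models[[1]]$train_negative)))
  invisible(x)
}

#' Majority-vote classification of an external sample
#'
#' Applies every model of a trained ensemble to new subjects and assigns each
#' subject the majority label of the votes. With known labels, accuracy,
#' sensitivity (recall on the positive class) and specificity are computed
#' from the confusion matrix.
#'
#' @param ensemble A fitted [svm_train_ensemble()] object.
#' @param data Tibble with `subject_id`, the ensemble's feature columns and,
#'   optionally, the true label column.
#' @return Object of class `wm_svm_vote`: per-subject vote triple and voted
#'   label, plus `accuracy`, `sensitivity`, `specificity` and the confusion
#'   counts when labels are available.
#' @export
svm_vote <- function(ensemble, data) {
  stopifnot(inherits(ensemble, "wm_svm_ensemble"))
  x <- as.matrix(data[ensemble$features])
  ids <- data$subject_id %||% as.character(seq_len(nrow(data)))
  votes <- vapply(ensemble$models, function(m) {
    as.character(stats::predict(m$fit, scale_apply(x, m$scaler)))
  }, character(nrow(x)))
  votes <- matrix(votes, nrow = nrow(x))
  n_pos <- rowSums(votes == "positive")
  voted <- ifelse(n_pos > ensemble$n_models / 2, "positive", "negative")
  vt <- tibble::as_tibble(votes, .name_repair = ~ paste0("vote_", seq_along(.x)))
  vt <- dplyr::mutate(vt, subject_id = ids, label = voted, .before = 1)
  res <- list(votes = vt, n_models = ensemble$n_models)
  if (!is.null(data[[ensemble$label]])) {
    truth <- ifelse(data[[ensemble$label]] == ensemble$positive,
                    "positive", "negative")
    tp <- sum(voted == "positive" & truth == "positive")
    tn <- sum(voted == "negative" & truth == "negative")
    fp <- sum(voted == "positive" & truth == "negative")
    fn <- sum(voted == "negative" & truth == "positive")
    res$votes$truth <- truth
    res$confusion <- c(tp = tp, tn = tn, fp = fp, fn = fn)
    res$accuracy <- (tp + tn) / length(truth)
    res$sensitivity <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    res$specificity <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  }
  structure(res, class = "wm_svm_vote")
}

#' @export
print.wm_svm_vote <- function(x, ...) {
  cat(sprintf("Majority vote over %d models, %d subjects\n",
              x$n_models, nrow(x$votes)))
  if (!is.null(x$accuracy)) {
    cat(sprintf("accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
                100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity))
  }
  invisible(x)
}
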