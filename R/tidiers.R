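# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname svr_predict_cv
#' @param x A `wm_svr_cv` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.wm_svr_cv <- function(x, ...) x$predictions

#' @rdname svr_predict_cv
#' @exportS3Method generics::glance
glance.wm_svr_cv <- function(x, ...) {
  tibble::tibble(r = x$r, p = x$p, k = x$k, n = x$n)
}

#' @rdname svm_train_ensemble
#' @param x A `wm_svm_ensemble` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.wm_svm_ensemble <- function(x, ...) {
  purrr::imap_dfr(x$models, function(m, i) {
    tibble::tibble(model = i,
                   subject_id = m$train_ids,
                   class = rep(c("positive", "negative"),
                               c(length(m$train_positive),
                                 length(m$train_negative))))
  })
}

#' @rdname svm_train_ensemble
#' @exportS3Method generics::glance
glance.wm_svm_ensemble <- function(x, ...) {
  tibble::tibble(n_models = x$n_models, train_fraction = x$train_fraction,
                 kernel = "sigmoid", cost = x$cost, gamma = x$gamma,
                 coef0 = x$coef0)
}

#' @rdname svm_vote
#' @param x A `wm_svm_vote` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.wm_svm_vote <- function(x, ...) x$votes

#' @rdname svm_vote
#' @exportS3Method generics::glance
glance.wm_svm_vote <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy %||% NA_real_,
    sensitivity = x$sensitivity %||% NA_real_,
    specificity = x$specificity %||% NA_real_,
    n = nrow(x$votes)
  )
}
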