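test_that("cross-validated SVR predicts a noiseless linear target almost perfectly", {
  dat <- make_features(60, 0, seed = 2)
  dat$hamd <- 10 + 100 * dat$gamma_auc
  fit <- svr_predict_cv(dat, k = 5, seed = 3)
  expect_gt(fit$r, 0.99)
})

test_that("cross-validation bookkeeping keeps test subjects out of training", {
  dat <- make_features(40, 0, seed = 4)
  fit <- svr_predict_cv(dat, k = 5, seed = 5)
  td <- tidy(fit)
  expect_setequal(td$subject_id, dat$subject_id)
  expect_equal(nrow(td), 40)               # each subject predicted once
  expect_equal(sort(unique(td$fold)), 1:5)
  expect_true(all(table(td$fold) >= floor(40 / 5)))
  # determinism: identical run reproduces folds and predictions
  fit2 <- svr_predict_cv(dat, k = 5, seed = 5)
  expect_identical(tidy(fit), tidy(fit2))
  expect_error(svr_predict_cv(dat[1:8, ], k = 5), "per fold")
})

test_that("SVR performance collapses when targets are independent of features", {
  rs <- vapply(1:100, function(i) {
    dat <- make_features(91, 0, seed = 100 + i)
    dat$hamd <- sample(dat$hamd)
    svr_predict_cv(dat, k = 5, seed = i)$r
  }, numeric(1))
  expect_lt(mean(abs(rs)), 0.15)
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("SVR recovers a planted severity signal at study scale", {
  hits <- vapply(1:10, function(i) {
    dat <- make_features(91, 0, shift = 0, seed = 200 + i)
    fit <- svr_predict_cv(dat, k = 5, seed = i)
    fit$r > 0 && fit$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.6)
})

test_that("ensemble training draws balanced subsamples reproducibly", {
  dat <- make_features(40, 100, seed = 6)
  ens <- svm_train_ensemble(dat, seed = 7)
  expect_length(ens$models, 3)
  for (m in ens$models) {
    expect_length(m$train_positive, round(0.8 * 40))
    expect_length(m$train_negative, round(0.8 * 40))
  }
  ens2 <- svm_train_ensemble(dat, seed = 7)
  expect_identical(tidy(ens), tidy(ens2))
  expect_error(svm_train_ensemble(make_features(40, 10, seed = 1)),
               "balance")
})

test_that("separable classes are learned by every ensemble member", {
  dat <- make_features(30, 60, shift = 0.5, noise = 0.005, seed = 8)
  ens <- svm_train_ensemble(dat, seed = 9)
  for (m in ens$models) {
    ids <- m$train_ids
    sub <- dat[match(ids, dat$subject_id), ]
    pred <- predict(m$fit, wmtopo:::scale_apply(as.matrix(sub[ens$features]),
                                                m$scaler))
    truth <- ifelse(sub$group == "patient", "positive", "negative")
    expect_equal(as.character(pred), truth)
  }
})

test_that("majority voting follows the vote arithmetic and confusion identities", {
  train <- make_features(40, 100, shift = 0.2, noise = 0.02, seed = 10)
  test <- make_features(34, 25, shift = 0.2, noise = 0.02, seed = 11)
  ens <- svm_train_ensemble(train, seed = 12)
  vote <- svm_vote(ens, test)
  td <- tidy(vote)
  n_pos <- rowSums(as.matrix(td[paste0("vote_", 1:3)]) == "positive")
  expect_identical(td$label,
                   ifelse(n_pos >= 2, "positive", "negative"))
  cf <- vote$confusion
  expect_equal(vote$accuracy, (cf["tp"] + cf["tn"]) / nrow(test),
               ignore_attr = TRUE)
  expect_equal(vote$sensitivity, cf["tp"] / (cf["tp"] + cf["fn"]),
               ignore_attr = TRUE)
  expect_equal(vote$specificity, cf["tn"] / (cf["tn"] + cf["fp"]),
               ignore_attr = TRUE)
  expect_equal(sum(cf), nrow(test))
  # a well-separated problem is classified above the majority-class baseline
  expect_gt(vote$accuracy, max(table(test$group)) / nrow(test))
})

test_that("label permutation collapses ensemble accuracy to the baseline", {
  accs <- vapply(1:20, function(i) {
    train <- make_features(40, 100, shift = 0.08, seed = 300 + i)
    test <- make_features(30, 30, shift = 0.08, seed = 400 + i)
    set.seed(i)
    train$group <- sample(train$group)
    ens <- svm_train_ensemble(train, seed = i)
    svm_vote(ens, test)$accuracy
  }, numeric(1))
  baseline <- 0.5  # balanced external sample: majority class = 50%
  expect_lt(abs(mean(accs) - baseline), 0.07)
})
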