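# Feature tables for the ML stages are simulated directly: per-subject AUC
# features with a group shift, mimicking the output of the topology stage.
make_features <- function(n_pat, n_ctl, shift = 0.08, noise = 0.03,
                          seed = 1) {
  set.seed(seed)
  n <- n_pat + n_ctl
  group <- rep(c("patient", "control"), c(n_pat, n_ctl))
  gamma <- 0.3 - shift * (group == "patient") + rnorm(n, 0, noise)
  tibble::tibble(
    subject_id = sprintf("s%03d", seq_len(n)),
    group = group,
    gamma_auc = gamma,
    lambda_auc = 0.21 + rnorm(n, 0, 0.01),
    sigma_auc = gamma / (0.21 / 0.2) + rnorm(n, 0, noise / 2),
    hamd = ifelse(group == "patient",
                  as.integer(pmax(round(22 - 40 * (gamma - 0.26) +
                                          rnorm(n, 0, 2)), 8)),
                  NA_integer_)
  )
}
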