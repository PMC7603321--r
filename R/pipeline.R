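# End-to-end orchestration: simulate -> (parcellate/extract) -> topology ->
# statistics -> prediction/classification, with a provenance manifest.

#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end analysis with the study defaults
#' preloaded: 91/225 discovery and 34/25 replication cohorts, 128 nodes,
#' sparsity sweep 0.10-0.30 in steps of 0.01, the four nuisance covariates,
#' 5-fold SVR and the 3-model balanced-subsample SVM. Any field can be
#' overridden for scaled-down runs.
#'
#' @param n_patients,n_controls Discovery cohort sizes.
#' @param replication Named list with `n_patients` and `n_controls` for the
#'   replication cohort, or `NULL` to skip replication/classification.
#' @param n_nodes,n_timepoints,randomization_shift,symptom_effect,noise_sd,base_rewiring,rewiring_jitter_sd,k_ring
#'   Generator settings, see [cohort_spec()].
#' @param s_min,s_max,step Sparsity sweep.
#' @param n_nulls Null networks per sparsity (default 100).
#' @param covariates Nuisance covariates for the group comparison.
#' @param k_folds SVR cross-validation folds (default 5).
#' @param n_svm_models,train_fraction Ensemble SVM settings.
#' @param negatives,clustering_variant,disconnected Policy switches, see
#'   [threshold_proportional()], [weighted_clustering()],
#'   [char_path_length()].
#' @param render_voxels If `TRUE`, render each subject's network as voxel
#'   time series on a toy mask and run the parcellation/extraction stages;
#'   otherwise the generated networks feed the thresholding stage directly.
#' @param mask_shape,mask_fill,voxel_noise_sd,connectivity Toy-mask and
#'   rendering settings (used only when `render_voxels = TRUE`).
#' @param seed Root seed; every stochastic stage derives its seed from it.
#' @return A list of class `wm_pipeline_config`.
#' @export
pipeline_config <- function(n_patients = 91, n_controls = 225,
                            replication = list(n_patients = 34,
                                               n_controls = 25),
                            n_nodes = 128, n_timepoints = 242,
                            randomization_shift = 0.4, symptom_effect = -2.5,
                            noise_sd = 3, base_rewiring = 0.1,
                            rewiring_jitter_sd = 0.05, k_ring = NULL,
                            s_min = 0.1, s_max = 0.3, step = 0.01,
                            n_nulls = 100,
                            covariates = c("age", "sex", "education",
                                           "mean_fd"),
                            k_folds = 5, n_svm_models = 3,
                            train_fraction = 0.8,
                            negatives = "signed",
                            clustering_variant = "onnela",
                            disconnected = "exclude",
                            render_voxels = FALSE,
                            mask_shape = c(12, 12, 12), mask_fill = 1,
                            voxel_noise_sd = 0.5, connectivity = 26,
                            seed = 1) {
  cfg <- as.list(environment())
  structure(cfg, class = "wm_pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage [", stage, "] failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

cohort_networks <- function(cohort, config, tag) {
  if (!isTRUE(config$render_voxels)) return(cohort$networks)
  mask <- run_stage(paste0(tag, ":mask"), make_toy_mask(
    config$mask_shape, config$mask_fill,
    seed = derive_seed(config$seed, 11), connectivity = config$connectivity
  ))
  labels <- run_stage(paste0(tag, ":parcellation"), grow_parcels(
    mask, config$n_nodes, seed = derive_seed(config$seed, 12),
    connectivity = config$connectivity
  ))
  nets <- run_stage(paste0(tag, ":connectome"), {
    purrr::imap(cohort$networks, function(w, id) {
      bold <- render_voxel_series(
        w, labels, config$n_timepoints, noise_sd = config$voxel_noise_sd,
        seed = derive_seed(config$seed, 500 + id_hash(id))
      )
      fc_matrix(extract_node_series(bold, labels), subject_id = id)
    })
  })
  attr(nets, "labels") <- labels
  nets
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> (optional parcellation/extraction) -> sparsity-swept
#' topology -> covariate-adjusted group comparison and symptom correlation ->
#' cross-validated SVR prediction -> ensemble SVM classification of the
#' replication cohort -> group-by-sample interaction ANOVA, writing each
#' stage's table and a provenance manifest to `out_dir`. Reruns with the
#' same configuration reproduce the outputs exactly.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @return A list of class `wm_pipeline` with elements `discovery`
#'   (cohort, topology), `replication` (or `NULL`), `comparison`,
#'   `correlation`, `prediction`, `classification`, `interaction` and
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "wm_pipeline_config"))

  disc_spec <- cohort_spec(
    n_patients = config$n_patients, n_controls = config$n_controls,
    n_nodes = config$n_nodes, n_timepoints = config$n_timepoints,
    randomization_shift = config$randomization_shift,
    symptom_effect = config$symptom_effect, noise_sd = config$noise_sd,
    base_rewiring = config$base_rewiring,
    rewiring_jitter_sd = config$rewiring_jitter_sd, k_ring = config$k_ring,
    rng_seed = derive_seed(config$seed, 1)
  )
  discovery <- run_stage("simulate:discovery", simulate_cohort(disc_spec))
  disc_nets <- cohort_networks(discovery, config, "discovery")
  disc_topo <- run_stage("topology:discovery", cohort_topology(
    disc_nets, config$s_min, config$s_max, config$step, config$n_nulls,
    seed = derive_seed(config$seed, 2), negatives = config$negatives,
    variant = config$clustering_variant, disconnected = config$disconnected
  ))

  comparison <- run_stage("compare", compare_topology(
    disc_topo, discovery$phenotypes, covariates = config$covariates
  ))
  correlation <- run_stage("correlate", correlate_with_symptoms(
    disc_topo, discovery$phenotypes
  ))
  prediction <- run_stage("predict", svr_predict_cv(
    dplyr::inner_join(disc_topo, discovery$phenotypes, by = "subject_id"),
    k = config$k_folds, seed = derive_seed(config$seed, 3)
  ))

  replication <- NULL
  classification <- NULL
  interaction <- NULL
  if (!is.null(config$replication)) {
    repl_spec <- cohort_spec(
      n_patients = config$replication$n_patients,
      n_controls = config$replication$n_controls,
      n_nodes = config$n_nodes, n_timepoints = config$n_timepoints,
      randomization_shift = config$randomization_shift,
      symptom_effect = config$symptom_effect, noise_sd = config$noise_sd,
      base_rewiring = config$base_rewiring,
      rewiring_jitter_sd = config$rewiring_jitter_sd, k_ring = config$k_ring,
      rng_seed = derive_seed(config$seed, 4)
    )
    repl <- run_stage("simulate:replication", simulate_cohort(repl_spec))
    repl_nets <- cohort_networks(repl, config, "replication")
    repl_topo <- run_stage("topology:replication", cohort_topology(
      repl_nets, config$s_min, config$s_max, config$step, config$n_nulls,
      seed = derive_seed(config$seed, 5), negatives = config$negatives,
      variant = config$clustering_variant, disconnected = config$disconnected
    ))
    replication <- list(cohort = repl, topology = repl_topo)

    ens <- run_stage("classify:train", svm_train_ensemble(
      dplyr::inner_join(disc_topo, discovery$phenotypes, by = "subject_id"),
      n_models = config$n_svm_models,
      train_fraction = config$train_fraction,
      seed = derive_seed(config$seed, 6)
    ))
    classification <- run_stage("classify:vote", svm_vote(
      ens, dplyr::inner_join(repl_topo, repl$phenotypes, by = "subject_id")
    ))
    attr(classification, "ensemble") <- ens

    interaction <- run_stage("interaction", {
      combined <- dplyr::bind_rows(
        dplyr::mutate(
          dplyr::inner_join(disc_topo, discovery$phenotypes,
                            by = "subject_id"),
          sample = "discovery"
        ),
        dplyr::mutate(
          dplyr::inner_join(repl_topo, repl$phenotypes, by = "subject_id"),
          sample = "replication"
        )
      )
      purrr::map_dfr(c("gamma_auc", "lambda_auc", "sigma_auc"), function(m) {
        dplyr::mutate(
          interaction_anova(combined[[m]], combined$group, combined$sample),
          metric = m, .before = 1
        )
      })
    })
  }

  result <- structure(list(
    discovery = list(cohort = discovery, topology = disc_topo),
    replication = replication,
    comparison = comparison, correlation = correlation,
    prediction = prediction, classification = classification,
    interaction = interaction, config = config
  ), class = "wm_pipeline")

  if (!is.null(out_dir)) {
    result$manifest <- write_pipeline_outputs(result, out_dir)
  }
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  paths <- character(0)
  wr <- function(x, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(x, p)
    paths[[name]] <<- p
    p
  }
  wr(result$discovery$cohort$phenotypes, "discovery_phenotypes.csv")
  wr(result$discovery$topology, "discovery_topology.csv")
  wr(result$comparison, "group_comparison.csv")
  wr(result$correlation, "symptom_correlation.csv")
  wr(tidy(result$prediction), "svr_predictions.csv")
  if (!is.null(result$replication)) {
    wr(result$replication$cohort$phenotypes, "replication_phenotypes.csv")
    wr(result$replication$topology, "replication_topology.csv")
    wr(tidy(result$classification), "svm_votes.csv")
    wr(result$interaction, "interaction_anova.csv")
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("wmtopo")),
    seed = cfg$seed,
    config = unclass(cfg),
    files = as.list(unname(tools::md5sum(unlist(paths))))
  )
  names(manifest$files) <- names(paths)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  manifest
}

#' @export
print.wm_pipeline <- function(x, ...) {
  cat("White-matter connectome topology pipeline\n")
  cat(sprintf("  discovery: %d patients / %d controls, %d nodes\n",
              x$config$n_patients, x$config$n_controls, x$config$n_nodes))
  cat("  group comparison:\n")
  print(dplyr::select(x$comparison, "metric", "test_used", "statistic",
                      "p_bonferroni", "estimate"))
  cat("  symptom correlation:\n")
  print(x$correlation)
  print(x$prediction)
  if (!is.null(x$classification)) print(x$classification)
  invisible(x)
}
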