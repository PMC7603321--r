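# Synthetic cohorts: toy masks, small-world subject networks, phenotypes.

#' Cohort specification
#'
#' Collects the generator parameters for a synthetic case-control cohort.
#' Defaults mirror the discovery-sample design the analysis targets:
#' 91 patients vs 225 controls, 128 network nodes, 242 timepoints, a patient
#' shift toward network randomization, and symptom scores (HAMD-like,
#' mean 22.3, SD about 4, floor 8) negatively coupled to network clustering.
#'
#' @param n_patients,n_controls Group sizes.
#' @param n_nodes Nodes per network (default 128).
#' @param n_timepoints Timepoints when rendering voxel series (default 242).
#' @param randomization_shift Extra rewiring probability added for patients,
#'   in \[0, 1\] (default 0.4).
#' @param symptom_effect Slope linking standardized network clustering to the
#'   symptom score; negative values plant the expected negative correlation
#'   (default -2.5 score points per clustering SD).
#' @param noise_sd SD of the symptom-score noise (default 3; with the default
#'   slope the score SD is close to 4).
#' @param fc_noise_sd SD of the additive connectivity estimation noise
#'   applied to every node pair of a subject's observed matrix. The default
#'   `NULL` uses `1 / sqrt(n_timepoints - 3)`, the sampling SD of a Fisher-z
#'   correlation estimate at the configured scan length, so the observed
#'   matrices are dense and noisy like empirical functional connectivity.
#'   Set to 0 for noise-free structural matrices.
#' @param base_rewiring Control-group rewiring probability (default 0.2,
#'   in the small-world regime).
#' @param rewiring_jitter_sd SD of per-subject jitter on the rewiring
#'   probability, emulating inter-individual topology variability
#'   (default 0.12; clipped to \[0, 1\]).
#' @param patient_jitter_sd Rewiring jitter SD for patients (default 0.2,
#'   wider than controls): clinical cohorts are heterogeneous in disease
#'   expression, with some patients near control-like topology and others
#'   heavily randomized. The spread also makes per-patient clustering vary
#'   enough for the planted clustering-symptom coupling to be recoverable
#'   from the measured features.
#' @param shortcut_strength Relative weight of long-range (rewired)
#'   connections (default 5). Values above 1 make the long-range edges the
#'   strongest in the matrix, so they survive proportional thresholding at
#'   every sparsity and keep characteristic path length near the random
#'   limit in both groups — mirroring empirical functional connectomes,
#'   where long-range (e.g. homotopic) connections are among the strongest
#'   and path length differs little between groups while clustering does.
#' @param k_ring Even ring-lattice degree; `NULL` (default) picks the
#'   smallest even degree giving edge density above 0.3, so proportional
#'   thresholds up to 0.3 are always attainable.
#' @param rng_seed Root seed; all generator randomness derives from it.
#' @return A list of class `wm_cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 91, n_controls = 225, n_nodes = 128,
                        n_timepoints = 242, randomization_shift = 0.4,
                        symptom_effect = -2.5, noise_sd = 3,
                        fc_noise_sd = NULL,
                        base_rewiring = 0.2, rewiring_jitter_sd = 0.12,
                        patient_jitter_sd = 0.2, shortcut_strength = 5,
                        k_ring = NULL, rng_seed = 1) {
  stopifnot(n_patients >= 1, n_controls >= 1, n_nodes >= 8, n_timepoints >= 1,
            randomization_shift >= 0, randomization_shift <= 1,
            noise_sd >= 0, is.null(fc_noise_sd) || fc_noise_sd >= 0,
            base_rewiring >= 0, base_rewiring <= 1,
            rewiring_jitter_sd >= 0, patient_jitter_sd >= 0,
            shortcut_strength > 0)
  structure(list(
    n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
    n_nodes = as.integer(n_nodes), n_timepoints = as.integer(n_timepoints),
    randomization_shift = randomization_shift,
    symptom_effect = symptom_effect, noise_sd = noise_sd,
    fc_noise_sd = fc_noise_sd,
    base_rewiring = base_rewiring, rewiring_jitter_sd = rewiring_jitter_sd,
    patient_jitter_sd = patient_jitter_sd,
    shortcut_strength = shortcut_strength,
    k_ring = k_ring, rng_seed = as.integer(rng_seed)
  ), class = "wm_cohort_spec")
}

# Normalized ring distance matrix: circular node distance scaled to [0, 1].
ring_distance <- function(n) {
  i <- matrix(seq_len(n), n, n)
  d <- abs(i - t(i))
  pmin(d, n - d) / (n / 2)
}

default_k_ring <- function(n_nodes) {
  # smallest even k with k/(n-1) > 0.3
  k <- 2 * ceiling(0.3 * (n_nodes - 1) / 2 + .Machine$double.eps)
  while (k / (n_nodes - 1) <= 0.3) k <- k + 2
  min(k, 2 * floor((n_nodes - 1) / 2))
}

#' Connected toy voxel mask
#'
#' Grows a single connected random blob covering approximately
#' `fill_fraction` of a 3D grid, as a stand-in for a group-level
#' white-matter mask.
#'
#' @param shape Integer vector of 3 grid dimensions.
#' @param fill_fraction Fraction of the grid to fill, in (0, 1].
#' @param seed Integer seed.
#' @param connectivity Voxel neighborhood (6, 18 or 26).
#' @return 3D logical array, connected under `connectivity`.
#' @export
make_toy_mask <- function(shape, fill_fraction = 1, seed = NULL,
                          connectivity = 26) {
  stopifnot(length(shape) == 3, all(shape >= 1),
            fill_fraction > 0, fill_fraction <= 1)
  shape <- as.integer(shape)
  n_total <- prod(shape)
  n_target <- max(1L, round(fill_fraction * n_total))
  if (n_target > n_total) {
    stop("grid cannot host ", n_target, " voxels", call. = FALSE)
  }
  mask <- array(TRUE, shape)
  if (n_target == n_total) return(mask)
  mask[] <- FALSE
  offs <- neighbor_offsets(connectivity)
  with_seed_(seed, {
    start <- sample.int(n_total, 1)
    mask[start] <- TRUE
    frontier <- start
    n_in <- 1L
    while (n_in < n_target) {
      frontier <- frontier[!duplicated(frontier)]
      # candidate neighbors of a randomly drawn frontier voxel
      v <- frontier[sample.int(length(frontier), 1)]
      ci <- arrayInd(v, shape)
      nc <- sweep(offs, 2, as.integer(ci), "+")
      ok <- nc[, 1] >= 1 & nc[, 1] <= shape[1] &
            nc[, 2] >= 1 & nc[, 2] <= shape[2] &
            nc[, 3] >= 1 & nc[, 3] <= shape[3]
      lin <- nc[ok, 1] + (nc[ok, 2] - 1L) * shape[1] +
             (nc[ok, 3] - 1L) * shape[1] * shape[2]
      new <- lin[!mask[lin]]
      if (length(new)) {
        add <- new[sample.int(length(new), 1)]
        mask[add] <- TRUE
        n_in <- n_in + 1L
        frontier <- c(frontier, add)
      } else {
        frontier <- frontier[frontier != v]
        if (!length(frontier)) {
          # blob is boxed in; restart frontier from all boundary voxels
          frontier <- which(mask)
        }
      }
    }
  })
  mask
}

#' Weighted small-world subject network
#'
#' Builds one subject's weighted connectivity matrix from a ring lattice with
#' Watts-Strogatz random rewiring: each lattice edge is, with probability
#' `rewiring_prob`, detached at its far endpoint and reattached to a uniform
#' random non-neighbor. Higher rewiring lowers expected clustering while path
#' length stays near the random limit — the "shift toward randomization"
#' phenotype. Edge weights are i.i.d. lognormal(0, 0.5) scaled to (0, 1],
#' i.e. positive and right-skewed like Fisher-z connectivity magnitudes;
#' optionally, long-range (rewired) edges are strengthened by a constant
#' factor (see `shortcut_strength` in [cohort_spec()]).
#'
#' @param n_nodes Number of nodes (>= 8).
#' @param rewiring_prob Rewiring probability in \[0, 1\].
#' @param k_ring Even lattice degree (default: density just above 0.3, see
#'   [cohort_spec()]).
#' @param seed Integer seed.
#' @param shortcut_strength Weight multiplier for edges outside the lattice
#'   neighborhood (default 1: plain Watts-Strogatz weights).
#' @return N x N symmetric nonnegative matrix, zero diagonal.
#' @export
simulate_subject_network <- function(n_nodes, rewiring_prob, k_ring = NULL,
                                     seed = NULL, shortcut_strength = 1) {
  stopifnot(n_nodes >= 8, rewiring_prob >= 0, rewiring_prob <= 1)
  k_ring <- k_ring %||% default_k_ring(n_nodes)
  stopifnot(k_ring %% 2 == 0, k_ring >= 2, k_ring < n_nodes)
  half <- k_ring / 2
  n <- n_nodes
  with_seed_(seed, {
    a <- matrix(FALSE, n, n)
    for (d in seq_len(half)) {
      j <- (seq_len(n) - 1 + d) %% n + 1
      a[cbind(seq_len(n), j)] <- TRUE
      a[cbind(j, seq_len(n))] <- TRUE
    }
    # Watts-Strogatz rewiring, lattice offsets in fixed order
    for (d in seq_len(half)) {
      for (i in seq_len(n)) {
        j <- (i - 1 + d) %% n + 1
        if (!a[i, j]) next  # already rewired away
        if (stats::runif(1) < rewiring_prob) {
          cand <- which(!a[i, ] & seq_len(n) != i)
          if (!length(cand)) next
          jj <- cand[sample.int(length(cand), 1)]
          a[i, j] <- a[j, i] <- FALSE
          a[i, jj] <- a[jj, i] <- TRUE
        }
      }
    }
    ui <- upper_index(n)
    sel <- ui[a[ui]]
    wt <- exp(stats::rnorm(length(sel), 0, 0.5))
    wt <- wt / max(wt)
    if (shortcut_strength != 1) {
      rd <- ring_distance(n) * (n / 2)
      wt <- wt * ifelse(rd[sel] > half, shortcut_strength, 1)
    }
    w <- matrix(0, n, n)
    w[sel] <- wt
    w + t(w)
  })
}

#' Simulate a complete synthetic cohort
#'
#' Generates per-subject weighted networks and a phenotype table with the
#' statistical structure the downstream analysis assumes: patients' networks
#' are rewired with probability `base_rewiring + randomization_shift`
#' (controls: `base_rewiring`), each subject's rewiring probability receives
#' Gaussian jitter, and patients' symptom scores are affine in their
#' network's standardized weighted clustering plus noise, shifted to mean
#' 22.3 and clipped to \[8, 52\].
#'
#' Phenotype covariates (age, sex, education, mean framewise displacement)
#' are drawn to match the reference cohort's group summaries and are
#' independent of topology, so covariate adjustment is exercised without
#' confounding by construction.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `wm_cohort` with elements `networks` (named list
#'   of matrices), `phenotypes` (tibble: `subject_id`, `group`, `age`, `sex`,
#'   `education`, `mean_fd`, `hamd` — `NA` for controls), and `internals`
#'   (tibble of planted per-subject rewiring probability and the weighted
#'   clustering of the plain noise-free network — the segregation level the
#'   symptom model couples to — for calibration checks).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "wm_cohort_spec"))
  np <- spec$n_patients; nc <- spec$n_controls
  n_sub <- np + nc
  ids <- sprintf("s%03d", seq_len(n_sub))
  group <- c(rep("patient", np), rep("control", nc))
  k_ring <- spec$k_ring %||% default_k_ring(spec$n_nodes)

  p_group <- ifelse(group == "patient",
                    spec$base_rewiring + spec$randomization_shift,
                    spec$base_rewiring)
  jit <- ifelse(group == "patient", spec$patient_jitter_sd,
                spec$rewiring_jitter_sd)
  p_sub <- with_seed_(derive_seed(spec$rng_seed, 1), {
    pmin(pmax(p_group + stats::rnorm(n_sub, 0, jit), 0), 1)
  })

  fc_noise <- spec$fc_noise_sd %||% (1 / sqrt(max(spec$n_timepoints - 3, 4)))
  # plain Watts-Strogatz nets first: their clustering is the subject's
  # segregation level, to which the symptom model couples; the long-range
  # strengthening is applied afterwards
  plain_nets <- lapply(seq_len(n_sub), function(i) {
    simulate_subject_network(spec$n_nodes, p_sub[i], k_ring,
                             seed = derive_seed(spec$rng_seed, 100 + i))
  })
  rd_lattice <- ring_distance(spec$n_nodes) * (spec$n_nodes / 2) <= k_ring / 2
  true_nets <- lapply(plain_nets, function(w) {
    w * ifelse(rd_lattice, 1, spec$shortcut_strength)
  })
  # observed connectivity = planted structure + dense estimation noise,
  # mimicking Fisher-z sampling error at the configured scan length
  networks <- lapply(seq_len(n_sub), function(i) {
    w <- true_nets[[i]]
    if (fc_noise > 0) {
      nn <- spec$n_nodes
      e <- matrix(0, nn, nn)
      e[upper.tri(e)] <- with_seed_(
        derive_seed(spec$rng_seed, 5000 + i),
        stats::rnorm(nn * (nn - 1) / 2, 0, fc_noise)
      )
      w <- w + e + t(e)
      diag(w) <- 0
    }
    w
  })
  names(networks) <- ids
  cp <- vapply(plain_nets, function(w) as.numeric(weighted_clustering(w)),
               numeric(1))

  phen <- with_seed_(derive_seed(spec$rng_seed, 2), {
    is_pat <- group == "patient"
    age <- ifelse(is_pat, stats::rnorm(n_sub, 36.9, 11.5),
                  stats::rnorm(n_sub, 39.5, 15.9))
    age <- pmin(pmax(age, 18), 65)
    sex <- ifelse(stats::runif(n_sub) < ifelse(is_pat, 62 / 91, 148 / 225),
                  "female", "male")
    edu <- ifelse(is_pat, stats::rnorm(n_sub, 12.5, 3.7),
                  stats::rnorm(n_sub, 13.0, 3.9))
    edu <- pmin(pmax(edu, 6), 22)
    fd <- stats::rlnorm(n_sub, log(0.12), 0.4)
    tibble::tibble(subject_id = ids, group = group, age = age, sex = sex,
                   education = edu, mean_fd = fd)
  })

  hamd <- rep(NA_integer_, n_sub)
  if (np >= 1) {
    cp_pat <- cp[seq_len(np)]
    cnorm <- if (np > 1 && stats::sd(cp_pat) > 0) {
      as.numeric(scale(cp_pat))
    } else {
      rep(0, np)
    }
    raw <- with_seed_(derive_seed(spec$rng_seed, 3), {
      22.3 + spec$symptom_effect * cnorm + stats::rnorm(np, 0, spec$noise_sd)
    })
    if (mean(raw < 8) > 0.25) {
      stop("symptom model cannot satisfy the score floor of 8 at this ",
           "noise level", call. = FALSE)
    }
    hamd[seq_len(np)] <- as.integer(pmin(pmax(round(raw), 8), 52))
  }
  phen$hamd <- hamd

  structure(list(
    networks = networks,
    phenotypes = phen,
    internals = tibble::tibble(subject_id = ids, group = group,
                               rewiring_prob = p_sub,
                               clustering = unname(cp)),
    spec = spec
  ), class = "wm_cohort")
}

#' @export
print.wm_cohort <- function(x, ...) {
  cat("Synthetic cohort:", x$spec$n_patients, "patients,",
      x$spec$n_controls, "controls;", x$spec$n_nodes, "nodes\n")
  cat("Patient rewiring:", x$spec$base_rewiring, "+",
      x$spec$randomization_shift, " symptom slope:", x$spec$symptom_effect,
      "\n")
  invisible(x)
}

#' Render a network as voxel time series
#'
#' Turns a target connectivity matrix into a 4D voxel series on a labeled
#' mask: node-level latent signals are drawn from a multivariate normal whose
#' correlation matches the (rescaled, positive-definite-corrected) target,
#' every voxel of a parcel shares its node's latent signal, and i.i.d.
#' Gaussian voxel noise is added. This exercises the full
#' parcellation-to-connectivity path; the empirical node correlation matrix
#' converges to the target as timepoints increase.
#'
#' @param w N x N symmetric weight matrix (the target structure).
#' @param labels Label array from [grow_parcels()] with N parcels.
#' @param n_timepoints Number of volumes to render.
#' @param noise_sd Per-voxel noise SD (latent signals have unit SD).
#' @param target_scale Maximum off-diagonal target correlation (default 0.6).
#' @param seed Integer seed.
#' @return 4D numeric array (x, y, z, time); the realized node-level target
#'   correlation matrix is attached as attribute `target_cor`.
#' @export
render_voxel_series <- function(w, labels, n_timepoints, noise_sd = 0.5,
                                target_scale = 0.6, seed = NULL) {
  assert_square_symmetric(w, "weight matrix")
  n <- nrow(w)
  n_lab <- attr(labels, "n_nodes") %||% max(labels)
  if (n_lab != n) stop("labels have ", n_lab, " parcels but w has ", n,
                       " nodes", call. = FALSE)
  r <- w / max(w) * target_scale
  diag(r) <- 1
  # project to the nearest well-conditioned correlation matrix
  eg <- eigen(r, symmetric = TRUE)
  ev <- pmax(eg$values, 1e-6)
  r <- eg$vectors %*% diag(ev) %*% t(eg$vectors)
  r <- stats::cov2cor(r)
  dm <- dim(labels)
  lab <- as.integer(labels)
  vox <- which(lab > 0L)
  with_seed_(seed, {
    x <- matrix(stats::rnorm(n_timepoints * n), n_timepoints, n) %*% chol(r)
    bold <- array(0, c(dm, n_timepoints))
    flat <- matrix(0, prod(dm), n_timepoints)
    flat[vox, ] <- t(x[, lab[vox], drop = FALSE]) +
      stats::rnorm(length(vox) * n_timepoints, 0, noise_sd)
    bold[] <- flat
    attr(bold, "target_cor") <- r
    bold
  })
}
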