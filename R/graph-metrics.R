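# Weighted small-world metrics, degree-preserving nulls, AUC summaries.

#' Mean weighted clustering coefficient
#'
#' Per-node triangle intensity on a nonnegative weighted graph, averaged over
#' nodes. The default is the Onnela geometric-mean form: with weights scaled
#' by the matrix maximum, node i scores
#' `sum_{j,h} (w_ij w_ih w_jh)^(1/3) / (k_i (k_i - 1))`
#' where k_i is the binary degree; nodes with degree < 2 contribute 0. The
#' Barrat (arithmetic-mean) form is available as an alternative.
#'
#' @param w N x N symmetric nonnegative weight matrix, zero diagonal.
#' @param variant `"onnela"` (default) or `"barrat"`.
#' @param normalize Divide weights by the matrix maximum first (default TRUE;
#'   puts per-node values in \[0, 1\] for the Onnela form).
#' @return Mean clustering coefficient (scalar); per-node values in attribute
#'   `per_node`.
#' @export
weighted_clustering <- function(w, variant = c("onnela", "barrat"),
                                normalize = TRUE) {
  variant <- match.arg(variant)
  assert_square_symmetric(w, "weight matrix")
  if (any(w < 0)) stop("weights must be nonnegative", call. = FALSE)
  a <- (w > 0) * 1
  k <- rowSums(a)
  mx <- max(w)
  if (mx == 0) {
    out <- 0
    attr(out, "per_node") <- rep(0, nrow(w))
    return(out)
  }
  if (normalize) w <- w / mx
  if (variant == "onnela") {
    m <- w^(1 / 3)
    tri <- diag(m %*% m %*% m)
    ci <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  } else {
    s <- rowSums(w)
    a2 <- a %*% a
    term <- rowSums(w * a2 * a)
    ci <- ifelse(k >= 2, term / (s * (k - 1)), 0)
  }
  out <- mean(ci)
  attr(out, "per_node") <- ci
  out
}

#' Characteristic path length
#'
#' Mean weighted shortest-path distance over node pairs, with edge length
#' defined as the inverse weight (strong connections are short). By default
#' unreachable pairs are excluded from the mean (the reachable-pair fraction
#' is attached); the harmonic alternative averages inverse distances
#' (efficiency-style), where unreachable pairs contribute zero.
#'
#' @inheritParams weighted_clustering
#' @param disconnected `"exclude"` (default) or `"harmonic"`.
#' @return Scalar path length with attribute `reachable_fraction`.
#' @export
char_path_length <- function(w, disconnected = c("exclude", "harmonic")) {
  disconnected <- match.arg(disconnected)
  assert_square_symmetric(w, "weight matrix")
  if (any(w < 0)) stop("weights must be nonnegative", call. = FALSE)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) == 0) stop("graph has no edges", call. = FALSE)
  cpl_from_graph(g, igraph::E(g)$weight, disconnected)
}

# Characteristic path length from an igraph object plus edge weights.
cpl_from_graph <- function(g, weights, disconnected = "exclude") {
  d <- igraph::distances(g, weights = 1 / weights)
  off <- d[upper.tri(d)]
  reach <- mean(is.finite(off))
  if (disconnected == "exclude") {
    fin <- off[is.finite(off)]
    if (!length(fin)) stop("all node pairs are disconnected", call. = FALSE)
    lp <- mean(fin)
  } else {
    lp <- 1 / mean(ifelse(is.finite(off), 1 / off, 0))
  }
  attr(lp, "reachable_fraction") <- reach
  lp
}

# Onnela clustering from an edge list (1-based, i<j) and weights already
# divided by their maximum; k is the binary degree vector.
onnela_from_edges <- function(n, el, wn) {
  m <- matrix(0, n, n)
  m[el] <- wn^(1 / 3)
  m <- m + t(m)
  k <- tabulate(el, nbins = n)
  tri <- diag(m %*% m %*% m)
  ci <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  mean(ci)
}

#' Degree-preserving null ensemble
#'
#' Reference values of clustering and path length from random networks
#' matched to the input: each null rewires the binary topology by
#' Maslov-Sneppen pairwise edge swaps (default 10 swap attempts per edge,
#' rejecting self-loops and multi-edges, so every node keeps its degree
#' exactly), then reassigns the original weights to the rewired edges in
#' random order. Means over the ensemble give the denominators of the
#' normalized small-world metrics.
#'
#' @inheritParams weighted_clustering
#' @param n_nulls Number of null networks (default 100).
#' @param seed Integer seed for the rewiring/permutation stream.
#' @param swaps_per_edge Swap attempts per edge (default 10).
#' @inheritParams char_path_length
#' @return A list with `cp_rand` and `lp_rand` (ensemble means) plus
#'   per-null vectors `cp` and `lp`.
#' @export
null_ensemble <- function(w, n_nulls = 100, seed = NULL, swaps_per_edge = 10,
                          variant = c("onnela", "barrat"), normalize = TRUE,
                          disconnected = c("exclude", "harmonic")) {
  variant <- match.arg(variant)
  disconnected <- match.arg(disconnected)
  assert_square_symmetric(w, "weight matrix")
  stopifnot(n_nulls >= 1)
  n <- nrow(w)
  g <- igraph::graph_from_adjacency_matrix((w > 0) * 1, mode = "undirected",
                                           diag = FALSE)
  m <- igraph::ecount(g)
  if (m < 2) stop("need at least 2 edges to rewire", call. = FALSE)
  ui <- upper_index(n)
  wt <- w[ui][w[ui] > 0]
  wt_scaled <- if (normalize) wt / max(wt) else wt
  res <- with_seed_(seed, {
    cp <- lp <- numeric(n_nulls)
    for (i in seq_len(n_nulls)) {
      gr <- igraph::rewire(g, igraph::keeping_degseq(niter = swaps_per_edge * m))
      el <- igraph::as_edgelist(gr, names = FALSE)
      perm <- sample.int(m)
      if (variant == "onnela") {
        cp[i] <- onnela_from_edges(n, el, wt_scaled[perm])
      } else {
        wn <- matrix(0, n, n)
        wn[el] <- wt[perm]
        wn <- wn + t(wn)
        cp[i] <- as.numeric(weighted_clustering(wn, variant, normalize))
      }
      lp[i] <- as.numeric(cpl_from_graph(gr, wt[perm], disconnected))
    }
    list(cp = cp, lp = lp)
  })
  list(cp_rand = mean(res$cp), lp_rand = mean(res$lp),
       cp = res$cp, lp = res$lp)
}

#' Small-world metrics at one sparsity
#'
#' Computes raw clustering Cp and path length Lp, their null-ensemble means,
#' and the normalized metrics gamma = Cp/Cp_rand, lambda = Lp/Lp_rand and
#' sigma = gamma/lambda. A network is small-world when gamma > 1 with
#' lambda close to 1, i.e. sigma > 1.
#'
#' @inheritParams null_ensemble
#' @return One-row tibble with columns `cp`, `lp`, `cp_rand`, `lp_rand`,
#'   `gamma`, `lambda`, `sigma`.
#' @export
small_world_point <- function(w, n_nulls = 100, seed = NULL,
                              variant = c("onnela", "barrat"),
                              normalize = TRUE,
                              disconnected = c("exclude", "harmonic"),
                              swaps_per_edge = 10) {
  variant <- match.arg(variant)
  disconnected <- match.arg(disconnected)
  cp <- as.numeric(weighted_clustering(w, variant, normalize))
  lp <- as.numeric(char_path_length(w, disconnected))
  nul <- null_ensemble(w, n_nulls = n_nulls, seed = seed,
                       swaps_per_edge = swaps_per_edge,
                       variant = variant, normalize = normalize,
                       disconnected = disconnected)
  if (nul$cp_rand <= 0 || nul$lp_rand <= 0) {
    stop("null ensemble mean is zero; cannot normalize", call. = FALSE)
  }
  gamma <- cp / nul$cp_rand
  lambda <- lp / nul$lp_rand
  tibble::tibble(cp = cp, lp = lp, cp_rand = nul$cp_rand,
                 lp_rand = nul$lp_rand, gamma = gamma, lambda = lambda,
                 sigma = gamma / lambda)
}

#' Area under a sparsity curve
#'
#' Trapezoidal integral of a metric over the sparsity axis, the
#' threshold-independent scalar summary used as a per-subject feature.
#'
#' @param sparsities Strictly increasing numeric vector (>= 2 points).
#' @param values Metric values matched to `sparsities`.
#' @return Scalar AUC.
#' @export
curve_auc <- function(sparsities, values) {
  stopifnot(length(sparsities) == length(values), length(sparsities) >= 2,
            all(diff(sparsities) > 0), all(is.finite(values)))
  sum(diff(sparsities) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
}

#' Small-world curves across a sparsity sweep
#'
#' @inheritParams small_world_point
#' @param z Connectivity matrix (e.g. Fisher-z FC).
#' @inheritParams sparsity_sweep
#' @return Long tibble with one row per sparsity: `sparsity`, `cp`, `lp`,
#'   `cp_rand`, `lp_rand`, `gamma`, `lambda`, `sigma`.
#' @export
topology_curves <- function(z, s_min = 0.1, s_max = 0.3, step = 0.01,
                            n_nulls = 100, seed = NULL,
                            negatives = c("signed", "absolute", "zero"),
                            variant = c("onnela", "barrat"),
                            normalize = TRUE,
                            disconnected = c("exclude", "harmonic"),
                            swaps_per_edge = 10) {
  negatives <- match.arg(negatives)
  graphs <- sparsity_sweep(z, s_min, s_max, step, negatives)
  ss <- round(seq(s_min, s_max, by = step), 10)
  purrr::map2_dfr(graphs, seq_along(graphs), function(g, i) {
    dplyr::bind_cols(
      tibble::tibble(sparsity = ss[i]),
      small_world_point(g, n_nulls = n_nulls, seed = derive_seed(seed, i),
                        variant = variant, normalize = normalize,
                        disconnected = disconnected,
                        swaps_per_edge = swaps_per_edge)
    )
  })
}

#' Per-subject AUC topology features
#'
#' Composes the sparsity sweep, per-sparsity small-world metrics and
#' trapezoidal AUC into the three per-subject features used throughout the
#' statistics and machine-learning stages.
#'
#' @inheritParams topology_curves
#' @param subject_id Optional subject identifier.
#' @return One-row tibble: `subject_id`, `gamma_auc`, `lambda_auc`,
#'   `sigma_auc`, with the full per-sparsity curves in attribute `curves`.
#' @export
subject_topology <- function(z, s_min = 0.1, s_max = 0.3, step = 0.01,
                             n_nulls = 100, seed = NULL, subject_id = NULL,
                             negatives = c("signed", "absolute", "zero"),
                             variant = c("onnela", "barrat"),
                             normalize = TRUE,
                             disconnected = c("exclude", "harmonic"),
                             swaps_per_edge = 10) {
  curves <- topology_curves(z, s_min, s_max, step, n_nulls, seed,
                            negatives, variant, normalize, disconnected,
                            swaps_per_edge)
  out <- tibble::tibble(
    subject_id = subject_id %||% attr(z, "subject_id") %||% NA_character_,
    gamma_auc = curve_auc(curves$sparsity, curves$gamma),
    lambda_auc = curve_auc(curves$sparsity, curves$lambda),
    sigma_auc = curve_auc(curves$sparsity, curves$sigma)
  )
  attr(out, "curves") <- curves
  out
}

#' Topology features for a whole cohort
#'
#' Applies [subject_topology()] to every subject's connectivity matrix.
#' Per-subject seeds are derived from the root seed and a hash of the subject
#' id, so results do not depend on subject order.
#'
#' @param networks Named list of connectivity matrices (names = subject ids).
#' @inheritParams subject_topology
#' @param keep_curves Keep per-subject curves in attribute `curves`
#'   (long tibble with a `subject_id` column)? Default FALSE.
#' @return Tibble with one row per subject: `subject_id`, `gamma_auc`,
#'   `lambda_auc`, `sigma_auc`.
#' @export
cohort_topology <- function(networks, s_min = 0.1, s_max = 0.3, step = 0.01,
                            n_nulls = 100, seed = NULL,
                            negatives = c("signed", "absolute", "zero"),
                            variant = c("onnela", "barrat"),
                            normalize = TRUE,
                            disconnected = c("exclude", "harmonic"),
                            swaps_per_edge = 10, keep_curves = FALSE) {
  stopifnot(is.list(networks), length(networks) >= 1)
  ids <- names(networks) %||% as.character(seq_along(networks))
  rows <- purrr::map2(networks, ids, function(z, id) {
    subject_topology(z, s_min, s_max, step, n_nulls,
                     seed = derive_seed(seed, id_hash(id)),
                     subject_id = id, negatives = negatives,
                     variant = variant, normalize = normalize,
                     disconnected = disconnected,
                     swaps_per_edge = swaps_per_edge)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "curves") <- NULL  # bind_rows can leak the first row's attribute
  if (keep_curves) {
    attr(out, "curves") <- dplyr::bind_rows(
      purrr::map2(rows, ids, function(r, id) {
        dplyr::mutate(attr(r, "curves"), subject_id = id, .before = 1)
      })
    )
  }
  out
}
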