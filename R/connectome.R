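# Node time series, Fisher-z connectivity, proportional thresholding.

#' Extract mean node time series
#'
#' Averages a 4D series over the voxels of each parcel, giving the node-level
#' signals from which connectivity is computed.
#'
#' @param bold 4D numeric array (x, y, z, time) whose spatial dimensions match
#'   `labels`.
#' @param labels Integer label array from [grow_parcels()].
#' @return A T x N numeric matrix (timepoints by nodes), columns named
#'   `"n<label>"`. Columns with zero variance are flagged in the logical
#'   attribute `zero_variance` and a warning is raised.
#' @export
extract_node_series <- function(bold, labels) {
  db <- dim(bold)
  if (length(db) != 4) stop("bold must be a 4D array", call. = FALSE)
  if (!identical(db[1:3], dim(labels))) {
    stop("bold spatial dimensions must match labels", call. = FALSE)
  }
  n_nodes <- attr(labels, "n_nodes") %||% max(labels)
  counts <- tabulate(labels[labels > 0L], nbins = n_nodes)
  if (any(counts == 0L)) {
    stop("empty node(s): ", paste(which(counts == 0L), collapse = ", "),
         call. = FALSE)
  }
  nt <- db[4]
  mat <- matrix(bold, nrow = prod(db[1:3]), ncol = nt)
  lab <- as.integer(labels)
  keep <- lab > 0L
  sums <- rowsum(mat[keep, , drop = FALSE], group = lab[keep])
  ts <- t(sums / counts)
  colnames(ts) <- paste0("n", seq_len(n_nodes))
  zv <- apply(ts, 2, stats::var) < .Machine$double.eps^0.5
  if (any(zv)) {
    warning("zero-variance node series: ",
            paste(colnames(ts)[zv], collapse = ", "), call. = FALSE)
  }
  attr(ts, "zero_variance") <- zv
  ts
}

#' Fisher-z functional connectivity matrix
#'
#' Pairwise Pearson correlation between node time series, variance-stabilized
#' with the Fisher r-to-z transform `atanh(r)`. Correlations are clipped to
#' +/-(1 - eps) beforehand so perfectly correlated series map to a large but
#' finite z. The diagonal is exactly zero.
#'
#' @param ts T x N matrix of node time series (T >= 3).
#' @param eps Clipping margin before `atanh` (default 1e-7).
#' @param on_zero_variance `"error"` (default) or `"drop"`: what to do with
#'   zero-variance columns; dropping removes the node with a warning.
#' @param subject_id Optional id stored as an attribute.
#' @return N x N symmetric numeric matrix of z values, zero diagonal.
#' @export
fc_matrix <- function(ts, eps = 1e-7,
                      on_zero_variance = c("error", "drop"),
                      subject_id = NULL) {
  on_zero_variance <- match.arg(on_zero_variance)
  if (!is.matrix(ts)) ts <- as.matrix(ts)
  if (nrow(ts) < 3) stop("need at least 3 timepoints", call. = FALSE)
  if (anyNA(ts)) stop("time series contain missing values", call. = FALSE)
  v <- apply(ts, 2, stats::var)
  zv <- v < .Machine$double.eps^0.5
  if (any(zv)) {
    if (on_zero_variance == "error") {
      stop("zero-variance column(s): ",
           paste(which(zv), collapse = ", "), call. = FALSE)
    }
    warning("dropping zero-variance column(s): ",
            paste(which(zv), collapse = ", "), call. = FALSE)
    ts <- ts[, !zv, drop = FALSE]
  }
  r <- stats::cor(ts)
  r <- pmin(pmax(r, -(1 - eps)), 1 - eps)
  z <- atanh(r)
  diag(z) <- 0
  dimnames(z) <- list(colnames(ts), colnames(ts))
  attr(z, "subject_id") <- subject_id
  z
}

#' Proportional sparsity threshold
#'
#' Keeps the strongest `round(sparsity * N(N-1)/2)` edges of a connectivity
#' matrix and zeroes the rest, preserving the surviving weights for weighted
#' graph analysis. Edges are ranked by signed value by default (the strongest
#' edges at sparsities up to 0.3 are overwhelmingly positive); surviving
#' negative weights are replaced by their absolute value so downstream
#' weighted metrics see nonnegative weights. Ties at the cut are broken by a
#' stable sort on (value, edge index), so the retained edge count is exact and
#' reproducible.
#'
#' @param z N x N symmetric matrix (e.g. from [fc_matrix()]).
#' @param sparsity Fraction of possible edges to keep, in (0, 1].
#' @param negatives Policy for negative entries: `"signed"` (rank by signed
#'   value, keep |w| of survivors; default), `"absolute"` (rank by |value|),
#'   or `"zero"` (discard negatives before ranking; the graph may then hold
#'   fewer than the nominal edge count).
#' @return N x N nonnegative weighted matrix with attribute `sparsity`.
#' @export
threshold_proportional <- function(z, sparsity,
                                   negatives = c("signed", "absolute", "zero")) {
  negatives <- match.arg(negatives)
  assert_square_symmetric(z, "connectivity matrix")
  stopifnot(sparsity > 0, sparsity <= 1)
  n <- nrow(z)
  ui <- upper_index(n)
  vals <- z[ui]
  m <- round(sparsity * n * (n - 1) / 2)
  rank_vals <- switch(negatives,
    signed = vals,
    absolute = abs(vals),
    zero = ifelse(vals > 0, vals, -Inf)
  )
  ord <- order(rank_vals, decreasing = TRUE)  # stable: ties fall back on index
  keep <- ord[seq_len(min(m, length(ord)))]
  if (negatives == "zero") keep <- keep[vals[keep] > 0]
  w <- matrix(0, n, n, dimnames = dimnames(z))
  kept_vals <- vals[keep]
  if (negatives != "zero") kept_vals <- abs(kept_vals)
  w[ui[keep]] <- kept_vals
  w <- w + t(w)
  structure(w, sparsity = sparsity)
}

#' Sparsity sweep
#'
#' Thresholds one connectivity matrix across a grid of sparsities
#' (default 0.10 to 0.30 in steps of 0.01, giving 21 graphs).
#'
#' @inheritParams threshold_proportional
#' @param s_min,s_max,step Sweep range and increment.
#' @return Named list of thresholded weight matrices, one per sparsity.
#' @export
sparsity_sweep <- function(z, s_min = 0.1, s_max = 0.3, step = 0.01,
                           negatives = c("signed", "absolute", "zero")) {
  negatives <- match.arg(negatives)
  stopifnot(s_min > 0, s_min <= s_max, s_max <= 1, step > 0)
  ss <- round(seq(s_min, s_max, by = step), 10)
  out <- lapply(ss, function(s) threshold_proportional(z, s, negatives))
  names(out) <- formatC(ss, format = "g")
  out
}
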