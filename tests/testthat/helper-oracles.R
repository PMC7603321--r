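# Independent brute-force oracles used to validate the fast implementations.
# These deliberately use naive O(N^3) loops and base-R flood fills, and must
# stay independent of the package's own code paths.

# Onnela-style weighted clustering by explicit triple enumeration.
brute_clustering_onnela <- function(w, normalize = TRUE) {
  n <- nrow(w)
  if (max(w) > 0 && normalize) w <- w / max(w)
  a <- w > 0
  ci <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(a[i, ])
    if (k < 2) next
    acc <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j != i && h != i && j != h && a[i, j] && a[i, h] && a[j, h]) {
          acc <- acc + (w[i, j] * w[i, h] * w[j, h])^(1 / 3)
        }
      }
    }
    ci[i] <- acc / (k * (k - 1))
  }
  mean(ci)
}

# Characteristic path length via Floyd-Warshall on 1/weight lengths,
# averaging finite off-diagonal distances.
brute_path_length <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  d[w > 0] <- 1 / w[w > 0]
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  off <- d[upper.tri(d)]
  mean(off[is.finite(off)])
}

# Flood fill over a voxel set: returns TRUE when the TRUE voxels of `vol`
# form a single connected component under the given neighborhood.
voxels_connected <- function(vol, connectivity = 26) {
  dm <- dim(vol)
  vox <- which(vol)
  if (!length(vox)) return(FALSE)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  offs <- switch(as.character(connectivity),
    "6" = offs[rowSums(abs(offs)) == 1, , drop = FALSE],
    "18" = offs[rowSums(abs(offs)) <= 2, , drop = FALSE],
    offs
  )
  seen <- array(FALSE, dm)
  stack <- vox[1]
  seen[vox[1]] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ci <- arrayInd(v, dm)
    for (r in seq_len(nrow(offs))) {
      nc <- ci + offs[r, ]
      if (any(nc < 1) || any(nc > dm)) next
      lin <- nc[1] + (nc[2] - 1) * dm[1] + (nc[3] - 1) * dm[1] * dm[2]
      if (vol[lin] && !seen[lin]) {
        seen[lin] <- TRUE
        stack <- c(stack, lin)
      }
    }
  }
  sum(seen) == sum(vol)
}

# Exact Mann-Whitney U (min convention) and two-sided p by complete
# enumeration of group assignments. Feasible for n1 + n2 <= 14.
enumerate_mann_whitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  u_stat <- function(xx, yy) sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  u1 <- u_stat(x, y)
  u_obs <- min(u1, n1 * n2 - u1)
  pool <- c(x, y)
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, function(ix) {
    uu <- u_stat(pool[ix], pool[-ix])
    min(uu, n1 * n2 - uu)
  })
  list(u = u_obs, p = mean(us <= u_obs))
}

# Deterministic random symmetric weight matrix with zero diagonal.
random_weight_matrix <- function(n, density = 0.5, seed = 1) {
  set.seed(seed)
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  vals <- stats::runif(sum(ut))
  vals[stats::runif(sum(ut)) > density] <- 0
  w[ut] <- vals
  w + t(w)
}

# Dense noisy symmetric matrix (FC-like), tie-free with probability 1.
random_fc_matrix <- function(n, seed = 1) {
  set.seed(seed)
  z <- matrix(stats::rnorm(n * n, 0, 0.3), n, n)
  z <- (z + t(z)) / 2
  diag(z) <- 0
  z
}
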