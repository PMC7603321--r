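# Random region-growing parcellation of a binary voxel mask.

neighbor_offsets <- function(connectivity = 26) {
  connectivity <- match.arg(as.character(connectivity), c("6", "18", "26"))
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- switch(connectivity,
    "6"  = rowSums(abs(g)) == 1,
    "18" = rowSums(abs(g)) <= 2,
    "26" = rep(TRUE, nrow(g))
  )
  g[keep, , drop = FALSE]
}

# Adjacency list over mask voxels: element i holds the in-mask voxel ids
# (1..n_voxels, in `which(mask)` order) adjacent to voxel i.
mask_adjacency <- function(mask, connectivity = 26) {
  dm <- dim(mask)
  vox <- which(mask)
  nv <- length(vox)
  id_of <- array(0L, dm)
  id_of[vox] <- seq_len(nv)
  coords <- arrayInd(vox, dm)
  offs <- neighbor_offsets(connectivity)
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nc <- sweep(coords, 2, offs[r, ], "+")
    ok <- nc[, 1] >= 1 & nc[, 1] <= dm[1] &
          nc[, 2] >= 1 & nc[, 2] <= dm[2] &
          nc[, 3] >= 1 & nc[, 3] <= dm[3]
    if (!any(ok)) next
    lin <- nc[ok, 1] + (nc[ok, 2] - 1L) * dm[1] + (nc[ok, 3] - 1L) * dm[1] * dm[2]
    nb <- id_of[lin]
    hit <- nb > 0L
    from <- c(from, which(ok)[hit])
    to <- c(to, nb[hit])
  }
  unname(split(to, factor(from, levels = seq_len(nv))))
}

# Connected components of a voxel mask; returns integer component label per
# in-mask voxel (which(mask) order).
mask_components <- function(mask, connectivity = 26) {
  adj <- mask_adjacency(mask, connectivity)
  nv <- length(adj)
  comp <- integer(nv)
  cur <- 0L
  for (s in seq_len(nv)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    stack <- s
    comp[s] <- cur
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      stack <- c(stack, new)
    }
  }
  comp
}

mask_is_connected <- function(mask, connectivity = 26) {
  if (sum(mask) == 0) return(FALSE)
  max(mask_components(mask, connectivity)) == 1L
}

#' Group-level mask from per-subject masks
#'
#' A voxel enters the group mask when it is inside the mask of at least
#' `overlap_fraction` of the subjects (the conventional 80% overlap rule for
#' group-level white-matter masks).
#'
#' @param masks List of 3D logical arrays, all of the same shape.
#' @param overlap_fraction Required fraction of subjects, in (0, 1].
#' @return A 3D logical array.
#' @export
group_mask <- function(masks, overlap_fraction = 0.8) {
  stopifnot(length(masks) >= 1, overlap_fraction > 0, overlap_fraction <= 1)
  dm <- dim(masks[[1]])
  if (length(dm) != 3) stop("masks must be 3D arrays", call. = FALSE)
  for (m in masks) {
    if (!identical(dim(m), dm)) stop("all masks must share one shape", call. = FALSE)
  }
  counts <- Reduce(`+`, lapply(masks, function(m) array(as.integer(m), dm)))
  out <- counts / length(masks) >= overlap_fraction
  dim(out) <- dm
  out
}

#' Random region-growing parcellation
#'
#' Subdivides a binary voxel mask into `n_nodes` contiguous parcels of
#' near-uniform size: `n_nodes` seed voxels are drawn uniformly without
#' replacement, then parcels grow one voxel at a time, always granting the
#' next voxel to the currently smallest parcel that still touches unlabeled
#' mask voxels, until the mask is exhausted. Ties (equally small parcels,
#' several candidate voxels) are broken by the seeded random stream, so runs
#' are reproducible.
#'
#' If the mask is disconnected and some component contains no seed voxel,
#' each orphan component is attached to the parcel with the nearest centroid
#' and a warning is raised.
#'
#' @param mask 3D logical array with at least `n_nodes` `TRUE` voxels.
#' @param n_nodes Number of parcels (the analysis default is 128).
#' @param seed Integer seed controlling seed-voxel placement and tie-breaks.
#' @param connectivity Voxel neighborhood: 6, 18 or 26 (default).
#' @return A 3D integer array of the same shape: 0 outside the mask, parcel
#'   labels 1..`n_nodes` inside. Attributes `n_nodes` and `connectivity` are
#'   attached.
#' @export
grow_parcels <- function(mask, n_nodes, seed = NULL, connectivity = 26) {
  dm <- dim(mask)
  if (length(dm) != 3) stop("mask must be a 3D array", call. = FALSE)
  vox <- which(mask)
  nv <- length(vox)
  if (n_nodes < 1) stop("n_nodes must be at least 1", call. = FALSE)
  if (nv < n_nodes) {
    stop("mask has ", nv, " voxels; cannot host ", n_nodes, " parcels",
         call. = FALSE)
  }
  adj <- mask_adjacency(mask, connectivity)
  lab <- with_seed_(seed, {
    lab <- integer(nv)
    seeds <- sample.int(nv, n_nodes)
    lab[seeds] <- seq_len(n_nodes)
    sizes <- rep(1L, n_nodes)
    frontier <- lapply(seeds, function(s) adj[[s]])
    n_left <- nv - n_nodes
    while (n_left > 0L) {
      ord <- order(sizes, sample.int(n_nodes))  # random tie-break among equals
      grew <- FALSE
      for (k in ord) {
        fr <- frontier[[k]]
        if (!length(fr)) next
        fr <- unique(fr[lab[fr] == 0L])
        if (!length(fr)) { frontier[[k]] <- fr; next }
        v <- if (length(fr) == 1L) fr else fr[sample.int(length(fr), 1L)]
        lab[v] <- k
        sizes[k] <- sizes[k] + 1L
        frontier[[k]] <- c(fr[fr != v], adj[[v]])
        n_left <- n_left - 1L
        grew <- TRUE
        break
      }
      if (!grew) {
        # disconnected remainder: attach orphan components to nearest parcel
        left <- which(lab == 0L)
        coords <- arrayInd(vox, dm)
        sub <- array(FALSE, dm)
        sub[vox[left]] <- TRUE
        comp <- mask_components(sub, connectivity)
        cent <- vapply(seq_len(n_nodes), function(k) {
          colMeans(coords[lab == k, , drop = FALSE])
        }, numeric(3))
        for (cid in seq_len(max(comp))) {
          members <- left[comp == cid]
          cc <- colMeans(coords[members, , drop = FALSE])
          d2 <- colSums((cent - cc)^2)
          lab[members] <- which.min(d2)
        }
        warning("mask is disconnected; ", length(left),
                " voxel(s) attached to nearest parcel by centroid distance",
                call. = FALSE)
        n_left <- 0L
      }
    }
    lab
  })
  out <- array(0L, dm)
  out[vox] <- lab
  structure(out, n_nodes = as.integer(n_nodes),
            connectivity = as.integer(connectivity))
}

#' Parcel size report
#'
#' Voxel counts per parcel plus their coefficient of variation, a quality
#' check on the near-uniform-size constraint of the region-growing rule.
#'
#' @param labels Integer label array from [grow_parcels()].
#' @return A tibble with columns `node` and `n_voxels`; the size coefficient
#'   of variation (SD/mean) is attached as attribute `cv`.
#' @export
parcel_size_report <- function(labels) {
  n_nodes <- attr(labels, "n_nodes") %||% max(labels)
  counts <- tabulate(labels[labels > 0L], nbins = n_nodes)
  cv <- if (mean(counts) > 0) stats::sd(counts) / mean(counts) else NA_real_
  if (n_nodes == 1L) cv <- 0
  out <- tibble::tibble(node = seq_len(n_nodes), n_voxels = counts)
  attr(out, "cv") <- cv
  out
}
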