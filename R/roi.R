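#' Extract the voxel time-series of one labeled region
#'
#' @param image4d 4-D array (x, y, z, t).
#' @param labelmap 3-D integer array on the same voxel grid.
#' @param region_code integer label of the region.
#' @return object of class `voxel_block`: `coords` (matrix of 0-based
#'   voxel indices, one row per voxel), `series` (voxels x volumes),
#'   `region_code`.
#' @export
extract_region_voxels <- function(image4d, labelmap, region_code) {
  di <- dim(image4d); dl <- dim(labelmap)
  if (length(di) != 4 || length(dl) != 3 || !all(di[1:3] == dl))
    stop("image and label map must share the voxel grid", call. = FALSE)
  idx <- which(labelmap == region_code, arr.ind = TRUE)
  if (nrow(idx) == 0)
    stop("region code ", region_code, " absent from label map", call. = FALSE)
  V <- di[4]
  flat <- matrix(image4d, prod(di[1:3]), V)
  lin <- (idx[, 3] - 1) * di[1] * di[2] + (idx[, 2] - 1) * di[1] + idx[, 1]
  series <- flat[lin, , drop = FALSE]
  structure(list(coords = unname(idx) - 1L, series = series,
                 region_code = region_code), class = "voxel_block")
}

#' Partition a voxel block into near-equal sub-regions by k-means
#'
#' K-means on spatial voxel coordinates, followed by greedy balancing:
#' voxels are reassigned from over-full clusters to the nearest
#' under-full cluster until no cluster exceeds `(1 + balance_tol)` times
#' the mean cluster size.  Ties in nearest-centroid assignment break
#' toward the lowest cluster index; the result is deterministic given
#' the seed.
#'
#' @param block a `voxel_block`.
#' @param k number of sub-regions (default 5).
#' @param seed RNG seed.
#' @param balance_tol allowed fractional deviation of the largest cluster
#'   from the mean size (default 0.25).
#' @return object of class `subregion_assignment`: `labels` (per-voxel
#'   cluster index in 1..k), `k`, `centers`.
#' @export
kmeans_subregions <- function(block, k = 5L, seed = 1L, balance_tol = 0.25) {
  coords <- block$coords
  n <- nrow(coords)
  if (n < k) stop("fewer voxels (", n, ") than clusters (", k, ")",
                  call. = FALSE)
  k <- as.integer(k)
  if (k == 1L) {
    return(structure(list(labels = rep(1L, n), k = 1L,
                          centers = matrix(colMeans(coords), 1)),
                     class = "subregion_assignment"))
  }
  set.seed(seed)
  km <- stats::kmeans(coords, centers = k, nstart = 25L, iter.max = 100L)
  labels <- km$cluster
  centers <- km$centers

  max_size <- (1 + balance_tol) * n / k
  repeat {
    sizes <- tabulate(labels, k)
    over <- which(sizes > max_size)
    if (!length(over)) break
    under <- which(sizes < n / k)
    if (!length(under)) under <- which(sizes <= max_size)
    # move the single voxel (from any over-full cluster) closest to an
    # under-full centroid; deterministic, lowest index wins ties
    best <- NULL
    for (o in over) {
      vox <- which(labels == o)
      for (u in under) {
        d <- rowSums((coords[vox, , drop = FALSE] -
                      matrix(centers[u, ], length(vox), ncol(coords),
                             byrow = TRUE))^2)
        j <- which.min(d)
        if (is.null(best) || d[j] < best$d - 1e-12) {
          best <- list(d = d[j], vox = vox[j], to = u)
        }
      }
    }
    labels[best$vox] <- best$to
    for (cl in seq_len(k)) {
      sel <- labels == cl
      if (any(sel)) centers[cl, ] <- colMeans(coords[sel, , drop = FALSE])
    }
  }
  # relabel clusters deterministically by centroid order
  ord <- do.call(order, as.data.frame(centers))
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  structure(list(labels = relabel[labels], k = k,
                 centers = centers[ord, , drop = FALSE]),
            class = "subregion_assignment")
}

#' Sub-region mean time-courses
#'
#' Per-cluster voxel-mean series, mean-centered per cluster (the
#' percent-change convention used throughout the package).
#'
#' @param block a `voxel_block`.
#' @param asg a `subregion_assignment` for the same block.
#' @return matrix k x volumes.
#' @export
subregion_timecourses <- function(block, asg) {
  if (length(asg$labels) != nrow(block$series))
    stop("assignment does not match block", call. = FALSE)
  out <- matrix(NA_real_, asg$k, ncol(block$series))
  for (cl in seq_len(asg$k)) {
    m <- colMeans(block$series[asg$labels == cl, , drop = FALSE])
    out[cl, ] <- m - mean(m)
  }
  out
}

#' Extract sub-region time-courses for every network region
#'
#' Convenience wrapper running [extract_region_voxels()],
#' [kmeans_subregions()] and [subregion_timecourses()] for each region
#' of a network over a rendered image/label-map pair.
#'
#' @param image4d 4-D array.
#' @param labelmap 3-D integer array.
#' @param region_codes named integer vector (abbrev -> label code).
#' @param k sub-regions per region.
#' @param seed RNG seed.
#' @return array regions x k x volumes with region dimnames.
#' @export
extract_all_subregions <- function(image4d, labelmap, region_codes, k = 5L,
                                   seed = 1L) {
  V <- dim(image4d)[4]
  out <- array(NA_real_, c(length(region_codes), k, V),
               dimnames = list(names(region_codes), NULL, NULL))
  for (i in seq_along(region_codes)) {
    blk <- extract_region_voxels(image4d, labelmap, region_codes[i])
    asg <- kmeans_subregions(blk, k = k, seed = seed + i)
    out[i, , ] <- subregion_timecourses(blk, asg)
  }
  out
}
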