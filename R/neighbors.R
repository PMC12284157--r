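# Spatial search primitives shared by the clustering and NND modules.
# Fixed-radius queries use a compiled uniform-grid index; kNN queries use the
# kd-tree in FNN. Brute-force counterparts live in the test helpers.

#' Fixed-radius neighbor counts
#'
#' Counts, for every point, the neighbors (self excluded) within `r` in xy;
#' when `z` is supplied the neighborhood is a cylinder with axial half-height
#' `rz` (default `2 * r`, matching the roughly two-fold larger axial spread
#' of localizations).
#'
#' @param x,y,z coordinate vectors in nm (`z` optional).
#' @param r lateral radius in nm.
#' @param rz axial half-window in nm (3D only).
#' @return integer vector of neighbor counts.
#' @export
radius_counts <- function(x, y, r, z = NULL, rz = 2 * r) {
  assert_scalar_pos(r, "r")
  use_z <- !is.null(z)
  if (!use_z) z <- numeric(0)
  cpp_radius_counts(as.numeric(x), as.numeric(y), as.numeric(z), r, rz, use_z)
}

#' Fixed-radius neighbor lists
#'
#' @inheritParams radius_counts
#' @return list of integer index vectors (1-based, self excluded).
#' @export
radius_neighbors <- function(x, y, r, z = NULL, rz = 2 * r) {
  assert_scalar_pos(r, "r")
  use_z <- !is.null(z)
  if (!use_z) z <- numeric(0)
  cpp_radius_neighbors(as.numeric(x), as.numeric(y), as.numeric(z), r, rz, use_z)
}

#' kth-nearest-neighbor distances
#'
#' Distances from each point to its 1st..kth nearest neighbors (self
#' excluded), via a kd-tree.
#'
#' @param coords numeric matrix (n x d), d = 2 or 3.
#' @param k maximum neighbor order.
#' @return n x k matrix of distances; column j holds the jth-NND.
#' @export
knn_distances <- function(coords, k) {
  coords <- as.matrix(coords)
  if (nrow(coords) < k + 1L) {
    stop(sprintf("need at least %d points for %d neighbor orders, got %d",
                 k + 1L, k, nrow(coords)))
  }
  FNN::get.knn(coords, k = k)$nn.dist
}

#' Density-based clustering (DBSCAN)
#'
#' Standard DBSCAN with `min_samples` counting the point itself (scikit-learn
#' semantics). With the package default `min_samples = 2`, one neighbor
#' within `eps` makes a core point, and the clusters coincide with the
#' connected components of the eps-adjacency graph - the permissive density
#' gating appropriate for RESI data where each molecule contributes a single
#' point. Border points join the cluster of their first discovered core
#' neighbor (deterministic in index order).
#'
#' @param coords numeric matrix (n x d).
#' @param eps neighborhood radius in nm.
#' @param min_samples minimum points (self included) for a core point.
#' @return integer vector of cluster labels; 0 denotes noise.
#' @export
dbscan_points <- function(coords, eps, min_samples = 2L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n == 0L) return(integer(0))
  assert_scalar_pos(eps, "eps")
  if (ncol(coords) >= 3L) {
    # true Euclidean 3D ball: reuse cylinder query with rz = eps, then filter
    nb <- cpp_radius_neighbors(coords[, 1], coords[, 2], coords[, 3],
                               eps, eps, TRUE)
    nb <- lapply(seq_len(n), function(i) {
      js <- nb[[i]]
      if (!length(js)) return(js)
      d2 <- (coords[js, 1] - coords[i, 1])^2 +
        (coords[js, 2] - coords[i, 2])^2 +
        (coords[js, 3] - coords[i, 3])^2
      js[d2 <= eps^2]
    })
  } else {
    nb <- cpp_radius_neighbors(coords[, 1], coords[, 2], numeric(0),
                               eps, eps, FALSE)
  }
  core <- (lengths(nb) + 1L) >= min_samples
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[[i]]
    while (length(queue)) {
      j <- queue[[1]]
      queue <- queue[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, nb[[j]][labels[nb[[j]]] == 0L])
      }
    }
  }
  labels
}
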