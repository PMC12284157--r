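# Two-target co-clustering, stoichiometry/ratio analysis and kth-NND
# profiling of RESI localizations.

point_matrix <- function(points, use_z = FALSE) {
  points <- data.table::as.data.table(points)
  if (use_z && "z" %in% names(points)) {
    cbind(points$x, points$y, points$z)
  } else {
    cbind(points$x, points$y)
  }
}

#' Two-target DBSCAN co-clustering
#'
#' Pools the ALFA (antibody) and GFP (receptor) RESI localizations, runs
#' DBSCAN at radius `eps`, discards noise, and keeps only clusters containing
#' at least `min_alfa` ALFA and `min_gfp` GFP localizations (per-target count
#' filters are applied after clustering, not as DBSCAN parameters).
#' Distances are 2D unless `use_z = TRUE`.
#'
#' @param alfa,gfp RESI localization tables (need columns x, y, optionally z)
#'   in the same coordinate frame.
#' @param eps DBSCAN radius in nm (default 40).
#' @param min_samples DBSCAN core threshold, self included (default 2: one
#'   neighbor within eps suffices; RESI has one point per molecule so density
#'   gating must be permissive).
#' @param min_alfa,min_gfp per-target minimum counts for a cluster to be kept.
#' @param use_z cluster in 3D.
#' @return list: `clusters` (data.table: cluster_id, n_alfa, n_gfp, per-target
#'   centers of mass com_alfa_* / com_gfp_*), `points` (pooled table with
#'   target_id and cluster_id; 0 = discarded).
#' @export
dbscan_cocluster <- function(alfa, gfp, eps = 40, min_samples = 2L,
                             min_alfa = 1L, min_gfp = 1L, use_z = FALSE) {
  alfa <- data.table::as.data.table(alfa)
  gfp <- data.table::as.data.table(gfp)
  keep <- intersect(intersect(names(alfa), names(gfp)),
                    c("x", "y", "z"))
  pooled <- rbind(alfa[, keep, with = FALSE], gfp[, keep, with = FALSE])
  pooled[, target_id := rep(c("ALFA", "GFP"), c(nrow(alfa), nrow(gfp)))]
  if (nrow(pooled) == 0L) {
    return(list(clusters = data.table::data.table(
      cluster_id = integer(0), n_alfa = integer(0), n_gfp = integer(0)),
      points = pooled))
  }
  labels <- dbscan_points(point_matrix(pooled, use_z), eps = eps,
                          min_samples = min_samples)
  pooled[, cluster_id := labels]
  has_z <- use_z && "z" %in% names(pooled)
  summ <- pooled[cluster_id > 0L, {
    a <- target_id == "ALFA"
    g <- !a
    row <- list(n_alfa = sum(a), n_gfp = sum(g),
                com_alfa_x = mean(x[a]), com_alfa_y = mean(y[a]),
                com_gfp_x = mean(x[g]), com_gfp_y = mean(y[g]))
    if (has_z) {
      row <- c(row, list(com_alfa_z = mean(z[a]), com_gfp_z = mean(z[g])))
    }
    row
  }, by = cluster_id]
  summ <- summ[n_alfa >= min_alfa & n_gfp >= min_gfp]
  pooled[!cluster_id %in% summ$cluster_id, cluster_id := 0L]
  data.table::setorder(summ, cluster_id)
  list(clusters = summ[], points = pooled[])
}

#' Single-target DBSCAN cluster analysis
#'
#' DBSCAN on one RESI channel (radius 20 nm, at least `min_size` molecules
#' per cluster by default); non-clustered molecules are discarded. The
#' cluster-size frequency table and the cluster density feed the chain
#' simulator as its fixed, experimentally determined parameters.
#'
#' @param points RESI localization table (x, y, optionally z).
#' @param eps DBSCAN radius in nm (default 20).
#' @param min_size minimum molecules per kept cluster (default 2).
#' @param fov field of view in nm, used for the cluster-density estimate;
#'   defaults to the bounding box.
#' @param use_z cluster in 3D.
#' @return list: `labels` (per input point; 0 = discarded), `sizes`
#'   (per-cluster size), `size_freq` (data.table size/count/prob),
#'   `density_um2` (clusters per square micrometer), `n_clusters`.
#' @export
dbscan_single_target <- function(points, eps = 20, min_size = 2L, fov = NULL,
                                 use_z = FALSE) {
  points <- data.table::as.data.table(points)
  if (nrow(points) == 0L) {
    return(list(labels = integer(0), sizes = integer(0),
                size_freq = data.table::data.table(size = integer(0),
                                                   count = integer(0),
                                                   prob = numeric(0)),
                density_um2 = 0, n_clusters = 0L))
  }
  labels <- dbscan_points(point_matrix(points, use_z), eps = eps,
                          min_samples = 2L)
  tab <- table(labels[labels > 0L])
  small <- as.integer(names(tab)[tab < min_size])
  labels[labels %in% small] <- 0L
  sizes <- as.integer(table(labels[labels > 0L]))
  if (is.null(fov)) {
    fov <- c(diff(range(points$x)), diff(range(points$y)))
  }
  if (length(fov) == 1L) fov <- c(fov, fov)
  area <- prod(fov) / 1e6
  sf <- data.table::as.data.table(table(size = sizes))
  sf[, size := as.integer(as.character(size))]
  data.table::setnames(sf, "N", "count")
  sf[, prob := count / sum(count)]
  list(labels = labels, sizes = sizes, size_freq = sf[],
       density_um2 = length(sizes) / area, n_clusters = length(sizes))
}

#' Stoichiometry (ratio) analysis of co-clusters
#'
#' Per co-cluster, the antibody count is `n_alfa / 2` (two ALFA sites per
#' antibody) and is regressed on the GFP count by ordinary least squares.
#' The slope is normalized for the labeling efficiencies:
#' `normalized_ratio = slope * eff_gfp / eff_alfa`, the estimated number of
#' antibodies per receptor.
#'
#' @param coclusters cluster table from [dbscan_cocluster()] (or any
#'   data.frame with n_alfa, n_gfp).
#' @param eff_alfa,eff_gfp labeling efficiencies.
#' @return a `ratio_fit`: slope, intercept, normalized_ratio, n_clusters,
#'   eff_alfa, eff_gfp, and the per-cluster table used.
#' @export
ratio_analysis <- function(coclusters, eff_alfa = 0.40, eff_gfp = 0.50) {
  cc <- data.table::as.data.table(coclusters)
  if (nrow(cc) < 3L) stop("need at least 3 co-clusters for a ratio fit")
  x <- cc$n_gfp
  y <- cc$n_alfa / 2
  if (stats::var(x) == 0) {
    stop("degenerate fit: all clusters have identical GFP counts")
  }
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 normalized_ratio = slope * eff_gfp / eff_alfa,
                 eff_alfa = eff_alfa, eff_gfp = eff_gfp,
                 n_clusters = nrow(cc),
                 per_cluster = cc[, .(n_alfa, n_gfp)]),
            class = "ratio_fit")
}

#' @export
print.ratio_fit <- function(x, ...) {
  cat(sprintf("ratio fit over %d co-clusters\n", x$n_clusters))
  cat(sprintf("  slope (mAb per GFP count): %.4f  intercept: %.4f\n",
              x$slope, x$intercept))
  cat(sprintf("  normalized mAb:receptor ratio (eff %.2f/%.2f): %.4f\n",
              x$eff_alfa, x$eff_gfp, x$normalized_ratio))
  invisible(x)
}

#' kth nearest-neighbor distance profile
#'
#' Per-point distances to the 1st..kth nearest neighbors (self excluded),
#' binned into fixed-width histograms per order. Frequencies are counts
#' divided by the number of points, making profiles from different-sized
#' point sets comparable.
#'
#' @param points RESI table or numeric matrix of coordinates.
#' @param orders integer vector of neighbor orders (default 1:6).
#' @param bin_width histogram bin width in nm (default 1).
#' @param r_max histogram range upper limit in nm (default 200).
#' @param use_z use 3D distances when z is available.
#' @return an `nnd_profile`: orders, bin_edges, counts and freq matrices
#'   (bins x orders), n_points, and the raw per-point distance matrix.
#' @export
nnd_profile <- function(points, orders = 1:6, bin_width = 1, r_max = 200,
                        use_z = FALSE) {
  coords <- if (is.matrix(points)) points else point_matrix(points, use_z)
  kmax <- max(orders)
  if (nrow(coords) < kmax + 1L) {
    stop(sprintf("nnd_profile needs at least %d points (max order %d + 1), got %d",
                 kmax + 1L, kmax, nrow(coords)))
  }
  nnd <- knn_distances(coords, kmax)
  edges <- seq(0, r_max, by = bin_width)
  nb <- length(edges) - 1L
  counts <- vapply(orders, function(k) {
    idx <- floor(nnd[, k] / bin_width) + 1
    tabulate(idx[idx <= nb], nbins = nb)
  }, integer(nb))
  colnames(counts) <- paste0("nnd", orders)
  structure(list(orders = orders, bin_edges = edges, counts = counts,
                 freq = counts / nrow(coords), n_points = nrow(coords),
                 nnd = nnd[, orders, drop = FALSE]),
            class = "nnd_profile")
}

#' @export
print.nnd_profile <- function(x, ...) {
  cat(sprintf("NND profile: %d points, orders %s, %d bins of %g nm\n",
              x$n_points, paste(range(x$orders), collapse = "-"),
              nrow(x$counts), diff(x$bin_edges[1:2])))
  means <- colMeans(x$nnd)
  cat("  mean NND per order (nm):",
      paste(sprintf("%.1f", means), collapse = ", "), "\n")
  invisible(x)
}

#' CSR reference NND profile at matched density
#'
#' Simulates complete spatial randomness at the density of the supplied point
#' set (or an explicit density) and profiles it with identical binning, for
#' bin-by-bin comparison with the data.
#'
#' @param points_or_density a point table/matrix, or a single number taken as
#'   density in points per square micrometer.
#' @param fov field of view in nm used for the density and the simulation.
#' @param seed integer seed.
#' @inheritParams nnd_profile
#' @return an `nnd_profile` of the simulated CSR field.
#' @export
csr_reference <- function(points_or_density, fov, seed = NULL, orders = 1:6,
                          bin_width = 1, r_max = 200) {
  if (length(fov) == 1L) fov <- c(fov, fov)
  density <- if (is.numeric(points_or_density) &&
                 length(points_or_density) == 1L) {
    points_or_density
  } else {
    n <- if (is.matrix(points_or_density)) nrow(points_or_density)
         else nrow(data.table::as.data.table(points_or_density))
    n / (prod(fov) / 1e6)
  }
  if (density <= 0) stop("density must be positive")
  kmax <- max(orders)
  if (density * prod(fov) / 1e6 < 10 * (kmax + 1)) {
    stop("fov too small for a stable CSR reference at this density")
  }
  sim <- simulate_csr(density, fov, seed = seed)
  nnd_profile(sim, orders = orders, bin_width = bin_width, r_max = r_max)
}
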