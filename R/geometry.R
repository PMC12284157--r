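# C1q-binding-platform counting and 3D complex angle/distance analysis.

#' Count C1q-compatible binding platforms in the antibody channel
#'
#' The hexavalent complement protein C1q engages six antibody Fc domains in
#' proximity; with two ALFA labels per antibody at 40% labeling efficiency,
#' six antibodies are approximated as at least `min_count` detected ALFA
#' localizations within `radius`. Every ALFA localization whose neighborhood
#' (itself included) reaches `min_count` seeds one binding configuration;
#' configurations sharing members are all counted, representing the apparent
#' gain in avidity. Neighborhoods are evaluated in the membrane plane (xy) by
#' default.
#'
#' @param alfa antibody RESI table (x, y, optionally z).
#' @param radius neighborhood radius in nm (default 25).
#' @param min_count minimum ALFA localizations, seed included (default 5).
#' @param use_z evaluate neighborhoods in 3D (cylinder with axial window
#'   `2 * radius`).
#' @return list: `n_platform_configs`, `seed_indices` (row indices of the
#'   seeding localizations), `neighborhood_counts` (per point, self
#'   included).
#' @export
count_c1q_platforms <- function(alfa, radius = 25, min_count = 5L,
                                use_z = FALSE) {
  alfa <- data.table::as.data.table(alfa)
  if (nrow(alfa) == 0L) {
    return(list(n_platform_configs = 0L, seed_indices = integer(0),
                neighborhood_counts = integer(0)))
  }
  z <- if (use_z && "z" %in% names(alfa)) alfa$z else NULL
  counts <- radius_counts(alfa$x, alfa$y, radius, z = z) + 1L # self included
  seeds <- which(counts >= min_count)
  list(n_platform_configs = length(seeds), seed_indices = seeds,
       neighborhood_counts = counts)
}

#' 3D geometry of antibody-receptor co-clusters
#'
#' For each co-cluster with more than `min_cd20 - 1` receptor molecules, the
#' vector v from the antibody center of mass to the receptor center of mass
#' is computed; the reported angle is between v and the membrane normal
#' (z-axis), so 0 deg means the antibody sits perfectly perpendicular above
#' the receptor cluster. The angle is folded to the 0-90 deg range (symmetry
#' about the membrane plane); the unfolded value is retained as
#' `angle_raw_deg`.
#'
#' @param coclusters cluster table from [dbscan_cocluster()] run with
#'   `use_z = TRUE` (needs com_*_z columns).
#' @param min_cd20 minimum receptor count (default 4: strictly more than 3).
#' @return data.table: cluster_id, n_gfp, angle_deg, angle_raw_deg,
#'   distance_nm, axial_nm. `distance_nm >= axial_nm` always.
#' @export
complex_angle <- function(coclusters, min_cd20 = 4L) {
  cc <- data.table::as.data.table(coclusters)
  if (!all(c("com_alfa_z", "com_gfp_z") %in% names(cc))) {
    stop("angle requires z: run dbscan_cocluster(..., use_z = TRUE) on 3D data")
  }
  cc <- cc[n_gfp >= min_cd20]
  vx <- cc$com_gfp_x - cc$com_alfa_x
  vy <- cc$com_gfp_y - cc$com_alfa_y
  vz <- cc$com_gfp_z - cc$com_alfa_z
  d <- sqrt(vx^2 + vy^2 + vz^2)
  data.table::data.table(
    cluster_id = cc$cluster_id, n_gfp = cc$n_gfp,
    angle_deg = acos(pmin(1, abs(vz) / d)) * 180 / pi,
    angle_raw_deg = acos(pmax(-1, pmin(1, vz / d))) * 180 / pi,
    distance_nm = d, axial_nm = abs(vz))
}

#' Aggregate complex geometry over clusters
#'
#' @param geometries output of [complex_angle()].
#' @return list with n and mean/s.d. of the axial distance, Euclidean
#'   distance and angle; s.d. is NA for a single geometry.
#' @export
complex_distance_summary <- function(geometries) {
  g <- data.table::as.data.table(geometries)
  if (nrow(g) == 0L) stop("no geometries to summarize")
  sdn <- function(v) if (length(v) > 1L) stats::sd(v) else NA_real_
  list(n = nrow(g),
       axial_mean_nm = mean(g$axial_nm), axial_sd_nm = sdn(g$axial_nm),
       distance_mean_nm = mean(g$distance_nm),
       distance_sd_nm = sdn(g$distance_nm),
       angle_mean_deg = mean(g$angle_deg), angle_sd_deg = sdn(g$angle_deg))
}
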