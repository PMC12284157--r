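# Grouping of DNA-PAINT localizations into per-molecule RESI localizations.
#
# The algorithm mirrors the published SMLM clustering: neighbor counts within
# a radius r mark local maxima, localizations within r of a qualifying
# maximum form a cluster, frame-based filters remove sticking artifacts, and
# cluster centers are inverse-variance weighted means with precision
# sigma_RESI = sigma_DNA-PAINT / sqrt(K).

#' Clustering parameters
#'
#' @param radius_r grouping radius r in nm, defining the circular (2D) or
#'   cylindrical (3D) neighborhood. A suitable r is about 1.5-2x the NeNa
#'   localization precision.
#' @param n_min minimum localizations per cluster: clusters must hold
#'   strictly more than `n_min` members.
#' @param is_3d use the axial coordinate; the z radius is `2 * radius_r`
#'   because the axial localization spread is about two-fold the lateral one.
#' @return a `cluster_params` object.
#' @export
cluster_params <- function(radius_r, n_min, is_3d = FALSE) {
  assert_scalar_pos(radius_r, "radius_r")
  if (n_min < 1) stop("n_min must be >= 1")
  structure(list(radius_r = radius_r, n_min = as.integer(n_min),
                 is_3d = isTRUE(is_3d)), class = "cluster_params")
}

#' Group localizations into raw clusters around local density maxima
#'
#' Neighbor counts are computed within `radius_r` (with an axial window of
#' `2 * radius_r` in 3D). A localization is a local maximum when its count
#' is at least that of every neighbor, with the lowest index winning ties (so a flat
#' dense cloud still yields exactly one maximum). Each maximum whose assigned
#' member count (itself included) exceeds `n_min` forms a cluster; a
#' localization within reach of several maxima joins the nearest one
#' (Euclidean, index tie-break). Non-clustered localizations are discarded.
#'
#' @param table a single-target [loc_table()].
#' @param params a [cluster_params()].
#' @return list of raw clusters; each holds `members` (row indices into
#'   `table`), `local_max_index`, `mean_frame` and `frame_window_fraction`
#'   (max fraction of members inside any 5%-wide frame window, computed
#'   against the table's `n_frames`).
#' @export
cluster_localizations <- function(table, params) {
  stopifnot(inherits(params, "cluster_params"))
  n <- nrow(table)
  if (n == 0L) return(list())
  r <- params$radius_r
  z <- if (params$is_3d && "z" %in% names(table)) table$z else NULL
  nb <- radius_neighbors(table$x, table$y, r, z = z, rz = 2 * r)
  counts <- lengths(nb)
  is_max <- vapply(seq_len(n), function(i) {
    js <- nb[[i]]
    if (!length(js)) return(TRUE)
    cj <- counts[js]
    all(cj < counts[i] | (cj == counts[i] & js > i))
  }, logical(1))
  maxima <- which(is_max)
  if (!length(maxima)) return(list())
  # assign each localization to the nearest qualifying maximum within reach
  assignment <- integer(n)
  best_d2 <- rep(Inf, n)
  for (m in maxima) {
    cand <- c(m, nb[[m]])
    d2 <- (table$x[cand] - table$x[m])^2 + (table$y[cand] - table$y[m])^2
    if (!is.null(z)) d2 <- d2 + (z[cand] - z[m])^2
    upd <- d2 < best_d2[cand] |
      (d2 == best_d2[cand] & (assignment[cand] == 0L | m < assignment[cand]))
    cand <- cand[upd]; d2 <- d2[upd]
    assignment[cand] <- m
    best_d2[cand] <- d2
  }
  meta <- attr(table, "meta")
  n_frames <- if (!is.null(meta)) meta$n_frames else max(table$frame) + 1L
  out <- list()
  for (m in maxima) {
    members <- which(assignment == m)
    if (length(members) <= params$n_min) next
    fr <- sort(table$frame[members])
    out[[length(out) + 1L]] <- list(
      members = members,
      local_max_index = m,
      mean_frame = mean(fr),
      frame_window_fraction = max_window_fraction(fr, n_frames))
  }
  out
}

# max fraction of (sorted) frames falling in any window of width
# ceil(0.05 * n_frames), slid over all positions; two-pointer scan
max_window_fraction <- function(sorted_frames, n_frames) {
  w <- ceiling(0.05 * n_frames)
  k <- length(sorted_frames)
  best <- 0L
  j <- 1L
  for (i in seq_len(k)) {
    while (sorted_frames[i] - sorted_frames[j] >= w) j <- j + 1L
    best <- max(best, i - j + 1L)
  }
  best / k
}

#' Filter clusters with frame-based artifact rules
#'
#' Removes clusters whose mean frame lies in the first or last 20% of frames
#' (half-open: `mean < 0.2 n` or `mean >= 0.8 n`), and clusters with over
#' 80% of their localizations inside any 5%-wide frame window (transient
#' sticking of imager strands).
#'
#' @param clusters output of [cluster_localizations()].
#' @param n_frames total frames.
#' @return filtered cluster list, with a `qc` attribute counting removals per
#'   rule.
#' @export
filter_clusters <- function(clusters, n_frames) {
  if (n_frames <= 0) stop("n_frames must be positive")
  mean_bad <- vapply(clusters, function(cl) {
    cl$mean_frame < 0.2 * n_frames || cl$mean_frame >= 0.8 * n_frames
  }, logical(1))
  window_bad <- vapply(clusters, function(cl) {
    cl$frame_window_fraction > 0.8
  }, logical(1))
  out <- clusters[!mean_bad & !window_bad]
  attr(out, "qc") <- c(n_in = length(clusters),
                       removed_mean_frame = sum(mean_bad),
                       removed_window = sum(window_bad & !mean_bad),
                       n_out = length(out))
  out
}

#' Compute RESI localizations from clusters
#'
#' The cluster center is the inverse-variance weighted mean per axis (weights
#' `1/sigma^2`). The reported precision is `sigma_bar / sqrt(K)` with
#' `sigma_bar` the precision-weighted mean member precision: averaging K
#' localizations improves precision by `sqrt(K)`. The weighted standard error
#' of the members is also reported (`sigma_resi_se`) as a secondary estimate.
#'
#' @param clusters output of [cluster_localizations()] / [filter_clusters()].
#' @param table the localization table the clusters index into.
#' @return data.table of RESI localizations: x, y (z if present), K,
#'   sigma_resi, sigma_resi_se, mean_frame, target_id, source_cluster_id.
#' @export
resi_centers <- function(clusters, table) {
  if (!length(clusters)) {
    return(data.table::data.table(x = numeric(0), y = numeric(0),
                                  K = integer(0), sigma_resi = numeric(0),
                                  sigma_resi_se = numeric(0),
                                  mean_frame = numeric(0),
                                  target_id = character(0),
                                  source_cluster_id = integer(0)))
  }
  has_z <- "z" %in% names(table)
  sig <- if ("sigma_xy" %in% names(table)) table$sigma_xy else
    rep(1, nrow(table))
  if (any(sig <= 0 | is.na(sig))) stop("non-positive localization precision")
  rows <- lapply(seq_along(clusters), function(ci) {
    cl <- clusters[[ci]]
    i <- cl$members
    w <- 1 / sig[i]^2
    sw <- sum(w)
    K <- length(i)
    sigma_bar <- sum(w * sig[i]) / sw
    cx <- sum(w * table$x[i]) / sw
    cy <- sum(w * table$y[i]) / sw
    se <- sqrt(sum(w * ((table$x[i] - cx)^2 + (table$y[i] - cy)^2) / 2) /
                 sw / K)
    row <- data.table::data.table(
      x = cx, y = cy, K = K,
      sigma_resi = sigma_bar / sqrt(K),
      sigma_resi_se = se,
      mean_frame = cl$mean_frame,
      target_id = if ("target_id" %in% names(table))
        as.character(table$target_id[i[1L]]) else NA_character_,
      source_cluster_id = ci)
    if (has_z) {
      wz <- if ("sigma_z" %in% names(table)) 1 / table$sigma_z[i]^2 else w
      row[, z := sum(wz * table$z[i]) / sum(wz)]
    }
    row
  })
  out <- data.table::rbindlist(rows, fill = TRUE)
  if (has_z) data.table::setcolorder(out, c("x", "y", "z"))
  out[]
}

#' One-call RESI pipeline: cluster, filter, compute centers
#'
#' @inheritParams cluster_localizations
#' @param filter apply the frame-based artifact filters (default TRUE).
#' @return data.table of RESI localizations (see [resi_centers()]) with a
#'   `qc` attribute.
#' @export
resi_pipeline <- function(table, params, filter = TRUE) {
  cl <- cluster_localizations(table, params)
  meta <- attr(table, "meta")
  n_frames <- if (!is.null(meta)) meta$n_frames else max(table$frame) + 1L
  qc <- NULL
  if (filter) {
    cl <- filter_clusters(cl, n_frames)
    qc <- attr(cl, "qc")
  }
  out <- resi_centers(cl, table)
  attr(out, "qc") <- qc
  out
}
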