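# Brute-force oracles, independent of the package's spatial-index code paths.
# All are quadratic all-pairs implementations for small instances.

brute_dist2 <- function(coords) {
  as.matrix(stats::dist(coords))^2
}

# neighbor counts within r (xy), optional cylinder with |dz| <= rz
brute_radius_counts <- function(x, y, r, z = NULL, rz = 2 * r) {
  n <- length(x)
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  ok <- d2 <= r^2
  if (!is.null(z)) ok <- ok & abs(outer(z, z, "-")) <= rz
  diag(ok) <- FALSE
  rowSums(ok)
}

brute_knn <- function(coords, k) {
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  res <- apply(d, 1, function(row) sort(row)[seq_len(k)])
  out <- if (k == 1L) matrix(res, ncol = 1L) else t(res)
  dimnames(out) <- NULL
  out
}

# connected components of the eps-graph (equivalent to DBSCAN with
# min_samples = 2); uses igraph as an independent implementation
graph_components <- function(coords, eps) {
  d <- as.matrix(stats::dist(coords))
  adj <- d <= eps
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  comp[comp %in% which(tabulate(comp) == 1L)] <- 0L # singletons = noise
  as.integer(comp)
}

# full brute-force re-implementation of the localization grouping algorithm
# (neighbor counts, >= local maxima with lowest-index tie-break, nearest-max
# assignment, strict > n_min size rule)
brute_cluster_locs <- function(table, r, n_min, use_z = FALSE) {
  n <- nrow(table)
  x <- table$x; y <- table$y
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  within <- d2 <= r^2
  if (use_z && "z" %in% names(table)) {
    within <- within & abs(outer(table$z, table$z, "-")) <= 2 * r
  }
  diag(within) <- FALSE
  counts <- rowSums(within)
  is_max <- vapply(seq_len(n), function(i) {
    js <- which(within[i, ])
    all(counts[js] < counts[i] | (counts[js] == counts[i] & js > i))
  }, logical(1))
  maxima <- which(is_max)
  assignment <- integer(n)
  for (i in seq_len(n)) {
    cand <- maxima[within[i, maxima] | maxima == i]
    if (!length(cand)) next
    dd <- d2[i, cand]
    if (use_z && "z" %in% names(table)) {
      dd <- dd + 0 # xy d2 already includes... use full 3D below
      dd <- (x[cand] - x[i])^2 + (y[cand] - y[i])^2 +
        (table$z[cand] - table$z[i])^2
    }
    assignment[i] <- cand[order(dd, cand)][1L]
  }
  out <- list()
  for (m in maxima) {
    members <- which(assignment == m)
    if (length(members) > n_min) {
      out[[length(out) + 1L]] <- sort(members)
    }
  }
  out
}

# exhaustive sliding-window scan for the 5%-of-frames rule
brute_window_fraction <- function(frames, n_frames) {
  w <- ceiling(0.05 * n_frames)
  best <- 0
  for (s in 0:(n_frames - 1)) {
    best <- max(best, sum(frames >= s & frames < s + w))
  }
  best / length(frames)
}

# small synthetic localization tables
make_table <- function(x, y, frame = NULL, sigma_xy = 1, n_frames = 1000,
                       z = NULL, target_id = "GFP") {
  n <- length(x)
  df <- data.frame(x = x, y = y,
                   frame = frame %||% rep(0L, n),
                   sigma_xy = rep_len(sigma_xy, n),
                   target_id = rep_len(target_id, n))
  if (!is.null(z)) df$z <- z
  loc_table(df, meta = acquisition_meta(n_frames = n_frames, fov = 1e5))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
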