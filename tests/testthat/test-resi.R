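# resi_clustering: localization grouping, frame filters, weighted centers.

test_that("coincident cloud and undersized tables behave per contract", {
  tab <- make_table(rep(10, 10), rep(20, 10))
  cl <- cluster_localizations(tab, cluster_params(radius_r = 1, n_min = 5))
  expect_length(cl, 1L)
  expect_length(cl[[1]]$members, 10L)
  # n_min >= table size -> no clusters (strict >)
  expect_length(cluster_localizations(tab, cluster_params(1, 10)), 0L)
  # empty table -> empty result, not an error
  empty <- make_table(numeric(0), numeric(0))
  expect_length(cluster_localizations(empty, cluster_params(1, 5)), 0L)
  expect_error(cluster_params(-1, 5), "radius_r")
})

test_that("two Gaussian clouds are separated, matching the brute-force oracle", {
  set.seed(21)
  tab <- make_table(c(rnorm(40, 0, 2), rnorm(35, 50, 2)),
                    c(rnorm(40, 0, 2), rnorm(35, 0, 2)),
                    frame = sample(0:999, 75, replace = TRUE))
  cl <- cluster_localizations(tab, cluster_params(radius_r = 4, n_min = 5))
  oracle <- brute_cluster_locs(tab, r = 4, n_min = 5)
  expect_equal(length(cl), length(oracle))
  got <- lapply(cl, function(c) sort(c$members))
  expect_setequal(lapply(got, paste, collapse = ","),
                  lapply(oracle, paste, collapse = ","))
})

test_that("clustering agrees exactly with the oracle on random instances (2D and 3D)", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- 300
    centers <- matrix(runif(30, 0, 500), ncol = 2)
    pick <- sample(15, n, replace = TRUE)
    x <- centers[pick, 1] + rnorm(n, 0, 3)
    y <- centers[pick, 2] + rnorm(n, 0, 3)
    tab <- make_table(x, y, frame = sample(0:999, n, replace = TRUE))
    for (nmin in c(3, 8)) {
      cl <- cluster_localizations(tab, cluster_params(6, nmin))
      oracle <- brute_cluster_locs(tab, 6, nmin)
      expect_setequal(lapply(cl, function(c) paste(sort(c$members),
                                                   collapse = ",")),
                      lapply(oracle, paste, collapse = ","))
    }
    # 3D: z radius doubled
    tab3 <- make_table(x, y, frame = sample(0:999, n, replace = TRUE),
                       z = centers[pick, 1] / 50 + rnorm(n, 0, 6))
    cl3 <- cluster_localizations(tab3, cluster_params(6, 3, is_3d = TRUE))
    oracle3 <- brute_cluster_locs(tab3, 6, 3, use_z = TRUE)
    expect_setequal(lapply(cl3, function(c) paste(sort(c$members),
                                                  collapse = ",")),
                    lapply(oracle3, paste, collapse = ","))
  }
})

test_that("clustering is invariant under row permutation", {
  set.seed(33)
  n <- 200
  x <- rnorm(n, rep(c(0, 40, 90), length.out = n), 2)
  y <- rnorm(n, 0, 2)
  tab <- make_table(x, y, frame = sample(0:999, n, replace = TRUE))
  perm <- sample(n)
  tabp <- make_table(x[perm], y[perm], frame = tab$frame[perm])
  cl <- cluster_localizations(tab, cluster_params(5, 10))
  clp <- cluster_localizations(tabp, cluster_params(5, 10))
  sets <- function(cls, map = identity) {
    sort(vapply(cls, function(c) paste(sort(map(c$members)), collapse = ","),
                character(1)))
  }
  expect_equal(sets(cl), sets(clp, function(m) perm[m]))
})

test_that("frame filters implement the 20%/80% and 5%-window rules", {
  n_frames <- 1000
  mk <- function(frames) {
    fr <- sort(frames)
    list(members = seq_along(fr), local_max_index = 1L,
         mean_frame = mean(fr),
         frame_window_fraction = max_window_fraction(fr, n_frames))
  }
  uniform <- mk(seq(0, 999, by = 37))
  early <- mk(rep(50:120, 2))
  late <- mk(rep(850:950, 1))
  sticky <- mk(c(rep(500:540, 5), seq(0, 999, by = 30))) # >80% in one window
  out <- filter_clusters(list(uniform, early, late, sticky), n_frames)
  expect_length(out, 1L)
  expect_equal(out[[1]]$mean_frame, uniform$mean_frame)
  qc <- attr(out, "qc")
  expect_equal(unname(qc["removed_mean_frame"]), 2)
  expect_equal(unname(qc["removed_window"]), 1)
  expect_error(filter_clusters(list(uniform), 0), "n_frames")
})

test_that("window fraction matches the exhaustive sliding-window oracle", {
  set.seed(44)
  for (i in 1:20) {
    n_frames <- sample(100:2000, 1)
    frames <- sort(sample(0:(n_frames - 1), sample(5:60, 1), replace = TRUE))
    expect_equal(max_window_fraction(frames, n_frames),
                 brute_window_fraction(frames, n_frames),
                 info = paste("case", i))
  }
  # 85% inside one 5% window, rest uniform -> excluded
  n_frames <- 1000
  frames <- c(rep(475:524, length.out = 85), round(seq(0, 999, length.out = 15)))
  cl <- list(list(members = 1:100, local_max_index = 1L,
                  mean_frame = mean(frames),
                  frame_window_fraction = max_window_fraction(sort(frames),
                                                              n_frames)))
  expect_length(filter_clusters(cl, n_frames), 0L)
})

test_that("weighted mean worked example and precision law", {
  # members x = {0 (sigma 1), 3 (sigma 2)} -> weights 1, 0.25 -> mean 0.6
  tab <- make_table(c(0, 3), c(0, 0), sigma_xy = c(1, 2))
  cl <- list(list(members = 1:2, local_max_index = 1L, mean_frame = 0,
                  frame_window_fraction = 1))
  res <- resi_centers(cl, tab)
  expect_equal(res$x, 0.6)
  expect_equal(res$K, 2L)
  # K = 25 at sigma 3 nm -> sigma_resi = 0.6 nm
  tab25 <- make_table(rnorm(25), rnorm(25), sigma_xy = 3)
  cl25 <- list(list(members = 1:25, local_max_index = 1L, mean_frame = 0,
                    frame_window_fraction = 0.2))
  expect_equal(resi_centers(cl25, tab25)$sigma_resi, 3 / sqrt(25))
  # equal precisions -> arithmetic mean
  expect_equal(resi_centers(cl25, tab25)$x, mean(tab25$x))
  # non-positive precision refused
  bad <- make_table(c(0, 1), c(0, 0), sigma_xy = 1)
  bad$sigma_xy[1] <- 0
  expect_error(resi_centers(cl, bad), "precision")
})

test_that("empirical RESI precision follows sigma / sqrt(K) within 10%", {
  sites <- simulate_csr(0.5, 50000, seed = 61) # ~1250 isolated sites
  sites[, `:=`(labeled = TRUE, round_id = 5L)]
  bp <- blink_params(mean_K = 25, sigma_dnapaint_xy = 3, n_frames = 5000)
  tab <- simulate_blinking(sites, bp, 50000, seed = 62)
  res <- resi_pipeline(tab, cluster_params(radius_r = 9, n_min = 5))
  nn <- FNN::get.knnx(cbind(sites$x, sites$y), cbind(res$x, res$y), k = 1)
  err <- nn$nn.dist[nn$nn.dist < 5]
  # per-axis sd of (center - truth) vs sigma / sqrt(mean K)
  sd_axis <- sqrt(mean(err^2) / 2)
  expect_equal(sd_axis, 3 / sqrt(mean(res$K)), tolerance = 0.1)
  expect_gt(nrow(res), 0.95 * nrow(sites))
})
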