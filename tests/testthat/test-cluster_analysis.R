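# cluster_analysis: DBSCAN co-clustering, single-target clustering, ratio
# fits, NND profiles, CSR references.

pts <- function(x, y) data.table::data.table(x = x, y = y)

test_that("co-clustering keeps two-target clusters and discards the rest", {
  alfa <- pts(c(0, 1000), c(0, 0))       # second ALFA is isolated
  gfp <- pts(c(30, 500), c(0, 0))        # second GFP is isolated
  cc <- dbscan_cocluster(alfa, gfp, eps = 40)
  expect_equal(nrow(cc$clusters), 1L)
  expect_equal(cc$clusters$n_alfa, 1L)
  expect_equal(cc$clusters$n_gfp, 1L)
  # centers of mass are per target
  expect_equal(cc$clusters$com_alfa_x, 0)
  expect_equal(cc$clusters$com_gfp_x, 30)
  # discarded points are labeled 0
  expect_equal(sum(cc$points$cluster_id == 0L), 2L)
  # empty input
  cc0 <- dbscan_cocluster(pts(numeric(0), numeric(0)),
                          pts(numeric(0), numeric(0)))
  expect_equal(nrow(cc0$clusters), 0L)
})

test_that("chained points form one cluster; membership = 40 nm graph components", {
  alfa <- pts(c(0, 70, 140), rep(0, 3))
  gfp <- pts(c(35, 105, 175), rep(0, 3))
  cc <- dbscan_cocluster(alfa, gfp, eps = 40)
  expect_equal(nrow(cc$clusters), 1L)
  expect_equal(cc$clusters$n_alfa + cc$clusters$n_gfp, 6L)
  # random instances against the independent graph oracle
  skip_if_not_installed("igraph")
  for (seed in 1:4) {
    set.seed(seed)
    n <- 400
    coords <- cbind(runif(n, 0, 3000), runif(n, 0, 3000))
    labels <- dbscan_points(coords, eps = 40, min_samples = 2L)
    oracle <- graph_components(coords, eps = 40)
    # same partition up to label names
    expect_equal(labels == 0L, oracle == 0L)
    tab <- table(labels[labels > 0], oracle[labels > 0])
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
})

test_that("single-target clustering exports sizes and density for the simulator", {
  g <- pts(c(0, 15, 100, 110, 120, 500), rep(0, 6))
  cs <- dbscan_single_target(g, eps = 20, min_size = 2L, fov = 1000)
  expect_equal(sort(cs$sizes), c(2L, 3L))
  expect_equal(cs$n_clusters, 2L)
  expect_equal(cs$labels[6], 0L) # singleton discarded
  expect_equal(cs$density_um2, 2) # 2 clusters in 1 um^2
  # size frequencies on a mixture match brute-force component counting
  skip_if_not_installed("igraph")
  set.seed(9)
  n <- 500
  coords <- cbind(runif(n, 0, 4000), runif(n, 0, 4000))
  cs2 <- dbscan_single_target(data.table::as.data.table(
    list(x = coords[, 1], y = coords[, 2])), eps = 20, fov = 4000)
  comp <- graph_components(coords, 20)
  oracle_sizes <- sort(as.integer(table(comp[comp > 0])))
  expect_equal(sort(cs2$sizes), oracle_sizes[oracle_sizes >= 2])
})

test_that("ratio analysis arithmetic, normalization and degeneracy", {
  # exact line: n_alfa = 2 * (0.4 * n_gfp + 1), slope of n_alfa/2 vs n_gfp = 0.4
  cc <- data.table::data.table(n_gfp = c(1, 3, 5, 10),
                               n_alfa = 2 * (0.4 * c(1, 3, 5, 10) + 1))
  rf <- ratio_analysis(cc, eff_alfa = 0.4, eff_gfp = 0.5)
  expect_equal(rf$slope, 0.4)
  expect_equal(rf$intercept, 1)
  expect_equal(rf$normalized_ratio, 0.4 * 0.5 / 0.4)
  # the published normalization: slope 0.38 at 40%/50% -> 0.475
  cc38 <- data.table::data.table(n_gfp = c(2, 4, 8), n_alfa = 0.76 * c(2, 4, 8))
  expect_equal(ratio_analysis(cc38)$normalized_ratio, 0.38 * 0.5 / 0.4)
  # identical clusters -> degenerate
  same <- data.table::data.table(n_gfp = rep(2, 5), n_alfa = rep(2, 5))
  expect_error(ratio_analysis(same), "degenerate")
  expect_error(ratio_analysis(cc[1:2]), "at least 3")
})

test_that("NND profile: basic examples, monotonicity, brute-force agreement", {
  # two points at distance d: both 1st NNDs equal d
  p2 <- nnd_profile(pts(c(0, 7), c(0, 0)), orders = 1)
  expect_equal(as.vector(p2$nnd), c(7, 7))
  # collinear 0..4: 2nd NND of the end point is 2
  p5 <- nnd_profile(pts(0:4, rep(0, 5)), orders = 1:2)
  expect_equal(p5$nnd[1, 2], 2)
  expect_equal(p5$nnd[3, 1], 1)
  # too few points -> error naming the minimum
  expect_error(nnd_profile(pts(1:3, 1:3), orders = 1:6), "7 points")
  # monotonicity in order and brute-force agreement on random sets
  set.seed(17)
  coords <- cbind(runif(300, 0, 2000), runif(300, 0, 2000))
  prof <- nnd_profile(coords, orders = 1:6)
  expect_true(all(diff(t(prof$nnd)) >= 0))
  expect_equal(prof$nnd, brute_knn(coords, 6), ignore_attr = TRUE)
  # histogram mass per order equals points within range
  expect_equal(colSums(prof$counts),
               colSums(prof$nnd < 200), ignore_attr = TRUE)
})

test_that("CSR reference matches CSR data and flags dimer excess", {
  rho <- 50
  s <- simulate_csr(rho, 20000, seed = 71)
  ref <- csr_reference(s, fov = 20000, seed = 72, orders = 1:3)
  prof <- nnd_profile(s, orders = 1:3)
  # two-sample chi-square homogeneity on the 1st-NND histograms, alpha 0.01.
  # Mutual nearest-neighbor pairs duplicate NND values (correlated samples),
  # so one member of each mutual pair is dropped on both sides first.
  dedup_nnd1 <- function(points) {
    xy <- cbind(points$x, points$y)
    nn <- FNN::get.knn(xy, k = 1)
    idx <- nn$nn.index[, 1]
    mutual_dup <- idx[idx] == seq_along(idx) & idx < seq_along(idx)
    nn$nn.dist[!mutual_dup, 1]
  }
  o <- tabulate(floor(dedup_nnd1(s)) + 1, nbins = 200)
  e <- tabulate(floor(dedup_nnd1(simulate_csr(rho, 20000, seed = 72))) + 1,
                nbins = 200)
  keep <- (o + e) >= 10
  suppressWarnings(p_hom <- stats::chisq.test(rbind(o[keep], e[keep]))$p.value)
  expect_gt(p_hom, 0.01)
  # dimers at 13.5 nm: excess below 20 nm versus CSR in the 1st NND
  op <- oligomer_params(proportions = c(0, 1, 0, 0), total_density = rho)
  d <- simulate_oligomers(op, 20000, seed = 73)
  d <- apply_labeling(d, eff_gfp = 0.5, seed = 74)
  d <- apply_uncertainty(d[d$labeled == TRUE], sd = 5, seed = 75)
  pd <- nnd_profile(d, orders = 1:3)
  refd <- csr_reference(d, fov = 20000, seed = 76, orders = 1:3)
  frac20 <- function(p) mean(p$nnd[, 1] < 20)
  expect_gt(frac20(pd), frac20(refd) + 0.2)
  # guards
  expect_error(csr_reference(0, fov = 1000), "positive")
  expect_error(csr_reference(pts(1, 1), fov = 100), "too small")
})

test_that("mean 1st NND of CSR matches 1/(2 sqrt(rho)) within 2%", {
  rho <- 400
  s <- simulate_csr(rho, 10000, seed = 81)
  core <- s$x > 150 & s$x < 9850 & s$y > 150 & s$y < 9850
  nnd1 <- knn_distances(cbind(s$x, s$y), 1)[core, 1]
  expect_equal(mean(nnd1), 1000 / (2 * sqrt(rho)), tolerance = 0.02)
})
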