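# synthetic_data: chain geometry, oligomer geometry, CSR statistics,
# labeling, round assignment/merging, blinking.

test_that("chain geometry: hinge spacing, site counts, dimer distances, angles", {
  cp <- chain_params(segment_length = 23,
                     segment_count_dist = data.frame(segments = c(1, 3, 7),
                                                     prob = c(0.2, 0.5, 0.3)),
                     chain_density = 3)
  sim <- simulate_chains(cp, fov = 20000, seed = 11)
  h <- sim$hinges
  # consecutive hinges exactly L apart (pre-noise)
  h[, `:=`(dx = c(NA, diff(x)), dy = c(NA, diff(y)),
           newchain = c(TRUE, diff(chain_id) != 0)), ]
  seg_len <- sqrt(h$dx^2 + h$dy^2)[!h$newchain]
  expect_equal(seg_len, rep(23, length(seg_len)), tolerance = 1e-12)
  # site counts: 2(s+1) ALFA, 2s GFP per chain
  sc <- merge(sim$sites[, .N, by = .(complex_id, target_id)],
              sim$chains, by.x = "complex_id", by.y = "chain_id")
  expect_true(all(sc[target_id == "ALFA", N == 2 * (n_segments + 1)]))
  expect_true(all(sc[target_id == "GFP", N == 2 * n_segments]))
  # every within-dimer GFP pair exactly 13.5 nm apart before noise
  gfp <- sim$sites[target_id == "GFP"]
  gfp[, dimer := rep(seq_len(.N / 2), 2), by = complex_id]
  # GFP rows are stacked (first members, then second members per segment)
  n_g <- nrow(gfp) / 2
  dd <- sqrt((gfp$x[seq_len(n_g)] - gfp$x[n_g + seq_len(n_g)])^2 +
               (gfp$y[seq_len(n_g)] - gfp$y[n_g + seq_len(n_g)])^2)
  expect_equal(dd, rep(13.5, n_g), tolerance = 1e-9)
  # ALFA pairs exactly 4 nm apart
  alfa <- sim$sites[target_id == "ALFA"]
  n_a <- nrow(alfa) / 2
  da <- sqrt((alfa$x[seq_len(n_a)] - alfa$x[n_a + seq_len(n_a)])^2 +
               (alfa$y[seq_len(n_a)] - alfa$y[n_a + seq_len(n_a)])^2)
  expect_equal(da, rep(4, n_a), tolerance = 1e-9)
})

test_that("opening angles computed from hinge coordinates stay in [30, 330]", {
  cp <- chain_params(segment_count_dist = data.frame(segments = 5, prob = 1),
                     chain_density = 3)
  sim <- simulate_chains(cp, fov = 20000, seed = 12, n_chains = 1000)
  h <- sim$hinges
  angles <- h[, {
    if (.N >= 3) {
      v1x <- x[-c(.N - 1, .N)] - x[-c(1, .N)] # back to previous hinge
      v1y <- y[-c(.N - 1, .N)] - y[-c(1, .N)]
      v2x <- x[-c(1, 2)] - x[-c(1, .N)]       # on to next hinge
      v2y <- y[-c(1, 2)] - y[-c(1, .N)]
      list(ang = acos(pmax(-1, pmin(1, (v1x * v2x + v1y * v2y) /
                                      (sqrt(v1x^2 + v1y^2) *
                                         sqrt(v2x^2 + v2y^2))))) * 180 / pi)
    } else list(ang = numeric(0))
  }, by = chain_id]$ang
  expect_gt(length(angles), 3000)
  expect_true(all(angles >= 30 - 1e-6 & angles <= 330 + 1e-6))
  # angle magnitude is uniform-ish over [30, 180]: both tails populated
  expect_gt(mean(angles < 90), 0.2)
  expect_gt(mean(angles > 120), 0.2)
})

test_that("degenerate chain requests error cleanly", {
  expect_error(chain_params(segment_count_dist =
                              data.frame(segments = integer(0),
                                         prob = numeric(0))), "empty")
  cp <- chain_params()
  expect_error(simulate_chains(cp, fov = 300, seed = 1), "fov too small")
})

test_that("oligomer generator: class geometry and proportions", {
  # pure dimers, no noise, full efficiency, low density: 1st NND == d_intra
  op <- oligomer_params(proportions = c(0, 1, 0, 0), total_density = 0.4,
                        d_intra = 13.5, uncertainty = 0)
  sites <- simulate_oligomers(op, fov = 50000, seed = 3)
  nnd1 <- brute_knn(cbind(sites$x, sites$y), 1)[, 1]
  expect_equal(nnd1, rep(13.5, nrow(sites)), tolerance = 1e-6)
  # monomers only: plain CSR at total density
  opm <- oligomer_params(proportions = c(1, 0, 0, 0), total_density = 20)
  m <- simulate_oligomers(opm, fov = 20000, seed = 4)
  expect_equal(m$molecule_id, m$complex_id) # each molecule its own complex
  # molecule count within 3 sd of Poisson expectation
  lambda <- 20 * 400
  expect_lt(abs(nrow(m) - lambda), 3 * sqrt(lambda))
  # class fractions match requested proportions within multinomial error
  op4 <- oligomer_params(proportions = c(0.4, 0.3, 0.2, 0.1),
                         total_density = 40)
  s4 <- simulate_oligomers(op4, fov = 30000, seed = 5)
  sizes <- s4[, .N, by = complex_id]$N
  frac <- vapply(1:4, function(k) sum(sizes[sizes == k]) / length(s4$x),
                 numeric(1))
  expect_equal(frac, c(0.4, 0.3, 0.2, 0.1), tolerance = 0.05)
  # trimer bridge distance: in a pure-trimer field the 2nd NND of the
  # bridged site equals d_bridge (A-B d_intra, B-C d_bridge)
  opt <- oligomer_params(proportions = c(0, 0, 1, 0), total_density = 0.6,
                         d_intra = 10, d_bridge = 25, uncertainty = 0)
  tri <- simulate_oligomers(opt, fov = 50000, seed = 6)
  per <- split(seq_len(nrow(tri)), tri$complex_id)
  for (idx in per[1:20]) {
    d <- sort(as.vector(stats::dist(cbind(tri$x[idx], tri$y[idx]))))
    expect_equal(length(d), 3L)
    expect_equal(d[1], 10, tolerance = 1e-6)          # intra-dimer bond
    expect_true(any(abs(d - 25) < 1e-6))              # bridge bond present
  }
  expect_error(oligomer_params(proportions = c(0.5, 0.6, 0, 0)), "simplex|sum")
})

test_that("CSR generator matches Poisson closed forms", {
  expect_equal(nrow(simulate_csr(0, 10000, seed = 1)), 0L)
  # mean 1st NND = 1/(2 sqrt(rho)); high density so edge bias is negligible
  rho <- 400 # per um^2
  s <- simulate_csr(rho, 10000, seed = 2)
  core <- s[x > 150 & x < 9850 & y > 150 & y < 9850]
  nnd1 <- knn_distances(cbind(s$x, s$y), 1)[s$x > 150 & s$x < 9850 &
                                              s$y > 150 & s$y < 9850, 1]
  expected <- 1 / (2 * sqrt(rho / 1e6))
  expect_equal(mean(nnd1), expected, tolerance = 0.02)
  # count ~ Poisson(rho * area): 3 sd band
  lambda <- rho * 100
  expect_lt(abs(nrow(s) - lambda), 3 * sqrt(lambda))
  # KS non-rejection against the closed-form NND cdf at alpha = 0.01
  cdf <- function(d) 1 - exp(-(rho / 1e6) * pi * d^2)
  # mutual-NN pairs tie exactly; ties only make the KS test conservative
  suppressWarnings(ksp <- stats::ks.test(nnd1, cdf)$p.value)
  expect_gt(ksp, 0.01)
})

test_that("labeling is Bernoulli with target-specific efficiency", {
  sites <- simulate_csr(25, 20000, seed = 8)
  expect_true(all(!apply_labeling(sites, eff_gfp = 0, seed = 1)$labeled))
  expect_true(all(apply_labeling(sites, eff_gfp = 1, seed = 1)$labeled))
  n <- nrow(sites)
  frac <- mean(apply_labeling(sites, eff_gfp = 0.5, seed = 2)$labeled)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
  # targets use their own efficiency
  sites2 <- data.table::copy(sites)[, target_id := "ALFA"]
  frac_a <- mean(apply_labeling(sites2, eff_alfa = 0.4, seed = 3)$labeled)
  expect_lt(abs(frac_a - 0.4), 3 * sqrt(0.24 / n))
})

test_that("round assignment merges same-round unresolvable pairs", {
  two <- data.table::data.table(x = c(0, 5), y = c(0, 0), z = 0,
                                target_id = "GFP", molecule_id = 1:2,
                                complex_id = 1L, labeled = TRUE)
  # force same round by using 1 round per target
  r1 <- assign_rounds(two, n_rounds_per_target = 1L, merge_radius = 10,
                      seed = 1)
  expect_equal(nrow(r1$sites), 1L)
  expect_equal(r1$sites$x, 2.5) # midpoint
  expect_equal(r1$sites$n_merged, 2L)
  # different rounds -> both survive: find a seed splitting the pair
  for (s in 1:50) {
    r <- assign_rounds(two, n_rounds_per_target = 4L, merge_radius = 10,
                       seed = s)
    if (nrow(r$sites) == 2L) break
  }
  expect_equal(nrow(r$sites), 2L)
  # distant pair never merged
  far <- data.table::copy(two)[, x := c(0, 50)]
  rf <- assign_rounds(far, n_rounds_per_target = 1L, seed = 2)
  expect_equal(nrow(rf$sites), 2L)
})

test_that("dimer same-round collision fraction matches 1/n_rounds", {
  # combinatorial oracle: two sites assigned independently to 4 rounds
  # collide with probability 1/4
  op <- oligomer_params(proportions = c(0, 1, 0, 0), total_density = 2,
                        d_intra = 5, uncertainty = 0)
  sites <- simulate_oligomers(op, fov = 40000, seed = 9)
  sites[, labeled := TRUE]
  rr <- assign_rounds(sites, n_rounds_per_target = 4L, merge_radius = 10,
                      seed = 10)
  n_pairs <- nrow(sites) / 2
  merged <- sum(rr$report$merged_away)
  expect_lt(abs(merged / n_pairs - 0.25), 3 * sqrt(0.25 * 0.75 / n_pairs))
})

test_that("blinking scatter, z spread and law of large numbers", {
  one <- data.table::data.table(x = 1000, y = 2000, z = 0,
                                target_id = "GFP", molecule_id = 1L,
                                complex_id = 1L, labeled = TRUE,
                                round_id = 5L)
  big <- blink_params(mean_K = 10000, sigma_dnapaint_xy = 3,
                      n_frames = 10000)
  tab <- simulate_blinking(one, big, fov = 5000, seed = 1, is_3d = TRUE)
  expect_equal(sd(tab$x), 3, tolerance = 0.05)
  expect_equal(sd(tab$z) / sd(tab$x), 2, tolerance = 0.1)
  # mean_K -> infinity limit: empirical center converges to the site
  expect_lt(abs(mean(tab$x) - 1000), 5 * 3 / sqrt(nrow(tab)))
  expect_lt(abs(mean(tab$y) - 2000), 5 * 3 / sqrt(nrow(tab)))
  # frames uniform over [0, n_frames)
  expect_gte(min(tab$frame), 0)
  expect_lt(max(tab$frame), 10000)
  expect_lt(abs(mean(tab$frame) - 5000), 5 * 10000 / sqrt(12 * nrow(tab)))
  # K >= 1 always: every labeled site appears
  many <- simulate_csr(2, 20000, seed = 2)
  many[, `:=`(labeled = TRUE, round_id = 5L)]
  small_k <- blink_params(mean_K = 0.2, n_frames = 100)
  tab2 <- simulate_blinking(many, small_k, fov = 20000, seed = 3)
  expect_gte(nrow(tab2), nrow(many))
})

test_that("generators are deterministic given (params, seed)", {
  cp <- chain_params()
  a <- simulate_chains(cp, fov = 10000, seed = 5)
  b <- simulate_chains(cp, fov = 10000, seed = 5)
  expect_identical(a, b)
  op <- oligomer_params()
  expect_identical(simulate_oligomers(op, 10000, seed = 6),
                   simulate_oligomers(op, 10000, seed = 6))
  # and the global RNG stream is left untouched
  set.seed(99); before <- .Random.seed
  invisible(simulate_csr(10, 10000, seed = 1))
  expect_identical(.Random.seed, before)
})
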