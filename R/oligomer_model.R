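# Simulation-based least-squares fitting of monomer/dimer/trimer/tetramer
# proportions to observed NND profiles (exhaustive simplex-grid search).
#
# Each candidate composition is simulated as a full mixture (not a per-class
# superposition of NNDs - cross-class neighbors make the NND non-additive),
# with labeling efficiency and 5 nm positional uncertainty applied and the
# total molecule density set so that the detected density matches the
# observation.

#' Enumerate the simplex grid of candidate compositions
#'
#' All 4-part compositions with parts that are multiples of `step` and sum
#' to 1 (1771 candidates at the default 5% step). Candidates are ordered by
#' increasing tetramer, then trimer, then dimer fraction, so that score ties
#' resolve toward fewer higher-order classes.
#'
#' @param step grid step as a fraction (default 0.05).
#' @return matrix with columns p1..p4.
#' @export
simplex_grid <- function(step = 0.05) {
  m <- round(1 / step)
  if (abs(m * step - 1) > 1e-9) stop("1/step must be an integer")
  rows <- list()
  for (l in 0:m) for (k in 0:(m - l)) for (j in 0:(m - l - k)) {
    rows[[length(rows) + 1L]] <- c(m - l - k - j, j, k, l)
  }
  g <- do.call(rbind, rows) / m
  colnames(g) <- c("p1", "p2", "p3", "p4")
  g
}

# detected point set of a candidate mixture; lean path used in the fit loop.
# total molecule density = detected_density / eff; complex counts are rounded
# expected values (low variance); labeling and uncertainty applied.
mixture_detected_xy <- function(proportions, detected_density_um2, eff,
                                uncertainty, d_intra, d_bridge, fov) {
  area <- fov_area_um2(fov)
  total_mol <- detected_density_um2 / eff * area
  n_complex <- as.integer(round(proportions * total_mol / (1:4)))
  ms <- mixture_sites(n_complex, d_intra, d_bridge, fov)
  n <- nrow(ms$xy)
  if (n == 0L) return(matrix(numeric(0), ncol = 2))
  keep <- stats::runif(n) < eff
  xy <- ms$xy[keep, , drop = FALSE]
  if (uncertainty > 0 && nrow(xy)) {
    xy <- xy + matrix(stats::rnorm(length(xy), 0, uncertainty), ncol = 2)
  }
  xy
}

#' Simulate the detected NND profile of an oligomer mixture
#'
#' Ground truth from the oligomer generator with complex counts matching the
#' molecule proportions, 5 nm (default) Gaussian uncertainty, Bernoulli
#' labeling; the NND profile is computed on the detectable subset. The total
#' molecule density is `params$total_density`; the detected density is
#' `eff_gfp` times that.
#'
#' @param proportions length-4 simplex of molecule fractions.
#' @param params an [oligomer_params()] (its `proportions` field is ignored
#'   in favor of the argument).
#' @param fov field of view in nm.
#' @param seed integer seed.
#' @param orders,bin_width,r_max profile settings.
#' @return an `nnd_profile` of the detected points.
#' @export
simulate_mixture <- function(proportions, params, fov, seed = NULL,
                             orders = 1:3, bin_width = 1, r_max = 200) {
  check_simplex(proportions)
  stopifnot(inherits(params, "oligomer_params"))
  if (length(fov) == 1L) fov <- c(fov, fov)
  with_seed(seed, {
    xy <- mixture_detected_xy(proportions,
                              detected_density_um2 =
                                params$total_density * params$eff_gfp,
                              eff = params$eff_gfp,
                              uncertainty = params$uncertainty,
                              d_intra = params$d_intra,
                              d_bridge = params$d_bridge, fov = fov)
    nnd_profile(xy, orders = orders, bin_width = bin_width, r_max = r_max)
  })
}

#' Fit oligomer proportions by simulation-based least squares
#'
#' Exhaustive evaluation of the simplex grid: each candidate composition is
#' simulated `n_reps` times at the observed detected density over `sim_fov`,
#' profiled, and scored against the observed profile
#' ([nnd_least_squares()]); the fitted composition is the argmin of the
#' replicate-averaged score. The full trace is retained so flat valleys are
#' visible; exact ties resolve toward fewer higher-order classes.
#'
#' @param observed an `nnd_profile` of the observed receptor channel, with
#'   orders covering `orders`.
#' @param observed_density_um2 detected molecule density of the observation
#'   (points per square micrometer).
#' @param params an [oligomer_params()] carrying the fixed geometry,
#'   efficiency and uncertainty.
#' @param grid_step simplex grid step (default 0.05).
#' @param n_reps simulations per candidate (default 3).
#' @param orders NND orders of the objective (default 1:3, where non-CSR
#'   peaks are informative; configurable to 1:6).
#' @param sim_fov field of view of the candidate simulations in nm (smaller
#'   than the observation for speed; default 6000).
#' @param refine also search a 0.01-step local grid around the coarse
#'   optimum (default FALSE).
#' @param seed integer seed.
#' @return an `oligomer_fit`: `proportions_hat`, `residual`, `trace`
#'   (candidate compositions and scores), settings.
#' @export
fit_proportions <- function(observed, observed_density_um2, params =
                              oligomer_params(), grid_step = 0.05,
                            n_reps = 3L, orders = 1:3, sim_fov = 6000,
                            refine = FALSE, seed = 1L) {
  if (!inherits(observed, "nnd_profile")) {
    stop("observed must be an nnd_profile")
  }
  if (!all(orders %in% observed$orders)) {
    stop("observed profile must cover the configured orders")
  }
  if (observed$n_points == 0L) stop("empty observed profile")
  assert_scalar_pos(observed_density_um2, "observed_density_um2")
  if (length(sim_fov) == 1L) sim_fov <- c(sim_fov, sim_fov)
  # restrict observed freq to the configured orders
  sel <- match(orders, observed$orders)
  obs_freq <- observed$freq[, sel, drop = FALSE]
  bw <- diff(observed$bin_edges[1:2])
  r_max <- max(observed$bin_edges)
  nb <- length(observed$bin_edges) - 1L
  kmax <- max(orders)
  eval_candidate <- function(p, ci) {
    s <- numeric(n_reps)
    for (rj in seq_len(n_reps)) {
      s[rj] <- with_seed(derive_seed(seed, "oligofit",
                                     index = ci * 100L + rj), {
        xy <- mixture_detected_xy(p, observed_density_um2, params$eff_gfp,
                                  params$uncertainty, params$d_intra,
                                  params$d_bridge, sim_fov)
        if (nrow(xy) < kmax + 1L) {
          Inf
        } else {
          nnd <- FNN::get.knn(xy, k = kmax)$nn.dist
          freq <- vapply(orders, function(k) {
            idx <- floor(nnd[, k] / bw) + 1
            tabulate(idx[idx <= nb], nbins = nb)
          }, integer(nb)) / nrow(xy)
          sum((obs_freq - freq)^2)
        }
      })
    }
    mean(s)
  }
  search <- function(grid, ci0) {
    scores <- numeric(nrow(grid))
    for (ci in seq_len(nrow(grid))) {
      scores[ci] <- eval_candidate(grid[ci, ], ci0 + ci)
    }
    scores
  }
  grid <- simplex_grid(grid_step)
  scores <- search(grid, 0L)
  best <- which.min(scores) # first minimum = fewest higher-order classes
  trace <- data.table::data.table(grid, score = scores)
  p_hat <- grid[best, ]
  residual <- scores[best]
  if (refine) {
    fine <- simplex_grid(0.01)
    keep <- rowSums(abs(sweep(fine, 2, p_hat)) <= grid_step + 1e-9) == 4L
    fine <- fine[keep, , drop = FALSE]
    fscores <- search(fine, nrow(grid))
    if (min(fscores) < residual) {
      fb <- which.min(fscores)
      p_hat <- fine[fb, ]
      residual <- fscores[fb]
    }
    trace <- rbind(trace, data.table::data.table(fine, score = fscores))
  }
  structure(list(proportions_hat = p_hat, residual = residual,
                 trace = trace, grid_step = grid_step, n_reps = n_reps,
                 orders = orders, sim_fov = sim_fov,
                 observed_density_um2 = observed_density_um2,
                 params = params),
            class = "oligomer_fit")
}

#' @export
print.oligomer_fit <- function(x, ...) {
  p <- x$proportions_hat * 100
  cat(sprintf(paste0("oligomer mixture fit: %.0f%% monomers, %.0f%% dimers, ",
                     "%.0f%% trimers, %.0f%% tetramers (residual %.3g)\n"),
              p[1], p[2], p[3], p[4], x$residual))
  invisible(x)
}

#' Summarize trimer + tetramer fractions across replicate fits
#'
#' @param fits list of `oligomer_fit` objects (one per cell/replicate).
#' @param condition optional vector of condition labels (one per fit); when
#'   given, aggregates are reported per condition.
#' @return data.table: condition, n, mean and s.d. (NA for a single fit) of
#'   the trimer+tetramer percentage, plus per-class mean percentages.
#' @export
trimer_tetramer_summary <- function(fits, condition = NULL) {
  if (!length(fits)) stop("no fits supplied")
  p <- t(vapply(fits, function(f) f$proportions_hat, numeric(4)))
  ho <- 100 * (p[, 3] + p[, 4])
  cond <- condition %||% rep("all", length(fits))
  dt <- data.table::data.table(condition = cond, higher_order_pct = ho,
                               monomer_pct = 100 * p[, 1],
                               dimer_pct = 100 * p[, 2])
  dt[, .(n = .N,
         mean_trimer_tetramer_pct = mean(higher_order_pct),
         sd_trimer_tetramer_pct = if (.N > 1) stats::sd(higher_order_pct)
                                  else NA_real_,
         mean_monomer_pct = mean(monomer_pct),
         mean_dimer_pct = mean(dimer_pct)),
     by = condition]
}

#' Antibody-channel first-NND peak report
#'
#' The ALFA (antibody) channel of a two-site-labeled antibody should show a
#' non-random excess only in the first NND (the intramolecular label pair);
#' higher-order antibody assemblies would add excess to later orders. Reports
#' the fraction of kth NNDs below a short-distance cutoff for the data and
#' for a matched-density CSR reference.
#'
#' @param alfa_points antibody RESI table.
#' @param fov field of view in nm.
#' @param cutoff short-distance cutoff in nm (default 2x the 4 nm
#'   intramolecular label spacing, plus headroom for 5 nm noise: 15 nm).
#' @param orders NND orders to report (default 1:3).
#' @param seed integer seed for the CSR reference.
#' @return data.table: order, fraction below cutoff in data and CSR, excess.
#' @export
alfa_peak_report <- function(alfa_points, fov, cutoff = 15, orders = 1:3,
                             seed = 1L) {
  prof <- nnd_profile(alfa_points, orders = orders)
  ref <- csr_reference(alfa_points, fov, seed = seed, orders = orders)
  frac_below <- function(p) {
    apply(p$nnd, 2, function(d) mean(d < cutoff))
  }
  fd <- frac_below(prof); fr <- frac_below(ref)
  data.table::data.table(order = orders, frac_data = fd, frac_csr = fr,
                         excess = fd - fr)
}
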