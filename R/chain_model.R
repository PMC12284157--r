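# Flexible-chain segment-length fitting.
#
# The observed receptor NND profile is compared against chain simulations at
# candidate hinge-to-hinge segment lengths; the simulations are pinned to the
# experimentally determined cluster-size frequencies and cluster density
# (from the single-target DBSCAN), with labeling efficiency and positional
# uncertainty applied. The candidate minimizing the summed squared frequency
# differences is the fitted length; its uncertainty is the first
# significantly distinguishable offset under a Monte-Carlo t-test scheme.

#' Sum-of-least-squares score between two NND profiles
#'
#' Sum over orders and bins of squared frequency differences. Frequencies
#' (counts / n_points) are used so that differing point counts or densities
#' do not dominate the comparison.
#'
#' @param observed,simulated `nnd_profile` objects with identical orders and
#'   bin edges.
#' @return scalar score (0 for identical profiles).
#' @export
nnd_least_squares <- function(observed, simulated) {
  if (!identical(observed$orders, simulated$orders) ||
      !isTRUE(all.equal(observed$bin_edges, simulated$bin_edges))) {
    stop("mismatched binning: profiles must share orders and bin edges")
  }
  sum((observed$freq - simulated$freq)^2)
}

#' Extract chain-simulation inputs from single-target cluster analysis
#'
#' @param points receptor RESI table.
#' @param fov field of view in nm.
#' @param eps,min_size single-target DBSCAN settings.
#' @return `cluster_stats`: size frequency table and cluster density, the
#'   fixed parameters of the chain simulations.
#' @export
chain_cluster_stats <- function(points, fov, eps = 20, min_size = 2L) {
  cs <- dbscan_single_target(points, eps = eps, min_size = min_size,
                             fov = fov)
  list(size_freq = cs$size_freq, density_um2 = cs$density_um2,
       n_clusters = cs$n_clusters)
}

#' Simulate the detected receptor point set of a chain model
#'
#' Builds chains at segment length `L` with segment counts drawn from the
#' cluster-size frequencies and chain density equal to the cluster density,
#' keeps the GFP sites, applies Bernoulli labeling and Gaussian uncertainty,
#' and returns the detected coordinates.
#'
#' @param L segment length in nm.
#' @param cluster_stats from [chain_cluster_stats()].
#' @param fov field of view in nm.
#' @param params a [chain_params()] supplying the fixed geometry (dimer
#'   distance, angle range), efficiency and uncertainty; `segment_length`,
#'   `segment_count_dist` and `chain_density` are overridden.
#' @param seed integer seed.
#' @return matrix of detected GFP coordinates.
#' @export
simulate_chain_gfp <- function(L, cluster_stats, fov, params = chain_params(),
                               seed = NULL) {
  p <- params
  p$segment_length <- L
  p$segment_count_dist <- data.frame(segments = cluster_stats$size_freq$size,
                                     prob = cluster_stats$size_freq$prob)
  p$chain_density <- cluster_stats$density_um2
  with_seed(seed, {
    ch <- simulate_chains(p, fov)
    gfp <- ch$sites[target_id == "GFP"]
    gfp <- apply_labeling(gfp, eff_alfa = p$eff_alfa, eff_gfp = p$eff_gfp)
    gfp <- gfp[labeled == TRUE]
    gfp <- apply_uncertainty(gfp, sd = p$uncertainty)
    cbind(gfp$x, gfp$y)
  })
}

chain_profile_at <- function(L, cluster_stats, fov, params, seed, orders,
                             bin_width, r_max) {
  xy <- simulate_chain_gfp(L, cluster_stats, fov, params, seed)
  nnd_profile(xy, orders = orders, bin_width = bin_width, r_max = r_max)
}

#' Fit the chain segment length by NND least squares over a grid
#'
#' For each candidate length, `n_reps` chain simulations (pinned to the
#' observed cluster-size frequencies and density) are profiled and scored
#' against the observed NND profile; the fitted length is the argmin of the
#' replicate-averaged score.
#'
#' @param observed receptor points (table/matrix) or an `nnd_profile`.
#' @param cluster_stats from [chain_cluster_stats()].
#' @param fov field of view in nm (used for the candidate simulations; when
#'   `observed` is a point set it is also profiled over this fov).
#' @param grid candidate segment lengths in nm (default 10:40; brackets
#'   plausible IgG hinge-to-hinge distances with margin).
#' @param params a [chain_params()] carrying the fixed geometry.
#' @param n_reps simulations per candidate (default 3).
#' @param orders NND orders in the objective (default 1:6).
#' @param bin_width,r_max histogram settings.
#' @param seed integer seed; candidate/replicate streams are derived from it.
#' @return a `chain_fit`: `L_hat`, `grid`, `residuals` (mean score per
#'   candidate), `residual_matrix` (candidate x replicate), settings.
#' @export
fit_segment_length <- function(observed, cluster_stats, fov, grid = 10:40,
                               params = chain_params(), n_reps = 3L,
                               orders = 1:6, bin_width = 1, r_max = 200,
                               seed = 1L) {
  if (any(grid <= 0)) stop("grid lengths must be positive")
  grid <- sort(grid)
  obs_profile <- if (inherits(observed, "nnd_profile")) observed else
    nnd_profile(observed, orders = orders, bin_width = bin_width,
                r_max = r_max)
  if (!identical(obs_profile$orders, orders)) {
    stop("observed profile orders differ from requested orders")
  }
  scores <- matrix(NA_real_, nrow = length(grid), ncol = n_reps)
  for (ci in seq_along(grid)) {
    for (rj in seq_len(n_reps)) {
      sp <- chain_profile_at(grid[ci], cluster_stats, fov, params,
                             seed = derive_seed(seed, "chainfit",
                                                index = ci * 1000L + rj),
                             orders = orders, bin_width = bin_width,
                             r_max = r_max)
      scores[ci, rj] <- nnd_least_squares(obs_profile, sp)
    }
  }
  mean_scores <- rowMeans(scores)
  structure(list(L_hat = grid[which.min(mean_scores)], grid = grid,
                 residuals = mean_scores, residual_matrix = scores,
                 n_reps = n_reps, orders = orders,
                 cluster_stats = cluster_stats),
            class = "chain_fit")
}

#' @export
print.chain_fit <- function(x, ...) {
  cat(sprintf("chain segment-length fit: L_hat = %g nm (grid %g-%g nm, %d reps)\n",
              x$L_hat, min(x$grid), max(x$grid), x$n_reps))
  if (!is.null(x$uncertainty)) {
    cat(sprintf("  Monte-Carlo uncertainty: %g nm\n", x$uncertainty))
  }
  invisible(x)
}

#' Monte-Carlo uncertainty of the fitted segment length
#'
#' Generates `n_optimal` reference ("optimal") chain simulations at the
#' fitted length; each reference is re-clustered to obtain its own cluster
#' sizes, which parameterize `n_iter` iterating simulations per reference at
#' each candidate length. Sums of least squares over the 1st-10th NND
#' histograms of iterating vs. reference simulations are compared between the
#' fitted length and each offset with a two-sided unpaired t-test; the
#' smallest offset with a significant difference is the uncertainty.
#'
#' @param L_star fitted segment length in nm.
#' @param cluster_stats observed cluster statistics (see
#'   [chain_cluster_stats()]), used to generate the reference simulations.
#' @param fov field of view in nm.
#' @param params a [chain_params()].
#' @param grid_step offset step in nm (default 1).
#' @param max_offset largest offset searched, in nm (default 8).
#' @param n_optimal reference simulations (default 3).
#' @param n_iter iterating simulations per reference (default 3).
#' @param alpha significance level of the unpaired t-test (default 0.05).
#' @param orders NND orders (default 1:10).
#' @param bin_width,r_max histogram settings.
#' @param seed integer seed.
#' @return list: `uncertainty` (nm; NA when unresolved), `resolved`,
#'   `alpha`, and `detail` (per offset/side: mean score and p value).
#' @export
mc_uncertainty <- function(L_star, cluster_stats, fov,
                           params = chain_params(), grid_step = 1,
                           max_offset = 8, n_optimal = 3L, n_iter = 3L,
                           alpha = 0.05, orders = 1:10, bin_width = 1,
                           r_max = 200, seed = 1L) {
  if (L_star <= 0) stop("L_star must be positive")
  refs <- lapply(seq_len(n_optimal), function(r) {
    xy <- simulate_chain_gfp(L_star, cluster_stats, fov, params,
                             seed = derive_seed(seed, "mcref", index = r))
    list(profile = nnd_profile(xy, orders = orders, bin_width = bin_width,
                               r_max = r_max),
         stats = chain_cluster_stats(data.table::data.table(x = xy[, 1],
                                                            y = xy[, 2]),
                                     fov))
  })
  scores_at <- function(L, tag) {
    unlist(lapply(seq_len(n_optimal), function(r) {
      vapply(seq_len(n_iter), function(j) {
        tryCatch({
          sp <- chain_profile_at(L, refs[[r]]$stats, fov, params,
                                 seed = derive_seed(seed, tag,
                                                    index = round(L * 1000) +
                                                      r * 10L + j),
                                 orders = orders, bin_width = bin_width,
                                 r_max = r_max)
          nnd_least_squares(refs[[r]]$profile, sp)
        }, error = function(e) NA_real_) # too few points at this scale
      }, numeric(1))
    }))
  }
  base_scores <- scores_at(L_star, "mcbase")
  if (sum(!is.na(base_scores)) < 2L) {
    return(list(uncertainty = NA_real_, resolved = FALSE, alpha = alpha,
                base_mean_score = NA_real_,
                detail = data.table::data.table()))
  }
  offsets <- seq(grid_step, max_offset, by = grid_step)
  detail <- list()
  uncertainty <- NA_real_
  for (d in offsets) {
    found <- FALSE
    for (side in c(-1, 1)) {
      L <- L_star + side * d
      if (L <= 0) next
      sc <- scores_at(L, "mciter")
      if (sum(!is.na(sc)) < 2L) next
      p <- stats::t.test(base_scores, sc, var.equal = TRUE)$p.value
      detail[[length(detail) + 1L]] <- data.table::data.table(
        offset = side * d, mean_score = mean(sc), p_value = p,
        significant = p < alpha)
      if (p < alpha) found <- TRUE
    }
    if (found) { uncertainty <- d; break }
  }
  list(uncertainty = uncertainty, resolved = !is.na(uncertainty),
       alpha = alpha, base_mean_score = mean(base_scores),
       detail = data.table::rbindlist(detail))
}
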