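# End-to-end orchestration: simulate -> (blink -> RESI) -> co-cluster ->
# analyze -> fit -> report, with one global seed expanded into per-stage
# streams so toggling a stage does not perturb the others.

#' Ground-truth oligomer compositions for the built-in condition labels
#'
#' "OBZ-like" is the representative Type II composition (35/48/10/7%
#' monomer/dimer/trimer/tetramer). For the T-cell-engager conditions only the
#' trimer+tetramer percentage is an experimental aggregate (i-TCE 49.6%,
#' c-TCE 27.2%); the remaining mass is distributed across monomer/dimer at
#' the OBZ 35:48 ratio and across trimer/tetramer at the OBZ 10:7 ratio.
#'
#' @param condition one of "OBZ-like", "c-TCE-like", "i-TCE-like".
#' @return length-4 simplex of molecule fractions.
#' @export
condition_proportions <- function(condition) {
  split4 <- function(higher) {
    lower <- 1 - higher
    c(lower * 35 / 83, lower * 48 / 83, higher * 10 / 17, higher * 7 / 17)
  }
  switch(condition,
         "OBZ-like" = c(0.35, 0.48, 0.10, 0.07),
         "c-TCE-like" = split4(0.272),
         "i-TCE-like" = split4(0.496),
         stop("unknown oligomer condition: ", condition))
}

#' Build a pipeline configuration
#'
#' All analysis thresholds default to the standard settings (40 nm
#' co-clustering, 20 nm single-target clustering, 25 nm / 5 ALFA platform
#' rule, 20%/80% mean-frame and 80%-in-5% window filters) and every one
#' is overridable.
#'
#' @param condition "RTX-like" or "OFA-like" (flexible chains; segment length
#'   23 and 17 nm respectively) or "OBZ-like" / "c-TCE-like" / "i-TCE-like"
#'   (low-order oligomers).
#' @param seed global seed; recorded in all outputs.
#' @param fov field of view in nm.
#' @param out_dir optional output directory for artifacts.
#' @param ... overrides of the default settings (see the returned list).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(condition = "RTX-like", seed = 1L, fov = 10000,
                            out_dir = NULL, ...) {
  cfg <- list(
    condition = condition, seed = as.integer(seed), fov = fov,
    out_dir = out_dir,
    # stage toggles
    do_blinking = FALSE, do_ratio = NULL, do_fit = TRUE, do_mc = FALSE,
    do_platforms = NULL,
    # generator settings
    chain = list(segment_length = if (condition == "OFA-like") 17 else 23,
                 chain_density = 7.5, eff_alfa = 0.40, eff_gfp = 0.50,
                 uncertainty = 5),
    oligomer = list(total_density = 50, eff_gfp = 0.50, uncertainty = 5,
                    d_intra = 13.5, d_bridge = 13.5),
    blink = list(mean_K = 25, sigma_dnapaint_xy = 3, n_frames = 5000L,
                 sticking_rate = 0),
    resi = list(radius_r = 6, n_min = 10),
    # analysis settings
    cocluster_eps = 40, single_eps = 20, single_min = 2L,
    platform_radius = 25, platform_min = 5L,
    nnd_orders = 1:6, bin_width = 1, r_max = 200,
    # fit settings
    fit_grid = 10:40, fit_reps = 3L, fit_orders = 1:6,
    mc_max_offset = 8, mc_orders = 1:10,
    oligo_grid_step = 0.05, oligo_reps = 3L, oligo_orders = 1:3,
    oligo_sim_fov = 6000)
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  is_chain <- cfg$condition %in% c("RTX-like", "OFA-like")
  cfg$do_ratio <- cfg$do_ratio %||% is_chain
  cfg$do_platforms <- cfg$do_platforms %||% is_chain
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file; keys as in [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("condition", "seed", "fov", "out_dir"))]
  do.call(pipeline_config,
          c(list(condition = y$condition %||% "RTX-like",
                 seed = y$seed %||% 1L, fov = y$fov %||% 10000,
                 out_dir = y$out_dir), args))
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the requested stages in order on synthetic data for the
#' configured condition: ground-truth simulation, labeling and positional
#' uncertainty, optionally blinking + RESI grouping, DBSCAN co-clustering and
#' ratio analysis (chain conditions), single-target cluster statistics, NND
#' profiling, model fitting (chain segment length or oligomer proportions),
#' optional Monte-Carlo uncertainty, and C1q platform counting. Emits a
#' machine-readable summary; with `out_dir` set, writes `summary.json`,
#' `config.yaml` and per-stage CSV artifacts.
#'
#' @param config a [pipeline_config()].
#' @return the summary (named list), invisibly also written to disk when
#'   `out_dir` is configured.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  is_chain <- cfg$condition %in% c("RTX-like", "OFA-like")
  fov <- cfg$fov
  summary <- list(condition = cfg$condition, seed = cfg$seed,
                  fov_nm = fov, settings = cfg[setdiff(names(cfg),
                                                       c("out_dir"))])
  # --- simulate ground truth -------------------------------------------
  if (is_chain) {
    cp <- do.call(chain_params, cfg$chain)
    sim <- simulate_chains(cp, fov, seed = derive_seed(cfg$seed, "simulate"))
    sites <- sim$sites
    eff_a <- cp$eff_alfa; eff_g <- cp$eff_gfp; unc <- cp$uncertainty
  } else {
    op <- do.call(oligomer_params,
                  c(list(proportions = condition_proportions(cfg$condition)),
                    cfg$oligomer))
    sites <- simulate_oligomers(op, fov,
                                seed = derive_seed(cfg$seed, "simulate"))
    eff_a <- 0.40; eff_g <- op$eff_gfp; unc <- op$uncertainty
  }
  sites <- apply_labeling(sites, eff_alfa = eff_a, eff_gfp = eff_g,
                          seed = derive_seed(cfg$seed, "labeling"))
  detected <- apply_uncertainty(sites[labeled == TRUE], sd = unc,
                                seed = derive_seed(cfg$seed, "noise"))
  # --- optional blinking + RESI ----------------------------------------
  if (isTRUE(cfg$do_blinking)) {
    rounds <- assign_rounds(detected, seed = derive_seed(cfg$seed, "rounds"))
    bp <- do.call(blink_params, cfg$blink)
    table <- simulate_blinking(rounds$sites, bp, fov,
                               seed = derive_seed(cfg$seed, "blinking"))
    parts <- split_by_target(table)
    rp <- cluster_params(cfg$resi$radius_r, cfg$resi$n_min)
    resi <- lapply(parts, resi_pipeline, params = rp)
    alfa <- resi[["ALFA"]] %||% data.table::data.table(x = numeric(0),
                                                       y = numeric(0))
    gfp <- resi[["GFP"]] %||% data.table::data.table(x = numeric(0),
                                                     y = numeric(0))
  } else {
    alfa <- detected[target_id == "ALFA"]
    gfp <- detected[target_id == "GFP"]
  }
  summary$n_alfa_detected <- nrow(alfa)
  summary$n_gfp_detected <- nrow(gfp)
  # --- co-clustering / ratio (needs both channels) ---------------------
  cocl <- NULL
  if (isTRUE(cfg$do_ratio)) {
    if (nrow(alfa) == 0L) {
      stop("missing artifact: ALFA channel (ratio stage needs a two-target ",
           "condition)")
    }
    cocl <- dbscan_cocluster(alfa, gfp, eps = cfg$cocluster_eps)
    rf <- ratio_analysis(cocl$clusters, eff_alfa = eff_a, eff_gfp = eff_g)
    summary$ratio <- list(slope_mab_per_gfp = rf$slope,
                          intercept = rf$intercept,
                          normalized_mab_per_receptor = rf$normalized_ratio,
                          n_coclusters = rf$n_clusters)
  }
  # --- single-target stats + NND profile -------------------------------
  stats1 <- chain_cluster_stats(gfp, fov, eps = cfg$single_eps,
                                min_size = cfg$single_min)
  summary$single_target <- list(n_clusters = stats1$n_clusters,
                                cluster_density_um2 = stats1$density_um2)
  profile <- nnd_profile(gfp, orders = cfg$nnd_orders,
                         bin_width = cfg$bin_width, r_max = cfg$r_max)
  summary$nnd_mean_nm <- as.list(stats::setNames(
    colMeans(profile$nnd), paste0("order", cfg$nnd_orders)))
  # --- model fitting ----------------------------------------------------
  if (isTRUE(cfg$do_fit)) {
    if (is_chain) {
      fit <- fit_segment_length(gfp, stats1, fov, grid = cfg$fit_grid,
                                params = do.call(chain_params, cfg$chain),
                                n_reps = cfg$fit_reps,
                                orders = cfg$fit_orders,
                                bin_width = cfg$bin_width, r_max = cfg$r_max,
                                seed = derive_seed(cfg$seed, "fit"))
      summary$chain_fit <- list(L_hat_nm = fit$L_hat,
                                grid_nm = range(cfg$fit_grid))
      if (isTRUE(cfg$do_mc)) {
        mc <- mc_uncertainty(fit$L_hat, stats1, fov,
                             params = do.call(chain_params, cfg$chain),
                             max_offset = cfg$mc_max_offset,
                             orders = cfg$mc_orders,
                             bin_width = cfg$bin_width, r_max = cfg$r_max,
                             seed = derive_seed(cfg$seed, "mc"))
        summary$chain_fit$uncertainty_nm <- mc$uncertainty
        summary$chain_fit$mc_resolved <- mc$resolved
      }
    } else {
      obs_prof <- nnd_profile(gfp, orders = cfg$oligo_orders,
                              bin_width = cfg$bin_width, r_max = cfg$r_max)
      dens <- nrow(gfp) / (fov_area_um2(c(fov, fov)[1:2]))
      op <- do.call(oligomer_params,
                    c(list(proportions = condition_proportions(cfg$condition)),
                      cfg$oligomer))
      fit <- fit_proportions(obs_prof, dens, params = op,
                             grid_step = cfg$oligo_grid_step,
                             n_reps = cfg$oligo_reps,
                             orders = cfg$oligo_orders,
                             sim_fov = cfg$oligo_sim_fov,
                             seed = derive_seed(cfg$seed, "fit"))
      p <- fit$proportions_hat
      summary$oligomer_fit <- list(
        monomer_pct = 100 * p[[1]], dimer_pct = 100 * p[[2]],
        trimer_pct = 100 * p[[3]], tetramer_pct = 100 * p[[4]],
        trimer_tetramer_pct = 100 * (p[[3]] + p[[4]]),
        residual = fit$residual)
    }
  }
  # --- C1q platforms ----------------------------------------------------
  if (isTRUE(cfg$do_platforms)) {
    if (nrow(alfa) == 0L) {
      stop("missing artifact: ALFA channel (platform stage)")
    }
    pl <- count_c1q_platforms(alfa, radius = cfg$platform_radius,
                              min_count = cfg$platform_min)
    summary$platforms <- list(n_configs = pl$n_platform_configs,
                              per_um2 = pl$n_platform_configs /
                                fov_area_um2(c(fov, fov)[1:2]))
  }
  # --- write artifacts --------------------------------------------------
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    yaml::write_yaml(cfg[setdiff(names(cfg), "out_dir")],
                     file.path(cfg$out_dir, "config.yaml"))
    data.table::fwrite(gfp, file.path(cfg$out_dir, "gfp_points.csv"))
    if (nrow(alfa)) {
      data.table::fwrite(alfa, file.path(cfg$out_dir, "alfa_points.csv"))
    }
    if (!is.null(cocl)) {
      data.table::fwrite(cocl$clusters,
                         file.path(cfg$out_dir, "coclusters.csv"))
    }
  }
  invisible(summary)
}
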