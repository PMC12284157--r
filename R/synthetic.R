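# Synthetic DNA-PAINT / RESI data generator.
#
# The generator builds ground-truth molecular arrangements on a planar
# membrane (the z = 0 plane), applies per-site Bernoulli labeling, assigns
# labeled sites to orthogonal imaging rounds (merging same-round pairs that
# DNA-PAINT cannot resolve), and emits blinking localization tables with
# Gaussian scatter, uniform frame times and transient sticking artifacts.

#' Parameters of the flexible-chain arrangement
#'
#' Chains model receptor dimers concatenated by bivalent antibodies: hinge
#' points (antibody hinge regions) are connected by straight segments of
#' length `segment_length`; each segment midpoint carries one receptor dimer
#' (2 GFP sites `d_gfp_dimer` apart, oriented along the segment) and each
#' hinge carries one antibody (2 ALFA sites `d_alfa_pair` apart, random
#' orientation). Consecutive segments open at an angle drawn uniformly from
#' `opening_angle_range` (180 deg = straight; the range excludes
#' near-complete fold-back below 30 deg).
#'
#' @param segment_length hinge-to-hinge distance L in nm.
#' @param opening_angle_range allowed inter-segment opening angle in degrees.
#' @param d_gfp_dimer within-dimer GFP-site separation in nm (experimentally
#'   determined label-to-label distance for a receptor dimer).
#' @param d_alfa_pair ALFA-site separation per antibody in nm.
#' @param segment_count_dist data.frame with columns `segments` (integer) and
#'   `prob`; probability table over the number of segments per chain. The
#'   default is a truncated geometric distribution over 1..20 (decay 0.3,
#'   mean about 3.3 segments): cluster-size histograms of chain-forming
#'   conditions decay from mostly small clusters to a tail of tens of
#'   molecules, and the segment-length fit parameterizes its simulations by
#'   detected cluster sizes, which presumes most chains are short.
#' @param chain_density chains per square micrometer; the default, together
#'   with the default segment distribution, gives a total receptor density of
#'   about 50 molecules per square micrometer.
#' @param eff_alfa,eff_gfp per-site labeling efficiencies (detection
#'   probabilities of the ALFA and GFP nanobodies).
#' @param uncertainty positional noise s.d. in nm (linkage error plus residual
#'   localization error), applied isotropically per coordinate.
#' @return a `chain_params` object.
#' @export
chain_params <- function(segment_length = 23,
                         opening_angle_range = c(30, 330),
                         d_gfp_dimer = 13.5,
                         d_alfa_pair = 4,
                         segment_count_dist = truncated_geometric(0.3, 20),
                         chain_density = 7.5,
                         eff_alfa = 0.40,
                         eff_gfp = 0.50,
                         uncertainty = 5) {
  assert_scalar_pos(segment_length, "segment_length")
  if (length(opening_angle_range) != 2L ||
      opening_angle_range[1] <= 0 || opening_angle_range[2] >= 360 ||
      opening_angle_range[1] > opening_angle_range[2]) {
    stop("opening_angle_range must be inside (0, 360) degrees")
  }
  assert_prob(eff_alfa, "eff_alfa"); assert_prob(eff_gfp, "eff_gfp")
  if (nrow(segment_count_dist) == 0L) stop("empty segment_count_dist")
  if (abs(sum(segment_count_dist$prob) - 1) > 1e-8) {
    stop("segment_count_dist probabilities must sum to 1")
  }
  assert_scalar_pos(chain_density, "chain_density")
  structure(list(segment_length = segment_length,
                 opening_angle_range = as.numeric(opening_angle_range),
                 d_gfp_dimer = d_gfp_dimer, d_alfa_pair = d_alfa_pair,
                 segment_count_dist = segment_count_dist,
                 chain_density = chain_density,
                 eff_alfa = eff_alfa, eff_gfp = eff_gfp,
                 uncertainty = uncertainty),
            class = "chain_params")
}

#' Truncated geometric probability table
#'
#' Helper for segment-count distributions: `P(s) ~ p (1-p)^(s-1)` on
#' `1..smax`, renormalized.
#'
#' @param p decay parameter in (0, 1).
#' @param smax upper truncation.
#' @return data.frame with columns `segments`, `prob`.
#' @export
truncated_geometric <- function(p, smax = 20L) {
  assert_prob(p, "p")
  pr <- p * (1 - p)^(0:(smax - 1L))
  data.frame(segments = seq_len(smax), prob = pr / sum(pr))
}

#' Parameters of the low-order oligomer arrangement
#'
#' Complexes are monomers, dimers, trimers and tetramers of the receptor.
#' Dimers are two sites `d_intra` apart; a trimer adds a third site bridged
#' at `d_bridge` from one dimer member; a tetramer bridges two dimers at
#' `d_bridge` (a chain-like A-B~C-D arrangement, with ~ the bridged bond).
#' `proportions` are fractions of molecules (not complexes) in each class.
#'
#' @param proportions length-4 simplex: monomer/dimer/trimer/tetramer
#'   molecule fractions.
#' @param d_intra within-dimer spacing in nm.
#' @param d_bridge bridged inter-dimer spacing in nm. Never printed for the
#'   system emulated here; the default simply reuses `d_intra` and should be
#'   treated as a configurable model choice.
#' @param total_density molecules per square micrometer.
#' @param eff_gfp labeling efficiency.
#' @param uncertainty positional noise s.d. in nm.
#' @return an `oligomer_params` object.
#' @export
oligomer_params <- function(proportions = c(0.35, 0.48, 0.10, 0.07),
                            d_intra = 13.5, d_bridge = 13.5,
                            total_density = 50, eff_gfp = 0.50,
                            uncertainty = 5) {
  check_simplex(proportions)
  assert_scalar_pos(total_density, "total_density")
  assert_prob(eff_gfp, "eff_gfp")
  structure(list(proportions = as.numeric(proportions), d_intra = d_intra,
                 d_bridge = d_bridge, total_density = total_density,
                 eff_gfp = eff_gfp, uncertainty = uncertainty),
            class = "oligomer_params")
}

check_simplex <- function(p) {
  if (length(p) != 4L || any(!is.finite(p)) || any(p < 0) ||
      abs(sum(p) - 1) > 1e-6) {
    stop("proportions must be 4 non-negative fractions summing to 1")
  }
  invisible(p)
}

#' Parameters of the blinking / acquisition model
#'
#' @param mean_K mean DNA-PAINT localizations per labeled site (zero-truncated
#'   Poisson).
#' @param sigma_dnapaint_xy lateral localization scatter s.d. in nm.
#' @param z_spread_factor axial/lateral scatter ratio (axial spread is
#'   approximately two-fold the lateral one).
#' @param n_frames frames per imaging round.
#' @param sticking_rate transient-sticking artifact clusters per square
#'   micrometer (their localizations fall inside one contiguous window of at
#'   most 5 percent of the frames).
#' @param n_rounds_per_target orthogonal docking-strand rounds per target.
#' @param merge_radius same-round unresolvable-pair radius in nm; roughly
#'   2x a typical DNA-PAINT NeNa precision.
#' @return a `blink_params` object.
#' @export
blink_params <- function(mean_K = 25, sigma_dnapaint_xy = 3,
                         z_spread_factor = 2, n_frames = 10000L,
                         sticking_rate = 0, n_rounds_per_target = 4L,
                         merge_radius = 10) {
  assert_scalar_pos(mean_K, "mean_K")
  assert_scalar_pos(sigma_dnapaint_xy, "sigma_dnapaint_xy")
  assert_scalar_pos(z_spread_factor, "z_spread_factor")
  if (sticking_rate < 0) stop("sticking_rate must be >= 0")
  structure(list(mean_K = mean_K, sigma_dnapaint_xy = sigma_dnapaint_xy,
                 z_spread_factor = z_spread_factor,
                 n_frames = as.integer(n_frames),
                 sticking_rate = sticking_rate,
                 n_rounds_per_target = as.integer(n_rounds_per_target),
                 merge_radius = merge_radius),
            class = "blink_params")
}

fov_area_um2 <- function(fov) {
  if (length(fov) == 1L) fov <- c(fov, fov)
  prod(fov) / 1e6
}

empty_sites <- function() {
  data.table::data.table(x = numeric(0), y = numeric(0), z = numeric(0),
                         target_id = character(0), molecule_id = integer(0),
                         complex_id = integer(0))
}

#' Simulate flexible chains of antibody-bridged receptor dimers
#'
#' Chain-starting points are uniform in the field of view; the first segment
#' direction is uniform on the circle and every subsequent hinge opens at an
#' angle drawn uniformly from `params$opening_angle_range` relative to the
#' incoming segment. Consecutive hinges are exactly `segment_length` apart
#' (noise is applied separately, see [apply_uncertainty()]).
#'
#' @param params a [chain_params()].
#' @param fov field-of-view `c(width, height)` in nm (scalar = square).
#' @param seed integer seed.
#' @param n_chains optional fixed chain count; default draws
#'   Poisson(chain_density x area).
#' @return list with `sites` (ground-truth site table: x, y, z, target_id,
#'   molecule_id, complex_id, site_role), `hinges` (chain_id, hinge index,
#'   x, y) and `chains` (chain_id, n_segments).
#' @export
simulate_chains <- function(params, fov, seed = NULL, n_chains = NULL) {
  stopifnot(inherits(params, "chain_params"))
  if (length(fov) == 1L) fov <- c(fov, fov)
  max_extent <- params$segment_length *
    max(params$segment_count_dist$segments)
  if (any(fov <= max_extent)) {
    stop("fov too small for the requested chains (max chain extent ",
         max_extent, " nm)")
  }
  with_seed(seed, {
    if (is.null(n_chains)) {
      n_chains <- stats::rpois(1, params$chain_density * fov_area_um2(fov))
    }
    if (n_chains == 0L) {
      return(list(sites = empty_sites(),
                  hinges = data.table::data.table(chain_id = integer(0),
                                                  hinge = integer(0),
                                                  x = numeric(0), y = numeric(0)),
                  chains = data.table::data.table(chain_id = integer(0),
                                                  n_segments = integer(0))))
    }
    segs <- params$segment_count_dist$segments[
      sample.int(nrow(params$segment_count_dist), n_chains, replace = TRUE,
                 prob = params$segment_count_dist$prob)]
    chain_id <- rep.int(seq_len(n_chains), segs)
    n_seg_tot <- length(chain_id)
    first <- !duplicated(chain_id)
    # absolute direction of each segment: free first direction, then a
    # turning angle = opening - 180 deg at each interior hinge
    op_rng <- params$opening_angle_range * pi / 180
    turn <- stats::runif(n_seg_tot, op_rng[1], op_rng[2]) - pi
    turn[first] <- stats::runif(n_chains, 0, 2 * pi)
    theta <- stats::ave(turn, chain_id, FUN = cumsum)
    L <- params$segment_length
    dx <- L * cos(theta); dy <- L * sin(theta)
    x0 <- stats::runif(n_chains, 0, fov[1])
    y0 <- stats::runif(n_chains, 0, fov[2])
    hx_end <- rep.int(x0, segs) + stats::ave(dx, chain_id, FUN = cumsum)
    hy_end <- rep.int(y0, segs) + stats::ave(dy, chain_id, FUN = cumsum)
    hinges <- data.table::data.table(
      chain_id = c(seq_len(n_chains), chain_id),
      hinge = c(rep.int(0L, n_chains),
                unlist(lapply(segs, seq_len), use.names = FALSE)),
      x = c(x0, hx_end), y = c(y0, hy_end))
    data.table::setorder(hinges, chain_id, hinge)
    # GFP: one dimer per segment midpoint, axis along the segment
    mx <- hx_end - dx / 2; my <- hy_end - dy / 2
    gofs <- params$d_gfp_dimer / 2
    gfp <- data.table::data.table(
      x = c(mx - gofs * cos(theta), mx + gofs * cos(theta)),
      y = c(my - gofs * sin(theta), my + gofs * sin(theta)),
      target_id = "GFP",
      complex_id = rep.int(chain_id, 2L))
    # ALFA: one antibody per hinge, pair orientation uniform
    n_h <- nrow(hinges)
    phi <- stats::runif(n_h, 0, 2 * pi)
    aofs <- params$d_alfa_pair / 2
    alfa <- data.table::data.table(
      x = c(hinges$x - aofs * cos(phi), hinges$x + aofs * cos(phi)),
      y = c(hinges$y - aofs * sin(phi), hinges$y + aofs * sin(phi)),
      target_id = "ALFA",
      complex_id = rep.int(hinges$chain_id, 2L))
    sites <- rbind(gfp, alfa)
    sites[, z := 0]
    sites[, molecule_id := .I]
    data.table::setcolorder(sites, c("x", "y", "z", "target_id",
                                     "molecule_id", "complex_id"))
    list(sites = sites[], hinges = hinges[],
         chains = data.table::data.table(chain_id = seq_len(n_chains),
                                         n_segments = as.integer(segs)))
  })
}

# lean mixture generator shared by simulate_oligomers and the fitter's inner
# loop: returns a plain matrix of GFP site coordinates plus complex ids.
mixture_sites <- function(n_complex, d_intra, d_bridge, fov) {
  n1 <- n_complex[1]; n2 <- n_complex[2]; n3 <- n_complex[3]; n4 <- n_complex[4]
  w <- fov[1]; h <- fov[2]
  parts <- vector("list", 4L)
  ids <- vector("list", 4L)
  next_id <- 0L
  if (n1 > 0) {
    parts[[1]] <- cbind(stats::runif(n1, 0, w), stats::runif(n1, 0, h))
    ids[[1]] <- seq_len(n1)
    next_id <- n1
  }
  place_dimer <- function(cx, cy) {
    phi <- stats::runif(length(cx), 0, 2 * pi)
    ox <- d_intra / 2 * cos(phi); oy <- d_intra / 2 * sin(phi)
    cbind(c(cx - ox, cx + ox), c(cy - oy, cy + oy))
  }
  if (n2 > 0) {
    cx <- stats::runif(n2, 0, w); cy <- stats::runif(n2, 0, h)
    parts[[2]] <- place_dimer(cx, cy)
    ids[[2]] <- next_id + rep.int(seq_len(n2), 2L)
    next_id <- next_id + n2
  }
  if (n3 > 0) {
    cx <- stats::runif(n3, 0, w); cy <- stats::runif(n3, 0, h)
    ab <- place_dimer(cx, cy)           # rows: A(1..n3), B(n3+1..2n3)
    bx <- ab[n3 + seq_len(n3), 1]; by <- ab[n3 + seq_len(n3), 2]
    psi <- stats::runif(n3, 0, 2 * pi)
    cpt <- cbind(bx + d_bridge * cos(psi), by + d_bridge * sin(psi))
    parts[[3]] <- rbind(ab, cpt)
    ids[[3]] <- next_id + rep.int(seq_len(n3), 3L)
    next_id <- next_id + n3
  }
  if (n4 > 0) {
    cx <- stats::runif(n4, 0, w); cy <- stats::runif(n4, 0, h)
    ab <- place_dimer(cx, cy)
    bx <- ab[n4 + seq_len(n4), 1]; by <- ab[n4 + seq_len(n4), 2]
    psi <- stats::runif(n4, 0, 2 * pi)
    cx2 <- bx + d_bridge * cos(psi); cy2 <- by + d_bridge * sin(psi)
    phi2 <- stats::runif(n4, 0, 2 * pi)
    dpt <- cbind(cx2 + d_intra * cos(phi2), cy2 + d_intra * sin(phi2))
    parts[[4]] <- rbind(ab, cbind(cx2, cy2), dpt)
    ids[[4]] <- next_id + rep.int(seq_len(n4), 4L)
  }
  keep <- !vapply(parts, is.null, logical(1))
  xy <- do.call(rbind, parts[keep])
  if (is.null(xy)) xy <- matrix(numeric(0), ncol = 2)
  list(xy = xy, complex_id = unlist(ids[keep]) %||% integer(0))
}

#' Simulate a field of low-order receptor oligomers
#'
#' Complex centers follow a homogeneous Poisson (CSR) process; class counts
#' are chosen so that molecule fractions match `params$proportions` and the
#' total molecule density matches `params$total_density`. Site geometry is
#' exact (noise is applied separately with [apply_uncertainty()]).
#'
#' @param params an [oligomer_params()].
#' @param fov field of view in nm.
#' @param seed integer seed.
#' @param count_mode "poisson" draws Poisson complex counts (a true point
#'   process); "expected" uses rounded expected counts (lower variance, used
#'   inside the mixture fitter).
#' @return ground-truth site table (columns as in [simulate_chains()]).
#' @export
simulate_oligomers <- function(params, fov, seed = NULL,
                               count_mode = c("poisson", "expected")) {
  stopifnot(inherits(params, "oligomer_params"))
  count_mode <- match.arg(count_mode)
  if (length(fov) == 1L) fov <- c(fov, fov)
  p <- params$proportions
  lambda <- p * params$total_density * fov_area_um2(fov) / (1:4)
  with_seed(seed, {
    n_complex <- if (count_mode == "poisson") stats::rpois(4, lambda)
                 else as.integer(round(lambda))
    ms <- mixture_sites(n_complex, params$d_intra, params$d_bridge, fov)
    n <- nrow(ms$xy)
    if (n == 0L) return(empty_sites())
    data.table::data.table(x = ms$xy[, 1], y = ms$xy[, 2], z = 0,
                           target_id = "GFP",
                           molecule_id = seq_len(n),
                           complex_id = as.integer(ms$complex_id))
  })
}

#' Simulate complete spatial randomness (CSR)
#'
#' Homogeneous Poisson point process at the given density; the null model
#' against which NND profiles are compared.
#'
#' @param density points per square micrometer (0 allowed; gives an empty set).
#' @param fov field of view in nm.
#' @param seed integer seed.
#' @param target_id target label for the generated sites.
#' @return ground-truth site table.
#' @export
simulate_csr <- function(density, fov, seed = NULL, target_id = "GFP") {
  if (density < 0) stop("density must be >= 0")
  if (length(fov) == 1L) fov <- c(fov, fov)
  with_seed(seed, {
    n <- stats::rpois(1, density * fov_area_um2(fov))
    if (n == 0L) return(empty_sites())
    data.table::data.table(x = stats::runif(n, 0, fov[1]),
                           y = stats::runif(n, 0, fov[2]), z = 0,
                           target_id = target_id,
                           molecule_id = seq_len(n),
                           complex_id = seq_len(n))
  })
}

#' Apply Bernoulli labeling to ground-truth sites
#'
#' Each site is independently detectable with the target-specific labeling
#' efficiency (probability that the site carries a functional label).
#'
#' @param sites ground-truth site table.
#' @param eff_alfa,eff_gfp labeling efficiencies per target.
#' @param seed integer seed.
#' @return the table with a logical `labeled` column.
#' @export
apply_labeling <- function(sites, eff_alfa = 0.40, eff_gfp = 0.50,
                           seed = NULL) {
  assert_prob(eff_alfa, "eff_alfa"); assert_prob(eff_gfp, "eff_gfp")
  sites <- data.table::copy(data.table::as.data.table(sites))
  with_seed(seed, {
    eff <- ifelse(sites$target_id == "ALFA", eff_alfa, eff_gfp)
    sites[, labeled := stats::runif(.N) < eff]
  })
  sites[]
}

#' Add isotropic Gaussian positional noise
#'
#' Models linkage error (label-to-epitope displacement) plus residual
#' localization error as independent Gaussian noise per coordinate.
#'
#' @param sites site table.
#' @param sd noise s.d. in nm per coordinate.
#' @param seed integer seed.
#' @param use_z also perturb z (default FALSE: planar membrane).
#' @return the table with perturbed coordinates.
#' @export
apply_uncertainty <- function(sites, sd = 5, seed = NULL, use_z = FALSE) {
  sites <- data.table::copy(data.table::as.data.table(sites))
  if (sd < 0) stop("sd must be >= 0")
  if (sd == 0 || nrow(sites) == 0L) return(sites[])
  with_seed(seed, {
    sites[, `:=`(x = x + stats::rnorm(.N, 0, sd),
                 y = y + stats::rnorm(.N, 0, sd))]
    if (use_z && "z" %in% names(sites)) {
      sites[, z := z + stats::rnorm(.N, 0, sd)]
    }
  })
  sites[]
}

#' Assign labeled sites to imaging rounds and merge unresolvable pairs
#'
#' Each labeled site is assigned uniformly to one of its target's orthogonal
#' docking-strand rounds (ALFA: rounds 1..4, GFP: rounds 5..8 at the default
#' 4 rounds per target). Two same-target sites that land in the same round
#' closer than `merge_radius` cannot be resolved by DNA-PAINT and are merged
#' into one site at their midpoint (connected groups collapse to their
#' centroid); merges are recorded in the report.
#'
#' @param sites site table with a `labeled` column.
#' @param n_rounds_per_target rounds per target.
#' @param merge_radius unresolvable-pair radius in nm.
#' @param seed integer seed.
#' @return list: `sites` (labeled, merged sites with `round_id` and
#'   `n_merged`), `report` (per target/round: sites in, sites out, merged).
#' @export
assign_rounds <- function(sites, n_rounds_per_target = 4L, merge_radius = 10,
                          seed = NULL) {
  sites <- data.table::as.data.table(sites)
  if (!"labeled" %in% names(sites)) stop("sites must be labeled first")
  lab <- sites[labeled == TRUE]
  with_seed(seed, {
    base <- ifelse(lab$target_id == "ALFA", 0L, n_rounds_per_target)
    lab[, round_id := base + sample.int(n_rounds_per_target, .N, replace = TRUE)]
    out <- vector("list", 0L)
    rep_rows <- vector("list", 0L)
    for (rid in sort(unique(lab$round_id))) {
      g <- lab[round_id == rid]
      if (nrow(g) > 1L) {
        comp <- dbscan_points(cbind(g$x, g$y), eps = merge_radius,
                              min_samples = 2L)
        singleton <- comp == 0L
        comp[singleton] <- max(comp) + seq_len(sum(singleton))
        merged <- g[, .(x = mean(x), y = mean(y), z = mean(z),
                        target_id = target_id[1L],
                        molecule_id = molecule_id[1L],
                        complex_id = complex_id[1L],
                        labeled = TRUE, round_id = rid, n_merged = .N),
                    by = .(.comp = comp)][, .comp := NULL]
      } else {
        merged <- data.table::copy(g)[, n_merged := 1L]
      }
      out[[length(out) + 1L]] <- merged
      rep_rows[[length(rep_rows) + 1L]] <- data.table::data.table(
        target_id = g$target_id[1L] %||% NA_character_, round_id = rid,
        sites_in = nrow(g), sites_out = nrow(merged),
        merged_away = nrow(g) - nrow(merged))
    }
    list(sites = data.table::rbindlist(out),
         report = data.table::rbindlist(rep_rows))
  })
}

#' Simulate DNA-PAINT blinking localizations from ground-truth sites
#'
#' Each site emits K localizations (zero-truncated Poisson with mean
#' `mean_K`), scattered as independent Gaussians with lateral s.d.
#' `sigma_dnapaint_xy` and axial s.d. `z_spread_factor` times larger, at
#' frames uniform over the acquisition. Sticking artifacts are injected as
#' Poisson(`sticking_rate` x area) extra clusters whose localizations all
#' fall inside one contiguous window of at most 5% of the frames.
#'
#' @param sites site table with `round_id` (see [assign_rounds()]).
#' @param blink a [blink_params()].
#' @param fov field of view in nm.
#' @param seed integer seed.
#' @param is_3d emit a z coordinate (default: TRUE if sites carry z).
#' @return a [loc_table()] with meta attached.
#' @export
simulate_blinking <- function(sites, blink, fov, seed = NULL, is_3d = FALSE) {
  stopifnot(inherits(blink, "blink_params"))
  sites <- data.table::as.data.table(sites)
  if (nrow(sites) && !"round_id" %in% names(sites)) {
    stop("sites must carry round_id; run assign_rounds() first")
  }
  if (length(fov) == 1L) fov <- c(fov, fov)
  meta <- acquisition_meta(n_frames = blink$n_frames, fov = fov,
                           is_3d = is_3d)
  with_seed(seed, {
    rtpois <- function(n, mu) {
      if (n == 0L) return(integer(0))
      u <- stats::runif(n, stats::ppois(0, mu), 1)
      stats::qpois(u, mu)
    }
    K <- rtpois(nrow(sites), blink$mean_K)
    idx <- rep.int(seq_len(nrow(sites)), K)
    n_loc <- length(idx)
    sxy <- blink$sigma_dnapaint_xy
    dt <- data.table::data.table(
      x = sites$x[idx] + stats::rnorm(n_loc, 0, sxy),
      y = sites$y[idx] + stats::rnorm(n_loc, 0, sxy),
      frame = sample.int(blink$n_frames, n_loc, replace = TRUE) - 1L,
      sigma_xy = sxy,
      round_id = sites$round_id[idx],
      target_id = sites$target_id[idx])
    if (is_3d) {
      sz <- blink$z_spread_factor * sxy
      zsite <- if ("z" %in% names(sites)) sites$z[idx] else 0
      dt[, z := zsite + stats::rnorm(n_loc, 0, sz)]
      dt[, sigma_z := sz]
    }
    # transient sticking artifacts
    n_stick <- stats::rpois(1, blink$sticking_rate * fov_area_um2(fov))
    if (n_stick > 0L) {
      win <- max(1L, floor(0.05 * blink$n_frames))
      Ks <- rtpois(n_stick, blink$mean_K)
      sx <- stats::runif(n_stick, 0, fov[1])
      sy <- stats::runif(n_stick, 0, fov[2])
      start <- sample.int(blink$n_frames - win + 1L, n_stick,
                          replace = TRUE) - 1L
      rid <- sample.int(2L * blink$n_rounds_per_target, n_stick,
                        replace = TRUE)
      si <- rep.int(seq_len(n_stick), Ks)
      stick <- data.table::data.table(
        x = sx[si] + stats::rnorm(length(si), 0, sxy),
        y = sy[si] + stats::rnorm(length(si), 0, sxy),
        frame = start[si] +
          as.integer(floor(stats::runif(length(si), 0, win))),
        sigma_xy = sxy,
        round_id = rid[si],
        target_id = ifelse(rid[si] <= blink$n_rounds_per_target,
                           "ALFA", "GFP"))
      if (is_3d) {
        stick[, z := stats::rnorm(.N, 0, blink$z_spread_factor * sxy)]
        stick[, sigma_z := blink$z_spread_factor * sxy]
      }
      dt <- rbind(dt, stick)
    }
    loc_table(dt, meta = meta)
  })
}

#' Simulate tilted antibody-receptor complexes in 3D
#'
#' Generates isolated complexes for geometry-recovery tests: a receptor
#' cluster (4 GFP sites in a small disc at the membrane plane) and an
#' antibody (2 ALFA sites) displaced by `distance` along a direction at polar
#' angle `angle_deg` from the membrane normal (0 deg = perpendicular above),
#' with uniform azimuth and Gaussian noise.
#'
#' @param n_complexes number of complexes.
#' @param angle_deg tilt angle from the z-axis in degrees.
#' @param distance center-of-mass displacement in nm.
#' @param fov field of view in nm (complexes placed on a sparse grid-free
#'   uniform layout).
#' @param noise_sd per-coordinate Gaussian noise s.d. in nm.
#' @param cluster_radius receptor-cluster disc radius in nm.
#' @param seed integer seed.
#' @return ground-truth site table with z.
#' @export
simulate_tilted_complexes <- function(n_complexes, angle_deg, distance,
                                      fov = 20000, noise_sd = 2,
                                      cluster_radius = 10, seed = NULL) {
  if (length(fov) == 1L) fov <- c(fov, fov)
  with_seed(seed, {
    cx <- stats::runif(n_complexes, 0, fov[1])
    cy <- stats::runif(n_complexes, 0, fov[2])
    ang <- angle_deg * pi / 180
    az <- stats::runif(n_complexes, 0, 2 * pi)
    vx <- distance * sin(ang) * cos(az)
    vy <- distance * sin(ang) * sin(az)
    vz <- distance * cos(ang)
    gfp <- data.table::data.table(
      x = rep(cx, each = 4L) +
        stats::runif(4L * n_complexes, -cluster_radius, cluster_radius),
      y = rep(cy, each = 4L) +
        stats::runif(4L * n_complexes, -cluster_radius, cluster_radius),
      z = 0, target_id = "GFP",
      complex_id = rep(seq_len(n_complexes), each = 4L))
    alfa <- data.table::data.table(
      x = rep(cx + vx, each = 2L) + stats::runif(2L * n_complexes, -2, 2),
      y = rep(cy + vy, each = 2L) + stats::runif(2L * n_complexes, -2, 2),
      z = rep(vz, each = 2L), target_id = "ALFA",
      complex_id = rep(seq_len(n_complexes), each = 2L))
    sites <- rbind(gfp, alfa)
    sites[, molecule_id := .I]
    if (noise_sd > 0) {
      sites[, `:=`(x = x + stats::rnorm(.N, 0, noise_sd),
                   y = y + stats::rnorm(.N, 0, noise_sd),
                   z = z + stats::rnorm(.N, 0, noise_sd))]
    }
    data.table::setcolorder(sites, c("x", "y", "z", "target_id",
                                     "molecule_id", "complex_id"))
    sites[]
  })
}
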