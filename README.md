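# resiquant

Quantitative post-localization analysis of DNA-PAINT / RESI single-molecule
localization microscopy data, for studying how therapeutic antibodies
rearrange membrane receptors at single-protein resolution.

## Who this is for

RESI (Resolution Enhancement by Sequential Imaging) splits each molecular
target stochastically across orthogonal DNA docking-strand imaging rounds, so
every molecule's DNA-PAINT localization cloud is isolated and can be averaged
into one sub-nanometer-precision "RESI localization"
(σ_RESI = σ_DNA-PAINT / √K). Given such data for a receptor channel (e.g.
GFP-nanobody-labeled CD20) and an antibody channel (ALFA-nanobody-labeled
therapeutic mAb), this package answers:

* how many antibodies bind per receptor (stoichiometry / ratio analysis),
* whether receptors sit in chains, low-order oligomers, or at random
  (nearest-neighbor-distance profiles vs complete spatial randomness),
* the hinge-to-hinge segment length of antibody-bridged receptor chains,
  with a Monte-Carlo uncertainty,
* the monomer/dimer/trimer/tetramer composition of a receptor population
  (simulation-based least-squares mixture fit),
* how many C1q-compatible antibody platforms (≥5 detected ALFA labels within
  25 nm) a field contains, and
* the 3D tilt angle and axial distance of antibody-receptor complexes.

A synthetic generator simulates the whole observation process — molecular
arrangements on a membrane, Bernoulli labeling (40% ALFA / 50% GFP), round
assignment with unresolvable-pair merging, Gaussian blinking with 2× axial
spread, uniform frame times and transient sticking artifacts — so every
estimator ships with parameter-recovery tests.

## The statistics at the core

* **RESI grouping**: neighbor counts within radius *r*; local maxima; clusters
  with > n_min members; frame filters (mean frame in first/last 20%, or >80%
  of localizations within 5% of frames → sticking artifact); centers are
  inverse-variance weighted means, precision σ̄/√K.
* **Ratio fit**: per 40-nm-DBSCAN co-cluster, OLS of (n_ALFA / 2) on n_GFP;
  normalized ratio = slope · ε_GFP / ε_ALFA.
* **Chain fit**: argmin over L ∈ {10..40 nm} of the summed squared
  differences between observed and simulated 1st-6th NND frequency
  histograms, simulations pinned to the observed 20-nm-DBSCAN cluster-size
  frequencies and density; uncertainty = smallest ΔL whose scores differ
  significantly (unpaired t-test, α = 0.05, NND orders 1-10).
* **Mixture fit**: exhaustive 5% simplex grid over
  (monomer, dimer, trimer, tetramer), each candidate simulated as a full
  mixture at matched detected density with 5 nm linkage uncertainty, scored
  on 1st-3rd NND histograms.

See `vignettes/resiquant-methods.Rmd` for assumptions, parameter defaults and
limitations.

## Worked example

```r
library(resiquant)

# a rituximab-like synthetic field: flexible chains of receptor dimers
cfg <- pipeline_config(condition = "RTX-like", seed = 3L, fov = 8000,
                       fit_grid = seq(19, 27, 2), fit_reps = 2L)
out <- run_pipeline(cfg)
round(out$ratio$slope_mab_per_gfp, 3)
#> [1] 0.325
round(out$ratio$normalized_mab_per_receptor, 3)
#> [1] 0.406
out$chain_fit$L_hat_nm
#> [1] 21
out$platforms$n_configs
#> [1] 131
```

Reading: the fitted slope ≈ 0.33 antibodies per detected receptor becomes
≈ 0.41 antibodies per receptor after labeling-efficiency normalization —
about one bivalent antibody per receptor dimer, the chain model's generative
ratio (OLS on noisy counts attenuates the slope below the ideal 0.5; see the
vignette). On this small 8 µm demo field the chain fit lands at 21 nm for a
generative 23 nm segment length, within the method's ~2 nm Monte-Carlo
uncertainty (full-scale recovery is exercised by `scripts/acceptance.R`),
and the field contains over a hundred C1q-compatible platform
configurations, as expected for a chain-forming (Type I-like) antibody.

An obinutuzumab-like (Type II) field instead fits a low-order oligomer
mixture:

```r
cfg2 <- pipeline_config(condition = "OBZ-like", seed = 5L, fov = 6000,
                        oligo_grid_step = 0.2, oligo_reps = 1L,
                        oligo_sim_fov = 5000)
out2 <- run_pipeline(cfg2)
unlist(out2$oligomer_fit[c("monomer_pct", "dimer_pct", "trimer_tetramer_pct")])
#>         monomer_pct           dimer_pct trimer_tetramer_pct
#>                  40                  40                  20
```

(Coarse 20% grid for speed in this example; the analysis default is the 5%
grid, which needs cell-scale data — see the vignette.)

A command-line front end wraps the same pipeline:

```sh
Rscript inst/scripts/resiquant-cli.R --config run.yaml
Rscript inst/scripts/resiquant-cli.R --condition RTX-like --seed 7 --fov 10000 --out-dir runs/rtx
```

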