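---
title: "Models and methods behind resiquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind resiquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resiquant)
```

# Scope

resiquant analyzes single-molecule localization microscopy data of the
DNA-PAINT/RESI type to quantify how therapeutic antibodies rearrange a
membrane receptor (the motivating system is anti-CD20 antibodies on
GFP-tagged CD20). It starts downstream of drift correction and channel
alignment: the input is a table of localizations with positions, frames,
per-localization precision, imaging round and target channel. From there it

1. groups DNA-PAINT localizations into per-molecule **RESI localizations**,
2. co-clusters the antibody (ALFA nanobody) and receptor (GFP nanobody)
   channels and fits the **antibody:receptor stoichiometry**,
3. profiles **kth nearest-neighbor distances** (NND) against complete spatial
   randomness (CSR),
4. fits a **flexible-chain model** (receptor dimers concatenated by bivalent
   antibodies) for its hinge-to-hinge segment length with a Monte-Carlo
   uncertainty,
5. fits **monomer/dimer/trimer/tetramer proportions** by simulation-based
   least squares,
6. counts **C1q-compatible antibody platforms** and measures **3D complex
   geometry** (tilt angle and axial distance).

A synthetic data generator reproduces the statistical structure these
analyses assume, so every quantitative claim of the pipeline can be tested as
a parameter-recovery experiment.

# RESI grouping

Each labeled molecule emits many localizations across one imaging round.
Grouping uses two parameters, a radius $r$ (about 1.5-2x the NeNa precision)
and a minimum count $n_\min$: neighbor counts within $r$ are computed for
every localization, a localization whose count is at least that of all its
neighbors is a local maximum (lowest index wins ties, so a flat dense cloud
still yields exactly one maximum — a strict "more neighbors" rule can orphan
symmetric clouds), and each maximum with strictly more than $n_\min$ assigned
localizations forms a cluster. A localization reachable from several maxima
joins the nearest one. In 3D the axial window is $2r$ because the axial
localization spread is about twice the lateral one.

Two frame-based filters remove imager "sticking" artifacts: clusters whose
mean frame falls in the first or last 20% of frames, and clusters with over
80% of localizations inside any window of 5% of the frames (evaluated by an
exact sliding-window scan). On synthetic data these remove over 99% of
injected sticking clusters while retaining over 99% of genuine clusters,
which the test suite asserts.

The RESI position is the inverse-variance weighted mean of the members
(weights $1/\sigma^2$), with precision $\sigma_\mathrm{RESI} =
\bar\sigma/\sqrt{K}$ for $K$ grouped localizations; with $K \approx 25$ at
$\sigma \approx 3$ nm this reaches $\approx 0.6$ nm. Whether the original
implementation reports $\bar\sigma/\sqrt K$ or the weighted standard error is
not documented; both are computed, the former is primary
(`sigma_resi` / `sigma_resi_se`).

# Co-clustering and stoichiometry

Two-target analysis pools both channels and runs DBSCAN at 40 nm; the
per-target minimum counts (at least 1 ALFA and 1 GFP) are applied as
post-hoc cluster filters, not DBSCAN parameters. Because RESI reduces each
molecule to a single point, density gating must be permissive:
`min_samples = 2` counting the point itself, under which DBSCAN clusters
coincide with the connected components of the 40 nm adjacency graph (the
test suite checks exactly this equivalence against an independent graph
implementation). Distances are 2D unless a z column is present and requested;
the published 2D analyses are the default.

Stoichiometry: per cluster, antibody count $= n_\mathrm{ALFA}/2$ (two ALFA
tags per antibody) is regressed on $n_\mathrm{GFP}$ by unweighted ordinary
least squares with intercept (the source material does not specify
weighting). The slope is normalized by the labeling efficiencies,
$\mathrm{ratio} = \mathrm{slope} \cdot \varepsilon_\mathrm{GFP} /
\varepsilon_\mathrm{ALFA}$ with $\varepsilon_\mathrm{ALFA} = 0.40$,
$\varepsilon_\mathrm{GFP} = 0.50$, so a slope of 0.38 corresponds to 0.475
antibodies per receptor, i.e. about one antibody per receptor dimer. Note
that an OLS slope on noisy counts is attenuation-limited: binomial detection
noise in the x variable biases the slope slightly below the generative ratio
unless the cluster-size variance is large. This is a property of the
published estimator, which we reproduce rather than correct.

# NND profiling

Per point, distances to the 1st..kth nearest neighbors (self excluded; kd
tree backed) are binned into 1-nm histograms over 0-200 nm and normalized by
the number of points, making profiles from different-sized fields
comparable. The CSR reference simulates a homogeneous Poisson process at
matched density in the same field of view; for 2D CSR at intensity $\rho$
the 1st-NND density is $2\pi\rho d\, e^{-\pi\rho d^2}$ with mean
$1/(2\sqrt\rho)$, which the generator reproduces within 2% (tested). No edge
correction is applied — the data analysis does not use one either — so tests
that compare against closed forms either use high densities (edge strip
negligible) or evaluate core points only.

# Synthetic data generator

The generator is the package's stated world; its defaults are the conditions
under which all recovery targets are evaluated.

* **Chains**: starting points uniform in the field of view; first segment
  direction uniform; at every hinge the opening angle between adjacent
  segments is uniform in [30°, 330°] (180° = straight; angles below 30°
  — near-complete fold-back — are excluded, consistent with
  electron-tomography-derived hinge flexibility). Consecutive hinges are
  exactly $L$ apart before noise. Each segment midpoint carries one receptor
  dimer: 2 GFP sites 13.5 nm apart, oriented **along the segment** (a dimer
  bridged at both ends by antibodies is aligned with the chain; the source is
  silent, this is configurable). Each hinge carries one antibody: 2 ALFA
  sites 4 nm apart, orientation uniform.
* **Segment counts**: truncated geometric over 1..20 with decay 0.3 (mean
  ~3.3 segments). Two reasons: observed cluster-size histograms decay from
  mostly small clusters to a tail of tens of molecules; and the segment-length
  fit parameterizes its candidate simulations by *detected* cluster sizes, a
  recipe that is only self-consistent when true chain sizes resemble detected
  cluster sizes (see Limitations).
* **Densities**: total receptor density ~50 molecules/µm² in all worlds
  (7.5 chains/µm² for chains; 50/µm² for oligomer fields), a realistic value
  for a transfected cell line. Nothing in the analysis depends on the exact
  value; it sets the CSR background level.
* **Oligomers**: complex centers are homogeneous Poisson; a dimer is two
  sites $d_\mathrm{intra} = 13.5$ nm apart at uniform orientation, a trimer
  adds a bridged site at $d_\mathrm{bridge}$ from one dimer member, a
  tetramer bridges two dimers (chain-like A–B~C–D). $d_\mathrm{bridge}$ is
  never printed for this system; the default reuses 13.5 nm and is explicitly
  a model choice. Proportions are **molecule** fractions (not complex
  fractions; configurable).
* **Labeling**: independent Bernoulli per site, 0.40 (ALFA) / 0.50 (GFP).
* **Positional uncertainty**: isotropic Gaussian, s.d. 5 nm per coordinate
  (linkage error plus residual localization error); applied in every
  simulation-based fit. The 5 nm value is stated for the oligomer
  simulations; we use the same single linkage-error model for chains.
* **Rounds**: each labeled site is assigned uniformly to one of its target's
  4 orthogonal docking-strand rounds; same-target, same-round sites closer
  than 10 nm (about twice a typical NeNa precision) are unresolvable and
  merge to their midpoint. For a dimer population the expected same-round
  collision fraction is $1/4$, which the tests verify combinatorially.
* **Blinking**: $K$ per site is Poisson truncated at 1 (the K distribution is
  not documented; truncation encodes "a detected site blinks at least
  once"), lateral scatter Gaussian with $\sigma_{xy}$, axial scatter
  $2\sigma_{xy}$, frames uniform; sticking artifacts are extra clusters whose
  localizations fall inside one contiguous 5%-of-frames window.
* The membrane is the $z = 0$ plane; a dedicated generator places tilted
  antibody-receptor complexes (polar angle from the membrane normal, uniform
  azimuth) for 3D geometry recovery tests.

What a green test does **not** establish: the generator has no photophysics
(photon budgets, PSF shape), no camera noise, no residual drift, no
astigmatism calibration error, and its labeling is independent Bernoulli
(real nanobody labeling can be sterically correlated within a complex).
Recovery results certify the analysis pipeline against its own model class,
not against every property of real acquisitions.

# Flexible-chain fit

The observed receptor channel is reduced to (i) its NND profile (orders 1-6)
and (ii) cluster statistics from the single-target 20 nm DBSCAN (size
frequencies of clusters with at least 2 molecules, and cluster density).
For each candidate segment length on a 10-40 nm grid (1 nm step, bracketing
plausible IgG hinge-to-hinge distances), 3 chain simulations are generated
with segment counts drawn from the observed size frequencies and chain
density equal to the observed cluster density, labeling and 5 nm uncertainty
applied; the score is the sum over orders and bins of squared frequency
differences, and the fitted length is the argmin of the replicate-averaged
score (whether the original fit averaged replicates is not stated; averaging
is used).

The Monte-Carlo uncertainty generates 3 "optimal" reference simulations at
the fitted length, re-clusters each to obtain its own sizes, simulates 3
iterating datasets per reference at each offset length, scores them over NND
orders 1-10, and compares score samples at the fitted length vs. each offset
with a two-sided unpaired t-test at $\alpha = 0.05$ (test flavor beyond
"unpaired t-test" is not documented; Student's equal-variance two-sample is
used). The uncertainty is the smallest significant offset; if none is
significant within the search range the result is flagged unresolved — small
datasets (tens of chains) do exactly that.

# Oligomer-mixture fit

Candidate compositions live on the 4-class simplex with a 5% grid (1,771
candidates). Each candidate is simulated as a **full mixture** — not a
superposition of per-class NND profiles, because cross-class neighbors make
the NND non-additive — at the observed detected density (total density =
detected density / labeling efficiency), with 5 nm uncertainty and Bernoulli
labeling, and scored on NND orders 1-3 (where the non-CSR peaks live;
configurable to 1-6). The fitted composition is the argmin of the
replicate-averaged score; the full trace is kept so flat valleys are visible,
and exact ties resolve toward fewer higher-order classes. An optional 1%
local refinement exists but the graded configuration is the plain 5% grid.

The information content of this statistic is modest: with 50% labeling a
tetramer frequently appears as one or two detected molecules, so neighboring
compositions differ by little. Recovery experiments show the fit needs
roughly a full cell of data (~20 x 20 µm at ~25 detected molecules/µm², i.e.
~10^4 points) for fitted monomer/dimer fractions to land within a few
percentage points of truth; at ~10 µm² scale the least-squares valley is
flatter than the observation noise. The candidate simulations run on the same
field-of-view size as the observation so edge effects cancel.

# C1q platforms and 3D geometry

A C1q-binding platform needs six antibody Fc domains in proximity; with two
ALFA sites per antibody at 40% labeling efficiency this is approximated as
at least 5 detected ALFA localizations within 25 nm (6 antibodies x 2 sites
x 0.4 ≈ 4.8 detected). Every localization whose neighborhood (itself
included — the inclusive reading matches that arithmetic) reaches the
threshold seeds one configuration, and overlapping configurations all count,
representing avidity. Neighborhoods are evaluated in the membrane plane (xy)
by default.

For each co-cluster with more than 3 receptor molecules, the vector from the
antibody center of mass to the receptor center of mass (full 3D centers of
mass; a z-median variant was considered and rejected as less standard) gives
the Euclidean distance, the axial distance $|\Delta z|$, and the angle to the
membrane normal — 0° means the antibody sits perpendicularly above the
receptor cluster. The reported angle is folded to [0°, 90°] (symmetry about
the membrane plane); the raw value is retained.

# Numerical and design choices

* Internal units are nanometers everywhere; frames are 0-based; pixel-to-nm
  conversion (130 nm/px default) happens only at the I/O boundary.
* All stochastic functions take an explicit seed and restore the caller's RNG
  state; a master seed is expanded into per-stage streams
  (`derive_seed`) so toggling one pipeline stage does not perturb another's
  draws. Identical (config, seed) gives byte-identical pipeline summaries.
* Fixed-radius neighbor queries use a compiled uniform-grid index; kNN
  queries a kd-tree; the test suite pins both to quadratic brute-force
  oracles on instances up to ~1,000 points.
* Frame-filter boundaries are half-open (`mean < 0.2 n` or `>= 0.8 n`) and
  the window rule is strict (`> 80%`), matching the stated "over 80%".
  "More than n_min localizations" is read strictly.
* Degenerate inputs: empty localization tables cluster to empty results;
  ratio fits refuse fewer than 3 clusters or zero count variance; NND
  profiles refuse point sets smaller than max(order) + 1; the CSR reference
  refuses fields too small for a stable estimate.

# Limitations

* The segment-length fit inherits a structural assumption of the published
  recipe: candidate simulations are parameterized by *detected* cluster
  sizes. When true chains are much longer than detected clusters (heavy
  labeling dropout splits chains at undetected dimers), the fitted length
  biases low by a few nanometers. The generator's default world satisfies the
  recipe's assumption; strongly long-chain worlds would not.
* The oligomer fit cannot sharply separate trimers from tetramers at 50%
  labeling; the trimer+tetramer sum is the robust readout, matching how the
  results are reported per condition.
* The OLS stoichiometry slope is attenuation-limited (see above); the
  normalized ratio is therefore a slight underestimate by construction.
* 3D geometry assumes the coverslip-parallel membrane defines the z axis;
  curved or tilted membranes mix tilt with geometry.
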