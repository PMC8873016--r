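---
title: "Whole-brain network topology in multi-site case-control studies: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-brain network topology in multi-site case-control studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fctopo)
```

# The analysis problem

Resting-state fMRI case-control studies of network topology ask whether a
clinical group differs from controls in how efficiently its functional
brain network is organized. The pipeline implemented here follows the
design that large multi-site depression consortia use:

1. **Node time series.** Each brain node is a 5 mm-radius sphere around an
   atlas coordinate (e.g. a 160-node coordinate atlas); its signal is the
   unweighted mean of all voxels whose centre falls within the sphere
   (inclusive boundary, Euclidean distance in millimetre space). The
   package consumes either pre-extracted node-by-time matrices or a 4D
   NIfTI image plus a node table.
2. **Connectivity.** Pearson correlation between all node pairs, Fisher
   z-transformed (`atanh`, with |r| clipped at `1 - 1e-7` so perfect
   correlations stay finite). Optional motion scrubbing removes timepoints
   whose framewise displacement strictly exceeds 0.2 mm before the
   correlation; a timepoint exactly at the threshold is kept.
3. **Density thresholding.** At each density $\kappa$ in a grid (default
   10% to 34% in 1% steps), the $K = \mathrm{round}(\kappa N(N-1)/2)$
   strongest positive edges are retained. Ties break by lexicographic
   (row, column) order so the retained set is deterministic.
4. **Weighted topology.** On each thresholded graph: global efficiency
   $E_{glob} = \frac{1}{N(N-1)}\sum_{i \ne j} d_{ij}^{-1}$, local
   efficiency (cube-root neighbourhood form), characteristic path length
   $L_p$, clustering coefficient $C_p$ (geometric-mean triangle form),
   nodal degree, nodal efficiency and betweenness. Edge lengths are
   reciprocal weights; distances come from Dijkstra's algorithm
   (compiled, since each subject is evaluated at 25 densities).
5. **AUC.** Each metric's curve over the density grid is summarized by its
   trapezoidal area under the curve, giving one outcome per subject per
   metric (per node for nodal metrics).
6. **Inference.** Per outcome, a linear mixed-effects model
   `y ~ group + age + sex + education + mean FD + (1 + group | site)`
   estimated by REML, Wald $t$ with residual degrees of freedom for the
   group term (Satterthwaite available as an option; see below). Nodal metrics form one Benjamini–Hochberg family per
   metric across nodes; global metrics are reported with raw p-values.
   Subgroup contrasts (first-episode drug-naive vs control, recurrent vs
   control, recurrent vs first-episode) and a symptom-severity model (the
   group term replaced by the HAMD score, patients only) reuse the same
   machinery. Sites contribute only if both groups have at least 10
   subjects there (re-checked within every subgroup subset).

# The synthetic cohort generator

Consortium data are access-restricted, so the package ships a generator
that emulates the *statistical structure* the pipeline consumes, with
known ground truth:

- A modular correlation template: `n_modules` contiguous blocks with
  within-block correlation 0.4 and between-block correlation 0.05 by
  default — enough community structure that efficiency and clustering are
  non-degenerate at the default densities. The raw block matrix is
  PSD-repaired deterministically (eigenvalue clipping at zero, then
  re-normalization to unit diagonal).
- A per-subject connectivity scale: off-diagonal covariance is multiplied
  by $\delta^{[\text{patient}]} \exp(b_{0,\text{site}} +
  b_{1,\text{site}}[\text{patient}] + \sum_k \beta_k x_k)$, clipped to the
  valid correlation range and PSD-repaired. $\delta$
  (`group_effect_delta`) is the injectable group effect; $\delta = 1$ with
  zero slope SD makes the two groups identical in law. The optional
  `subtype_deltas` argument confines the effect to a patient subtype
  (e.g. recurrent patients only), which is how the recurrent-driven
  subgroup pattern is emulated.
- Time series are i.i.d. multivariate normal draws from the scaled
  template. Temporal autocorrelation is deliberately **not** modelled: the
  pipeline uses only the static Pearson correlation, so autocorrelation
  changes estimator variance but not what the pipeline computes. This is a
  stated limitation — calibration results transfer to real BOLD data only
  to the extent that effective degrees of freedom are comparable.
- Covariates: age ~ U(18, 60) years, education ~ U(6, 20) years, mean
  framewise displacement ~ |N(0.10, 0.06)| mm, 60% female. HAMD scores for
  patients follow `base + slope * (1 - connectivity scale) + noise`
  (defaults 22, 10, SD 4), so symptom-association power is tunable and
  recoverable. Site counts default to 16 sites with subtype fractions
  roughly matching a large published consortium composition (28%
  first-episode drug-naive, 23% recurrent, the rest unlabelled). These
  defaults are documented choices, not estimates from any restricted
  dataset.

What the generator does **not** emulate: hemodynamic forward models,
scanner-specific artefacts, spatially structured noise, or missing-data
mechanisms. Passing tests therefore demonstrate the pipeline's
correctness and statistical calibration on data with known truth — not
that any particular clinical result is reproducible.

# Design choices in the open

**Edge weights are kept on the raw Fisher-z scale.** A common toolbox
convention rescales each thresholded graph by its maximum weight so that
efficiencies land in [0, 1]. We deliberately do not do this by default:
the between-subject difference in overall connectivity strength is part of
the case-control signal, and per-subject max-normalization removes it.
In simulation this matters qualitatively — with per-subject normalization
a uniform attenuation of patient connectivity leaves global efficiency
unchanged to first order, and the residual effect (a noisier, more random
retained edge set) *raises* patient $E_{glob}$ while lowering $E_{loc}$.
On raw weights the attenuation propagates into longer path lengths and
lower efficiencies, the direction the analysis is designed to detect.
`proportional_threshold(..., normalize = TRUE)` restores the bounded
convention for users who want scale-invariant topology only; analyses that
must separate scale from topology can instead add
`overall_fc_strength()` as a covariate.

**Negative edges** are removed before thresholding (weighted path metrics
need non-negative weights); `negative = "absolute"` is available.

**Disconnected pairs** contribute zero to efficiencies and are excluded
from $L_p$, with the per-density count of infinite pairs logged — the two
conventions are explicit and never silent.

**Degree** is the binary count of suprathreshold edges;
`nodal_degree(type = "strength")` exposes the weighted sum.

**Mixed-model fallback chain.** With few subjects per site the random
group slope is often weakly identified. A fit that fails to converge or is
singular is refit with a random intercept only, then (last resort) with
ordinary least squares on site fixed effects. The structure actually used
is recorded in every result row; nothing falls back silently.

**Degrees of freedom.** The Wald $t$ for the effect of interest uses
residual degrees of freedom ($n$ minus the number of fixed-effect
coefficients), the default of the mixed-model tooling this analysis family
is usually run with. The Satterthwaite approximation
(`fit_lme(df_method = "satterthwaite")`) is principled when random-slope
variance is genuinely present, but with a handful of sites it collapses
the group-effect df towards the site count whenever a possibly spurious
random slope is retained; in null simulations with four sites that
stratum essentially never rejects, making the overall test markedly
conservative. The residual convention keeps the null rejection rate at
the nominal level in the same simulations (the standard error still
reflects the fitted random-effects structure).

**FDR families.** Each nodal metric is corrected across its nodes as one
family; global metrics are reported uncorrected, mirroring how such
studies report a handful of global outcomes alongside node-wise maps. Both
choices are visible in the `family` column.

**Symptom model restricted to patients.** Controls have no meaningful
symptom score; the restriction is documented and the site filter is
re-applied on the patient subset.

**Boundary conventions** chosen once and tested: FD scrubbing strictly
greater than threshold; site filter at least (not more than) the minimum;
voxel-in-sphere inclusive of the boundary; thresholding tie-break
lexicographic.

# Numerical choices

- PSD repair: eigenvalue clipping at 0, reconstruction, re-normalization
  to unit diagonal; failure beyond `-1e-10` aborts with the offending
  eigenvalue.
- Fisher transform clipping at `1 - 1e-7`.
- Density grids must tile `[kappa_min, kappa_max]` exactly (the last point
  falls on `kappa_max` within 1e-12); a step that does not divide the
  range is an error rather than a silent truncation.
- Shortest-path ties in betweenness share credit fractionally; equality of
  floating-point path lengths is detected with a relative tolerance of
  1e-10 (exact for binary graphs, immaterial for continuous weights).
- All randomness flows through R's RNG; a cohort is bit-reproducible from
  its seed, and `run_pipeline()` derives per-stage streams from one root
  seed so stages can be re-run independently.

# Problem sizes used in the validation suite

The test suite validates correctness with brute-force oracles on graphs of
up to 12 nodes (Floyd–Warshall distances, direct-summation local
efficiency, path-count betweenness, triangle enumeration), and validates
the statistics by simulation: null calibration with 500 replicate
4-site cohorts at the AUC level, and end-to-end recovery with 50
replicate cohorts of 4 sites x 25 subjects per group, 60 nodes and 120
timepoints with a 0.8 attenuation injected in patients — sizes chosen so
the full suite runs comfortably on a laptop while keeping Monte-Carlo
error small relative to the bands being checked. The same quantities are
recomputed by `scripts/acceptance.R`.

# Worked example

```{r example, eval = FALSE}
library(fctopo)

spec <- synthetic_spec(n_sites = 4, n_per_group_per_site = 25,
                       n_nodes = 60, n_timepoints = 120, n_modules = 6,
                       group_effect_delta = 0.8, seed = 42)
cohort <- synthesize_cohort(spec)

grid <- density_grid()           # 10%..34%, step 1%
auc_tab <- cohort_auc_table(cohort, grid,
                            metrics = c("e_glob", "e_loc", "e_nodal"))
res <- contrast_all_outcomes(auc_tab, cohort_covariates(cohort))
subset(as.data.frame(res), node_id == "GLOBAL",
       select = c(metric, beta, t, df, p, random_structure))

map_significant_nodes(res, cohort$nodes, metric = "e_nodal")
```

# Known limitations

- The generator's i.i.d. time samples understate the variance of
  correlation estimates relative to autocorrelated BOLD data.
- Random slopes over four-site designs are frequently singular; results
  then rest on the intercept-only fallback (always recorded).
- The package performs no image preprocessing: slice timing, realignment,
  normalization, nuisance regression and FD computation are assumed done
  upstream; FD is consumed as given.
- Site-effect handling is purely model-based (random effects); no
  harmonization of the connectivity matrices themselves is attempted.
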