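---
title: "Monte Carlo screening of environmental predictors for maximum-entropy niche models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo screening of environmental predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enmscreen)
```

## The problem

Presence-background niche models estimate habitat suitability from species
occurrence records and a stack of environmental raster layers. The fitting
software must hold every candidate layer in memory, so in practice modellers
pre-select a handful of predictors by hand — untenable when the candidate
pool is a large archive of climate-model output with hundreds of variables.

`enmscreen` screens such a pool stochastically. Instead of one model on all
n variables, it runs many small models, each on a random k-variable subset,
and accumulates for every variable (i) how many runs used it and (ii) the
sum of its permutation importance across those runs. The ratio of the two —
the average permutation importance — ranks the pool, and the running top-k
set converges long before the $\binom{n}{k}$ subset space could be
enumerated (already $\binom{19}{6} = 27{,}132$ for a classical bioclim
pool). Because every run is independent, the screen is embarrassingly
parallel and its cost is set by how densely the pool must be sampled, not
by the memory footprint of any single model.

## The model inside each run

Each run fits a maximum-entropy presence-background model: the Gibbs
distribution over the background sample

$$q_\lambda(x) = \frac{e^{\lambda \cdot f(x)}}{Z(\lambda)},\qquad
Z(\lambda) = \sum_{x \in \text{background}} e^{\lambda \cdot f(x)},$$

whose coefficients minimize the penalized negative log-likelihood of the
presences

$$J(\lambda) = -\frac{1}{n_p}\sum_{i \in \text{presence}} \lambda \cdot f(x_i)
 + \log Z(\lambda) + \sum_j \beta_j\,|\lambda_j|.$$

$f$ is the classical feature expansion: predictors are min-max scaled to
$[0,1]$ and expanded into linear (L), quadratic (Q), product (P, one column
per unordered variable pair), hinge (H, forward and reverse, 50 knots per
variable by default) and threshold (T, 50 step knots) features. The default
feature-class set is LQHP with regularization multiplier 1.0, the
historical default for large presence samples. Per-feature penalties are
$\beta_j = \text{RM} \times \beta_{\text{class}}(n_p) \times s_j /
\sqrt{n_p}$ with $s_j$ the feature's standard deviation over the presences
(floored at 0.001 on the unit feature scale) and $\beta_{\text{class}}$ the
published per-class interpolation tables (L/Q/P: samples (0, 10, 30, 100)
$\to$ (1, 1, 0.2, 0.05); hinge: constant 0.5; threshold: (0, 100) $\to$
(2, 1)). Which exact penalty interpolation a given historical MaxEnt build
used is not recoverable, so the tables are exposed as settings
(`modelSettings(betaTables = ...)`) rather than asserted as canonical.

The convex objective is optimized by an exact reformulation of the L1 term:
$\lambda = u - v$ with $u, v \ge 0$ turns $J$ into a smooth
bound-constrained problem solved by L-BFGS-B from a zero start, so the fit
is fully deterministic (tolerance $10^{-7}$, iteration cap 3000; hitting the
cap raises a convergence error rather than returning a half-converged
model). Coefficients pinned at the bound are exactly zero, which is what
the AICc parameter count uses.

Raw output is $q_\lambda$, normalized to sum to one over the training
background. Logistic output uses the historical transform
$\tau e^{H} r / (1 - \tau + \tau e^{H} r)$ with $\tau = 0.5$ and $H$ the
entropy of the fitted raw distribution; the no-information model therefore
maps to 0.5 everywhere. (An alternative algebraic form of this transform
that circulates in secondary descriptions fails that identity; the form
implemented here is the one with the correct uniform-model behaviour.)
Values projected outside the training range of a variable are clamped to
it.

## The screening algorithm

An *ensemble* is `nSprints` (default 100) *sprints* of `runsPerSprint`
(default 10) runs:

1. Each run draws k **distinct** variables uniformly from the pool. The
   draw is without replacement within a run: with k distinct uses per run,
   the expected number of samples per variable after R runs is exactly
   $kR/n$, which is the accounting the method's sampling-density guidance
   relies on.
2. The run fits a model on exactly those k variables and computes
   permutation importance: each variable's values are permuted jointly
   across presence and background rows, the training AUC drop from baseline
   (floored at 0) is recorded, and drops are normalized to percentages
   summing to 100 over the run's subset. Run-level importances are
   percentages *within* the run's own model, so the tally average is a mean
   of percentages.
3. The tally adds 1 to each used variable's count and the run's importance
   to its cumulative sum. Updates are applied in run-index order, so logs
   are identical regardless of execution order or the `workers` setting.
4. At the end of each sprint a model is fitted on the current top-k
   variables (highest average importance; ties break by pool order) and
   its AICc and training AUC are logged. While fewer than k variables have
   been used at all, the sprint-end model is deferred rather than fitted on
   a smaller set, keeping sprint metrics comparable.

Per-run seeds are derived from the master seed and the global run index by
a fixed integer hash (`deriveRunSeed`), which is what makes the ensemble
reproducible under any parallel execution order. Failed runs are logged and
excluded from the tally (their subsets do not count as uses). An
experimental stopping rule (`stopAfterStable`) can end the ensemble once
the top-k set has been unchanged for a configured number of sprints; it is
off by default.

Stability is reported two ways: the earliest sprint from which the top-k
*set* never changes again, and the earliest from which the full *rank
order* never changes. A selection that still changes in the final sprint is
reported as unstable rather than "stable since the last sprint".

## Evaluation statistics

* **AUC** is the rank-based (Mann-Whitney) form with ties counted ½.
* **AICc** $= 2K - 2\ln L + 2K(K+1)/(n-K-1)$ with $K$ the number of
  nonzero coefficients and $\ln L$ the sum of log raw outputs renormalized
  over the evaluation extent. The extent is the union of presence and
  background samples by default — the standard information-criterion usage
  in niche modelling — with a background-only option. AICc is reported as
  missing when $n \le K + 1$.
* **Niche overlap**: maps are renormalized to sum to one over shared valid
  cells, then Schoener's $D = 1 - \frac12\sum|p_1 - p_2|$ and Warren's
  Hellinger-based $I = 1 - \frac12\sum(\sqrt{p_1}-\sqrt{p_2})^2$. Overlap
  is conventionally computed on logistic-output maps (any common positive
  rescaling cancels in the normalization); raw maps can be passed equally.
  $I \ge D$ holds for typical maps but is not guaranteed, so only the
  $[0,1]$ bounds and symmetry are asserted.
* **Permutation importance** uses training-data predictions (the
  convention when importance is read from a model's own report) and a
  single permutation per variable by default; `nPermutations` averages
  several for variance reduction.

## Data preparation

Occurrences are deduplicated on exact coordinates (first record kept) and
spatially thinned by a greedy keep-first pass in record order: a record
survives iff its haversine distance (Earth radius 6371 km) to every
previously kept record is at least the thinning radius (default 16 km).
Greedy keep-first is deterministic and auditable, but thinned counts are
order-dependent, so counts reported for a particular study dataset are
reproduced only approximately by any independent thinning implementation.
Distances are spherical throughout — a 16 km buffer in planar lon/lat
degrees would be badly distorted at mid latitudes.

Background points are drawn uniformly without replacement from the valid
cells of the raster stack, 10,000 by default. Without replacement is the
natural reading of "select N cells from the study area" and guarantees the
exhaustive case (n equal to the number of valid cells) enumerates each cell
once; with a large grid the two conventions are practically
indistinguishable.

Raster I/O supports the ESRI ASCII grid format, which is plain text,
self-describing, and sufficient for aligned single-band stacks; inputs must
already share grid, origin and cell size (reprojection and resampling are
out of scope). The nodata mask is the union across layers, applied once at
read time, because the stack is treated as a single coverage area.
Collinearity among predictors is *reported* (pairwise r, r², and VIF with
the conventional highlight thresholds 0.8 / 0.8 / 10; perfectly collinear
variables get an infinite VIF) but never acted on — screening starts from
the full pool by design, and collinearity handling belongs to the
refinement steps that follow screening.

## The synthetic-data generator

`syntheticScenario()` emulates the real inputs: Gaussian random fields
(white noise smoothed by a Gaussian kernel of standard deviation
`smoothness` cells, via circular FFT convolution so the field is stationary
with no edge decay), standardized and linearly mixed through the Cholesky
factor of a target correlation matrix so inter-layer correlations approach
the target (exactness is asymptotic in grid size; tests use ±0.05 at
200×200). True suitability is the inverse logit of a stated linear (plus
optional quadratic) combination of the standardized signal layers, and
presences are drawn without replacement with probability proportional to
suitability, at cell centres (optional within-cell jitter), never on
nodata cells.

The defaults describe the package's standard recovery experiment: a 60×60
grid, 12 layers with smoothness 3, suitability driven by three layers with
a niche-shaped response — linear coefficients (2, −2, 2) plus quadratic
(−2, −2, −2) on standardized fields — and 150 presences. The quadratic
terms matter: a purely linear logit saturates, spreading presences over
half the landscape and leaving each true variable barely more
discriminative than a noise layer, whereas a niche optimum concentrates
presences (prevalence ≈ 10–15%) and gives each true variable
single-variable presence/background AUC around 0.7 — which is what "a
strong signal" has to mean operationally for a screen based on
discrimination drops. Smoothness is kept at 3 cells on a 60-cell grid so
the landscape retains enough independent spatial patches that chance
inter-layer correlation stays modest; smoother fields make noise layers
genuinely (if accidentally) informative in any single realization, which is
a property of real landscapes but not of a ground-truth test. What the
generator does
*not* emulate: derived bioclim-style variables with built-in algebraic
relationships, anisotropy, sampling bias in the occurrences, and
non-Gaussian marginals. Recovery results on these landscapes therefore
demonstrate the machinery's correctness and the sampling-density logic,
not performance on any particular real archive.

## Problem sizes and numerical choices

The bundled tests and the acceptance script run entirely on synthetic data
at deliberately modest sizes: 25–110 squared grids, 60–150 presences,
300–1000 background points, and LQ feature classes for the
screening-heavy experiments (the ground truth is linear/quadratic, so
richer classes add cost without changing what is being verified; the
engine's hinge/product/threshold paths are exercised directly in the unit
tests). The recovery experiment uses a 12-layer pool with k = 4 and
24 sprints × 10 runs, which yields 960 uses, i.e. exactly 80 average
samples per variable — the sampling density at which a reasonable top set
is expected to emerge — across 20 independent replicates.

Other numerical choices: features are scaled per variable by training
min/max and clamped on projection; constant feature columns are dropped
with a warning (an all-constant stack yields the uniform model, raw
$= 1/n_b$); coefficient values below $10^{-10}$ after optimization are
truncated to exact zeros; ties in the top-k ranking break by pool order so
results are deterministic; the singleton-subset run assigns importance 100
by normalization convention.

## Known limitations

* The engine targets fidelity to the maximum-entropy formulation, not
  bit-compatibility with any historical MaxEnt release; penalty tables are
  configurable for that reason.
* Thinning is greedy keep-first; it does not maximize the retained count.
* No categorical features, no sampling-bias correction, no
  clamping/extrapolation diagnostics, no reprojection.
* Large rasters are handled in memory; the out-of-core aspect of the
  screening idea (layers streamed from the filesystem per run) is modelled
  by the per-run column subsetting, not by actual streamed I/O.
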