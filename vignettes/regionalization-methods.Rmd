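---
title: "Ecological suitability and quality regionalization: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ecological suitability and quality regionalization: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

geoherb answers a practical question for a medicinal crop: *where* on a
territory does the species grow well, and *where* does the harvested material
accumulate the most marker compounds? It chains six stages — factor
screening, a presence-background niche model, natural-breaks
regionalization, content regression, raster projection and overlay — and
ships a synthetic-landscape generator so the whole chain is testable without
access to a regional environmental database. This vignette records the
models, their assumptions, and the design decisions that were genuinely
open.

## The data model

Environmental layers are regular lon/lat grids in the ESRI ASCII dialect.
Two conventions had to be fixed because input files do not carry them:

* **Registration.** `xllcorner`/`yllcorner` name the corner of the
  lower-left cell (the ESRI convention); cell identity for zonal work is by
  cell center.
* **Edge tie-break.** A point exactly on an internal cell edge belongs to
  the east/north neighbour, so extraction is deterministic.
* **Areas.** Cell areas use a spherical approximation,
  `(cellsize * pi/180 * R)^2 * cos(lat)` with `R = 6371.0088` km, per grid
  row. Zonal tables report km² and percentages rounded to two decimals.
* **Nodata.** Missing cells are `NA` internally and propagate through every
  operation: a nodata input cell yields a nodata output cell, and a sample
  row touching nodata is excluded from model fitting with a warning rather
  than imputed.

## Factor screening

Highly collinear layers destabilize niche-model attribution, so the factor
set is first thinned until every retained pair satisfies `|r| <= 0.8`
(sample Pearson correlation at the sampling sites). The loop is greedy,
worst pair first: find the largest off-diagonal `|r|`; if above the
ceiling, drop one member and recompute. Which member to drop is, in field
practice, an expert judgement about biological relevance — not computable.
The default keeps the member with the smaller mean absolute correlation to
all other candidates (the least redundant one), with lexicographic
tie-break; a user-supplied priority list overrides the rule and reproduces
expert choice exactly. Greedy removal was chosen over a set-cover
optimization because it matches the iterative rounds of screening tools
used in this field, and its post-condition (`max |r| <= 0.8` among
survivors) is asserted on every run. Categorical factors enter the
correlations as their integer codes — a documented caveat, not a
recommendation; it mirrors how vegetation-type and soil-type layers are
routinely correlated in published tables.

## The niche model

The core is a from-scratch presence-background maximum-entropy model. Over
a background sample of `N` cells (default 10,000, or every valid cell if
fewer; training presences are appended to the background, the standard
treatment of the normalizer), the model is the Gibbs density

    q(x) = exp(lambda . f(x)) / Z(lambda)

and fitting maximizes the regularized training gain

    mean over presences of lambda . f(x_i) - log Z(lambda)
      - sum_j beta_j |lambda_j| + log N,

which is zero for the uniform model. Features `f` are derived per factor:
continuous factors are rescaled to [0,1] by their background min/max, then
expanded into linear, quadratic and — when at least 15 presences are
available — forward hinge features at 31 evenly spaced knots; categorical
factors become one indicator per background level. The per-feature L1
penalties default to the published per-class tables interpolated at the
presence count, scaled by the feature's presence SD over `sqrt(m)`, with a
single `beta_multiplier` to tighten or relax all of them.

**Optimizer.** Cyclic coordinate ascent with an analytic Newton step per
feature, soft-thresholded for the L1 term and backtracked so the
regularized gain never decreases (this monotonicity is asserted in the test
suite). Coordinate ascent was preferred over quasi-Newton for two reasons:
it is simple and monotone, and it makes the *contribution trace*
well-defined — every update's gain increment is credited to the feature
that moved, which is exactly how percent contribution is defined (increase
in regularized gain added to the moving variable's total, subtracted when
`|lambda|` shrinks; feature totals floored at zero, summed per factor,
normalized to 100). Iteration stops when a full cycle improves the gain by
less than the convergence threshold (default 0.0005, the conventional
setting of desk studies with this model family) or after `max_cycles`
cycles (default 500; a much larger cap is harmless since convergence
virtually always fires first at these problem sizes).

**Outputs.** The raw output normalizes to 1 over the training background.
The logistic output is `exp(H) q / (1 + exp(H) q)` with `H` the entropy of
the fitted background distribution — the tau = 0.5 convention under which
the all-zero model scores 0.5 everywhere and a "typical" presence cell
scores about 0.5.

**Validation.** AUC is the Mann–Whitney pairwise statistic (ties credited
one half) of presence scores against the fixed background; it is invariant
under the raw/logistic choice. Both validation designs used in practice are
implemented: k-fold cross-validation (default, k = 10, fold sizes differing
by at most one) and a single random split with a 10% test fraction.
Whether test AUC should use true absences is moot here — there are none —
so background points stand in, which is the standard presence-background
reading.

**Attribution.** Besides percent contribution, permutation importance
shuffles one factor's raw values jointly across training presences and
background, re-evaluates training AUC with weights held fixed, and reports
the drop (floored at zero, normalized to 100). Response curves evaluate the
model over one factor's background range with the other continuous factors
held at their background means and categorical factors at their modes.

## Regionalization

Suitability is first clipped to the range observed at the occurrence cells
— cells outside `[min, max]` of the sampled suitability become nodata — and
then classified into four ordered classes (unsuitable, secondarily
suitable, suitable, optimum) by Jenks natural breaks: Fisher's exact
dynamic program minimizing total within-class sum of squared deviations,
implemented in C++ because the DP is `O(k n^2)`. Rasters beyond 10,000
finite values are reduced to a seeded subsample first. Breakpoints are
reported as class maxima; classification is lower-inclusive with the top
class closed. The published class bounds print touching interval endpoints
without stating sides, so lower-inclusive was fixed and documented: a value
equal to an internal bound belongs to the class above it. Zonal area tables
sum the latitude-aware cell areas per zone and class; percentages are
recomputable from the table's own areas, which the tests exercise against
published rows that are internally consistent (one published row is not,
and is deliberately excluded rather than "fixed").

## Content models and the quality overlay

Compound contents (% w/w) relate to ecological factors two ways. First, a
correlation report: Pearson r per factor-compound pair with the two-tailed
p from `t = r sqrt((n-2)/(1-r^2))`, flagged `*`/`**` at 0.05/0.01. Second,
bidirectional stepwise OLS with `alpha_enter = 0.05` and
`alpha_remove = 0.10` — the long-standing defaults of the statistical
packages this workflow historically used. Reports in this field rarely
record whether selection ran forward, backward or both ways, so
bidirectional (the most common package default) was chosen.
The fitted equations are projected cellwise onto the rasters in the
layers' native units (temperatures °C×10, sunshine h×10, seasonality
SD×100) — the published coefficient magnitudes only make sense in those
units, which is also why the growing-season sunshine coefficient's
apparent smallness (2.5e-5 per h×10) is not a typo. Negative predicted
contents are clamped to zero and counted.

Content rasters are graded by the published tiers (astragaloside IV:
< 0.04, 0.04–0.12, 0.12–0.20%; calycosin-7-glucoside: < 0.06, 0.06–0.18,
0.18–0.30%), lower-inclusive, with an optional refinement that splits the
outer tiers at their midpoints into a five-grade display scale — the
source describes five map grades but prints three content ranges, and this
is the only reading that honours both. "Both contents maximized" is
operationalized as the intersection: a cell is high-quality when it is in
the optimum suitability class *and* the top grade of both compounds. The
overlay is monotone by construction: tightening any grade can only remove
cells.

## The synthetic landscape generator

The generator exists so every downstream stage has a ground truth. It
emulates, structurally, the data situation of a regional medicinal-plant
study:

* **21 layers** (18 continuous, 3 categorical) with realistic magnitudes
  for a temperate steppe region, built by smoothing white noise with a
  moving-average kernel (default width 5 cells, circular boundaries),
  empirically whitening the smoothed fields and coloring them with the
  Cholesky factor of a target correlation matrix. Whitening makes the
  sample correlations match the targets exactly rather than merely in
  expectation — spatial autocorrelation would otherwise inflate the
  sampling error of r far beyond what cell counts suggest. The default
  targets put sub-0.8 compound-symmetric blocks on the factor families that
  are redundant in real databases (annual/seasonal temperature, the two
  sunshine layers, winter precipitation), so the default roster survives
  screening; screening behaviour itself is tested with purpose-built
  0.95-correlated blocks.
* **A rare, sharp habitat truth.** Suitability is the inverse logit of a
  weighted sum of the standardized latent fields plus an intercept of -15;
  with the default weights (logit-scale SD about 9, temperature
  seasonality dominant) about 5% of cells are favourable, with a sharp
  transition. Both choices matter: if suitable habitat covers half the
  landscape, even the *true* suitability ranks presences against
  background with AUC near 0.7, and no fitted model can look skilled. A
  localized species on a large territory — single-digit percent of cells
  favourable — is the regime in which occurrence data identify a niche,
  and is what the generator emulates. Occurrences sample cells without
  replacement proportionally to the truth, then place a point uniformly
  inside the cell.
* **Contents from the built-in equations.** Sample contents are the two
  generating linear equations plus Gaussian noise with
  `sigma^2 = var(lp) (1 - R2) / R2`, so the expected coefficient of
  determination equals the target (defaults 0.542 and 0.345). Contents are
  floored at zero because mass fractions cannot be negative; the default
  factor means keep both linear predictors two to three SDs above zero so
  the floor rarely binds (a few percent of samples) and coefficient
  recovery stays effectively unbiased. All measurement error is folded
  into the single Gaussian term — the assay's own error is not separately
  modelled, because no separate estimate of it exists to emulate.

What the generator does *not* reproduce: real geography (no coastlines,
political boundaries or terrain structure — synthetic zones are a
rectangular lattice), anisotropic or long-range spatial correlation,
sampling bias in the occurrences (they are drawn from the truth itself,
while field surveys follow roads and known production areas), and
non-Gaussian content noise. Passing tests on synthetic data therefore
demonstrate that the *computations* are correct and that the chain recovers
known structure under its own assumptions — not that the model assumptions
hold for any particular real landscape.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full chain on a 100 × 100
grid with 21 layers, 200 presences and a 10,000-point background —
comfortable desk scale chosen to keep a complete run around a minute while
leaving every code path (hinge features, subsampled Jenks, 10-fold
cross-validation) active. Smaller worlds (30–40 cells a side, 4–6 layers)
back the oracle comparisons. Other numerical choices worth recording:

* Coordinate steps are capped at 5 per update before backtracking, and the
  background weights are renormalized every cycle, so `exp` never
  overflows.
* The single-coordinate curvature is floored at 1e-12 to keep Newton steps
  finite on near-constant features.
* Jenks on more than 10,000 finite values uses a seeded subsample
  (`O(k n^2)` exact DP above that would dominate runtime); the seed is a
  function argument, so the pipeline is reproducible end to end.
* Grade and class boundaries are lower-inclusive everywhere, with end
  classes absorbing out-of-range values under a warning.
* `cor.test`, `lm` and `add1`/`drop1` come from base R; the package does
  not re-implement standard statistics.

## Known limitations

* The feature auto-selection and penalty tables follow the published
  conventions of the 3.3.3-era reference implementation, but fidelity is
  claimed at the level of conventions, not bit-for-bit behaviour; product
  and threshold features are tabulated for completeness but not generated
  by default.
* Percent contribution is path-dependent (it credits whichever feature
  moved during fitting), as it is in the reference implementation; with
  strongly correlated factors it should be read alongside permutation
  importance, which is model-agnostic.
* The stepwise selection inherits the usual caveats of stepwise inference:
  reported p-values are conditional on selection and the selected set is
  unstable near the thresholds. The generating-equation recovery tests
  quantify this on synthetic data.
* The even-odd polygon rasterizer assigns cells by center containment
  only; slivers narrower than a cell can drop out, which is acceptable at
  the 1-km-class resolutions this workflow targets.
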