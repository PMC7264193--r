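---
title: "Methods: harmonization, zonation, and mixed-model selection for body-size trends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: harmonization, zonation, and mixed-model selection for body-size trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pemasize)
```

`pemasize` studies how climate, urbanization and time shape body size in a
widespread small mammal, using trait records pooled from museum specimens,
historical censuses and live-capture surveys. This vignette is the
package's own account of the methods: the models and their assumptions,
the tunable parameters, what the synthetic data do and do not emulate, the
numerical conventions, and the design choices that were genuinely open.

## The statistical model

The response is an individual's body mass (g) or head-body length (mm,
derived as total length minus tail length). The core model is a Gaussian
linear mixed model on the untransformed trait:

- **Fixed effects** (all continuous predictors mean-centred and scaled by
  the sample SD): mean annual temperature (MAT, °C) and precipitation
  (MAP, mm) of the collection year, log human population density
  (log persons/km², decade-indexed), sex (female reference, so the
  `sexmale` coefficient is the male−female difference), season as a
  4-level factor with Fall as reference (the reported contrasts are
  fall–spring, fall–summer, fall–winter), and — in temporal models — the
  standardized decade bin index as a single numeric trend.
- **Random effects**: intercepts for ecoregion and data source in every
  model; temporal models additionally carry a correlated per-zone
  (intercept, decade-slope) pair, where zones are the 200 km grid cells
  described below. The slope–intercept correlation of that pair is a
  quantity of direct scientific interest: a strongly negative value means
  zones holding larger animals trend smaller over decades and vice versa.

Two deliberate structural choices deserve explanation. First, all
candidate models are fit by **maximum likelihood (ML), not REML**, because
candidates differ in their fixed effects and REML likelihoods are not
comparable across fixed-effect structures; a REML refit of a selected
model is available (`fit_lmm(..., refit_reml = TRUE)`) and changes only
the reported estimates, never the ranking. Second, temporal models retain
the ecoregion and source intercepts alongside the zone structure. The
data-generating world (synthetic or real) contains ecoregion- and
source-level heterogeneity whether or not the analyst models it, and
omitting those intercepts lets whichever realized region effects happen to
align with the climate gradients masquerade as climate effects. Keeping
them is the conservative choice and is what the parameter-recovery tests
validate.

Model suites are ranked by **AICc** with the parameter count `k` equal to
fixed effects + variance/covariance parameters + the residual variance.
Akaike weights, ΔAICc, and Nakagawa-style marginal/conditional R²
(variance of the fixed-effect predictor over the summed variance
components) are computed from their closed forms. p-values on fixed
effects are Wald z tests and are labelled as such; model support values
are the primary inferential currency.

## Record harmonization

Filters run in a fixed order, each logged in an audit table
(`records_out = records_in − removed` at every step, chaining):

1. coordinate presence (records that cannot be georeferenced are dropped;
   manual georeferencing is out of scope);
2. dates: missing month or day, 1-January dates (a known signature of
   year-only reporting), years before 1895, impossible calendar dates;
3. sex: case-insensitive `female`/`male` only; trailing `?` or any other
   token ("undetermined", empty) is ambiguous and removed;
4. life stage: records *labelled* `juvenile` are removed (unknown stages
   are retained — only explicit labels are trusted);
5. HB-length derivation; non-positive derivations are flagged
   (`negative_hb`) and nulled rather than propagated;
6. per-trait branches: the mass dataset drops masses strictly below 9 g
   (9.0 g is retained; the floor targets unambiguous juveniles), then a
   **single-pass** outlier rule removes any record with any measurement
   (mass, tail, total) more than 3 sample SDs from that dataset's mean.
   The statistics are computed once, not iterated, and a zero-SD
   measurement removes nothing. The HB dataset gets the same outlier pass
   without the mass floor;
7. season assignment with fixed boundaries (Spring Mar 20–Jun 20, Summer
   Jun 21–Sep 21, Fall Sep 22–Dec 20, Winter Dec 21–Mar 19; astronomical
   dates move by at most a day across years, so fixed boundaries keep the
   assignment reproducible), and decade bins of ten years anchored at
   1895 (13 bins through 2019, the last truncated to 2015–2019);
8. optional cuts: temporal analyses keep years ≥ 1945 (earlier decades
   are too sparse to satisfy the zonation criteria), and the live-capture
   source can be excluded because its length measurements are
   systematically short.

One property worth stating explicitly: a k-SD outlier rule applied to
unbounded Gaussian noise flags a small fraction (~0.27% at k = 3) of
perfectly clean records *by construction*, because the threshold scales
with the SD. The pipeline makes no attempt to distinguish these from
injected errors — no rule could — and the test fixtures that demand exact
audit bookkeeping therefore use the generator's bounded-noise option
(below). A related consequence of the sample-SD convention: in very small
datasets a single gross error can dominate the SD and escape the rule
entirely (five values {10, 10, 10, 10, 100} yield z ≈ 1.79 for the 100).

## Covariate pairing

Rasters are regular lat/lon grids with half-open cells
[west, east) × [south, north), so every interior point maps to exactly
one pixel and a point a hair inside the eastern edge reads the edge cell.
Climate is read from the layer matching the record's collection year
(deer mice live well under a year, so the collection-year climate is the
relevant exposure). Density is read from the record's decade, with
records after the last available decade (2010) using that last layer;
values are aggregated by block means at 1, 4 or 10 km (partial edge
blocks average the pixels available; complete blocks conserve the global
mean) and transformed as log(density + 0.01) — the floor makes zeros
finite and is far below any ecologically meaningful density.
Standardization uses the sample (n−1) SD and stores the mean/SD metadata
so coefficients can be re-expressed per °C, per mm, or per log-unit of
density. Which aggregation scale feeds the models is not empirically
pinned down; 1 km is the default and all three are available.

## Spatial replicates: ecoregions and grid zonation

Ecoregion membership is a point-in-polygon label; three wide-ranging
regions are split at 42°N into Northern/Southern daughters (latitude
exactly 42 goes North). Points on shared polygon edges take the
lexicographically first region name (byte order, locale-independent) —
an arbitrary but deterministic convention for a measure-zero case.

The zonation optimizer works in a conterminous-US Albers equal-area conic
projection (standard parallels 29.5°/45.5°, spherical earth, implemented
from the standard closed forms and verified by round-trip and
metric-scale tests) so that "200 × 200 km" is metrically meaningful. Cell
corners are sampled *continuously* over the projected bounding box — on a
fixed lattice the replace-if-overlapping rule could never fire — and a
candidate cell is retained when it holds ≥ 75 records and ≥ 4 decade bins
each hold ≥ 10 records. The decade criterion is read as "at least four
bins with at least ten records", not "ten in every represented bin": a
single stray record in an otherwise empty decade should not disqualify a
densely sampled cell (the stricter reading is available via the criteria
list). A qualifying candidate that overlaps retained cells replaces *all*
of them iff its record count strictly exceeds their combined total; this
combined-total rule makes the total retained record count provably
non-decreasing over iterations (a per-cell comparison rule is available
as an option but lacks the monotonicity guarantee). Edge-touching cells
do not conflict: overlap means positive-area intersection.

The optimizer's iteration loop is exact, not approximate: a prefix-sum
bin index gives every candidate an O(1) upper bound on its record count,
and only candidates that could qualify are counted exactly. On one CPU,
200,000 iterations over ~50,000 projected records run in well under two
minutes; small instances reach ≥ 95% of a brute-force lattice optimum in
the test suite.

## The synthetic study system

`generative_truth()` holds every parameter of the simulator. Defaults are
the package's reference conditions and are deliberately on the scale of
the real system: baseline adult mass 20 g and HB length 90 mm;
standardized effects of −0.5 g/SD for MAT and MAP, −0.3 for log density,
−0.2 for decade; females 0.65 g heavier; fall the lightest season
(spring +1.8, summer +0.8, winter +0.9 g); ecoregion SD 1.23 g and source
SD 0.2 g; per-zone intercept SD 0.5 g and decadal slope SD 0.3 g with
slope–intercept correlation −0.9; residual SD 3.6 g. Records concentrate
in 40 lattice cells (the "true zones", known to the generator so recovery
tests have unambiguous truth) plus a 5% uniform background; sampling
weight per decade follows the historical record-density shape (sparse
before 1945, a mid-century census pulse, a present-day pulse), and source
labels follow eras (census source 1948–1956, live-capture from 2013).
Live-capture HB lengths carry a −4 mm bias; the real magnitude of that
bias is not established, so only its sign and detectability matter and it
is configurable. Contaminants — labelled juveniles, sub-9 g unlabelled
juveniles, unusable dates, ambiguous sex strings, gross measurement
errors — are injected as mutually exclusive classes at configurable rates
and recorded in a hidden truth column for exact bookkeeping.

Two refinements keep the generator honest about what filters can and
cannot see. Clean records never draw a 1-January date: that signature is
reserved for the misreported-date class (real New-Year collecting is
vanishingly rare), so date-filter audits are exact. And the mass residual
is split into a shared individual "condition" component (55% of the
residual variance, propagated to HB length at the allometric scale) plus
trait-specific noise — marginal variances are unchanged, but the two
traits acquire the moderate log-log allometric correlation real animals
show, rather than being conditionally independent.

What the generator does **not** emulate: species-distribution structure
(records are uniform within zones), trap-level capture processes,
elevation-adjusted climate downscaling, spatially autocorrelated
residuals, or age structure beyond the juvenile classes. Passing
recovery tests therefore demonstrates that the *pipeline and estimators*
are correct under the stated generative assumptions — not that the real
data satisfy those assumptions.

## Numerical conventions and degenerate inputs

- lme4 fits use `nloptwrap` first, retrying once with `bobyqa` on
  non-convergence; a fit that still fails is returned flagged and is
  excluded from ranking (and logged). Boundary ("singular") optima are
  *converged* fits with a flag: at a true correlation of −0.9 and 40
  zones the ML correlation frequently lands exactly on −1, a legitimate
  boundary optimum that the diagnostics must not discard.
- Random terms whose grouping factor has one level are dropped; with no
  random terms left the model collapses to OLS (tested to 1e−6 against
  `lm`).
- AICc requires n > k + 1 and errors otherwise; Akaike-weight ties are
  broken by model name in byte order.
- The empirical slope–intercept correlation from two zones is ±1 by
  construction and is flagged unreliable (fewer than three zones).
- All internal character sorts use radix (byte) order so results are
  identical across locales; every stochastic stage takes an explicit seed
  and restores the caller's RNG state, and one top-level seed fans out to
  per-stage child seeds so stages can be rerun independently.
- Standardization refuses zero-SD columns; `unstandardize()` inverts
  exactly (round-trip tested to 1e−10).

## Problem sizes used by the test suite

The suite validates the likelihood against a brute-force grid-search
oracle on 8–10-row fixtures (tolerance 1e−3), information criteria and
weights against closed forms (1e−12), the optimizer against exhaustive
lattice enumeration on 3–4-cluster instances, and parameter recovery at
the reference scale (n = 20,000 records, 40 zones), with 20-replicate
blocks for model-selection behaviour and 100 cheap replicates (n = 3,000)
for the null-coverage control. These sizes were chosen to exercise every
code path at the smallest scale where the statistical property being
tested is identifiable.

## Known limitations

- The candidate sets default to all subsets of the global fixed-effect
  structure (32 spatial, 64 temporal); bespoke published candidate lists
  can be supplied explicitly but are not reconstructed.
- The decade trend enters as a single standardized linear term; nonlinear
  decadal shapes are visible only through the exploratory per-zone OLS
  trends (`fit_per_zone_trends()`).
- With ~40 zones, correlation-type quantities carry sampling noise of
  roughly ±0.17 regardless of estimator; single-realization magnitudes
  near a threshold should be read accordingly.
- The BLUP-based slope–intercept correlation inherits shrinkage: sparse
  zones pull it toward the model-implied value, which is why both the
  covariance-parameter estimate and the BLUP correlation are reported.
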