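# pemasize

Spatiotemporal body-size trend analysis for multi-source small-mammal trait
records, built around the North American deer mouse (*Peromyscus
maniculatus*, "PEMA").

## The scientific problem

Body-size decline is a hypothesized universal response to climate warming
(Bergmann's rule read over time instead of space), while urbanization may
push size either way — down through urban heat, up through fragmentation
and food subsidies (the island rule). Testing these ideas for a single
widespread species needs tens of thousands of trait measurements pooled
from heterogeneous sources: digitized museum specimens (VertNet-style),
historical census programmes (NACSM-style), and modern live-capture
surveys (NEON-style). Each stream carries its own biases — juvenile
contamination, misreported dates, ambiguous sex codes, and systematically
shorter length measurements on live animals — so the pooled data must be
harmonized, paired with environmental covariates, and stratified into
spatially explicit replicates before any model can be trusted.

`pemasize` implements that full pipeline as tested, reusable R functions:

1. **Harmonization** (`run_pipeline()`): head-body length derivation
   (HB = total − tail), date/sex/life-stage filters, a 9 g adult mass
   floor, a single-pass 3-SD outlier rule over every measurement, and
   season (equinox/solstice) and decade (10-year bins anchored at 1895)
   assignment — all with a per-step audit trail.
2. **Covariates** (`extract_climate()`, `extract_density()`,
   `standardize()`): mean annual temperature and precipitation of each
   record's collection year, log human population density of its decade
   (at 1, 4 or 10 km aggregation), standardized over the modelled dataset.
3. **Zonation** (`assign_ecoregion()`, `optimize_grid_zones()`): ecoregion
   membership with 42°N splits of three wide-ranging regions, and a
   stochastic optimizer that retains non-overlapping 200 × 200 km
   equal-area cells holding ≥ 75 records with ≥ 4 decades of ≥ 10 records
   each — the spatiotemporal replicates.
4. **Models** (`fit_lmm()`, `rank_models()`, `nakagawa_r2()`,
   `random_effect_diagnostics()`): suites of Gaussian linear mixed models
   fit by maximum likelihood with lme4, ranked by
   AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1), with Akaike weights
   w_i = exp(−Δ_i/2)/Σ exp(−Δ_j/2), marginal/conditional R², and the
   correlation between per-zone random intercepts and random decadal
   slopes — the statistic behind "bigger populations are shrinking,
   smaller ones are growing".
5. **Synthesis** (`generative_truth()`, `simulate_records()`): a
   generator for climate surfaces, decadal density layers, ecoregions and
   trait records with fully known effects, random-effect SDs, measurement
   bias and contamination rates, so every stage above is testable against
   ground truth.

## Worked example

```r
library(pemasize)

bundle <- simulate_bundle(list(seed = 42, n = 8000))
harmonized <- run_pipeline(bundle$records,
                           list(temporal = TRUE, include_neon = FALSE))
head(harmonized$audit, 7)
#>            step n_in n_removed n_out
#> 1   coordinates 8000         0  8000
#> 2         dates 8000       326  7674
#> 3           sex 7674       242  7432
#> 4     lifestage 7432       407  7025
#> 5  mass_present 7025         0  7025
#> 6    mass_floor 7025       173  6852
#> 7 mass_outliers 6852       112  6740

zones <- optimize_grid_zones(harmonized$mass, max_iter = 20000, seed = 42)
zones
#> <grid_zonation> 27 cell(s) of 200 km, 4450 zoned record(s), 20000 iteration(s), seed 42

dataset <- build_model_dataset(harmonized$mass, bundle$climate, bundle$density,
                               bundle$ecoregions, zonation = zones,
                               zone_source = "zonation")
fit <- fit_lmm(dataset,
               model_spec("body_mass",
                          c("MAT", "MAP", "sex", "season", "decade"),
                          "temporal"))
fit
#> <fit_result> body_mass ~ MAT + MAP + sex + season + decade [temporal]
#>   n = 4450, k = 14, logLik = -11978.39, AICc = 23984.88, converged: TRUE
#>           term estimate     se     z        p
#> 1  (Intercept)   18.940 0.4245 44.61 0.00e+00
#> 2        MAT_z   -0.643 0.1096 -5.87 4.43e-09
#> 3        MAP_z   -0.369 0.1911 -1.93 5.35e-02
#> 4      sexmale   -0.670 0.1066 -6.28 3.33e-10
#> 5 seasonSpring    1.903 0.1515 12.56 3.55e-36
#> 6 seasonSummer    0.917 0.1521  6.03 1.65e-09
#> 7 seasonWinter    1.046 0.1530  6.83 8.23e-12
#> 8 decade_bin_z   -0.290 0.0786 -3.69 2.22e-04
```

Reading the output: body mass falls with temperature (Bergmann's rule;
−0.64 g per SD of MAT) and declines across decades (−0.29 g per SD of
decade) after accounting for climate, season, sex and the random
structure; males are ~0.67 g lighter than females and fall-collected
animals are the lightest. `nakagawa_r2(fit)` gives marginal R² = 0.077
(fixed effects) and conditional R² = 0.164 (fixed + random), and
`random_effect_diagnostics(fit)` returns the zone slope–intercept
correlation (strongly negative here: zones holding heavier mice trend
lighter over decades, and vice versa).

The generator's defaults are the package's reference study conditions;
`cmd_recover()` runs the full simulate → harmonize → model loop and
tabulates every true parameter against its estimate with 3-SE coverage
flags.

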