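Package: pemasize
Title: Spatiotemporal Body-Size Trend Analysis for Multi-Source Small-Mammal Trait Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for analysing climate- and
    urbanization-driven body-size variation in the North American deer mouse
    (Peromyscus maniculatus) from heterogeneous trait-record streams
    (digitized museum specimens, historical censuses, live-capture surveys).
    Provides harmonization and quality filtering of Darwin-Core-style records
    with a per-step audit trail, pairing of records with year-indexed climate
    surfaces and decade-indexed human population density layers, stochastic
    optimisation of non-overlapping 200 km equal-area grid zones used as
    spatiotemporal replicates, and suites of linear mixed-effects models
    ranked by AICc with marginal/conditional R-squared and random-effect
    diagnostics (including the correlation between zone intercepts and zone
    decadal slopes). A fully parameterised synthetic-data generator with
    known generative truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    MASS,
    mgcv,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
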