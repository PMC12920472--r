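Package: entsdm
Title: Optimized Maximum-Entropy Species Distribution Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Presence-only species distribution modeling with an
    L1-regularized maximum-entropy (MaxEnt) engine and the surrounding
    analysis pipeline: occurrence cleaning and spatial thinning, predictor
    screening by model contribution and Pearson collinearity, feature-class
    and regularization-multiplier tuning by small-sample-corrected AIC
    (AICc), AUC and true-skill-statistic evaluation with bootstrap
    replicates, suitability classification (fixed or Jenks natural breaks),
    area and change accounting on geographic grids, and geodesic
    centroid-shift analysis between climate scenarios. Includes a synthetic
    landscape generator with a known species-environment relationship so the
    whole pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    geosphere,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
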