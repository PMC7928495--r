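Package: enmscreen
Title: Monte Carlo Variable Screening for Maximum-Entropy Niche Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens large pools of environmental predictors for
    presence-background ecological niche modelling by running many small
    maximum-entropy model fits on random variable subsets and accumulating a
    tally of per-variable permutation importance that converges on the top
    contributing subset. Includes a self-contained penalized maximum-entropy
    (MaxEnt-style) engine with linear, quadratic, product, hinge and
    threshold feature classes, model evaluation statistics (AUC, AICc,
    Schoener's D and Warren's I niche overlap), spatial occurrence thinning,
    ESRI ASCII raster grid input/output, background point sampling,
    collinearity reporting, and a synthetic-landscape generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    parallel
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'enmscreen-package.R'
    'envgrid.R'
    'features.R'
    'maxent.R'
    'metrics.R'
    'occurrences.R'
    'pipeline.R'
    'screen.R'
    'synthetic.R'
    'utils.R'
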