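Package: socpotential
Title: Quantile-Based Soil Organic Carbon Storage Potential
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts conditional percentiles of topsoil (0-30 cm) soil organic
    carbon from climate, terrain and land-cover covariates with a multi-task
    quantile neural network trained under the pinball loss, harmonizes layered
    soil profiles to a standard depth with the equal-area smoothing spline,
    converts concentrations to areal carbon stocks through a bulk-density
    pedotransfer function, and quantifies additional storage potential,
    4-per-mille accumulation timelines, historical carbon debt from land-cover
    substitution, and climate-change sensitivity. Includes a synthetic-data
    generator with closed-form conditional quantiles so every stage is testable
    against an analytic oracle, and a sampled Shapley attribution of the model's
    predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    minpack.lm,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'RcppExports.R'
    'socpotential-package.R'
    'attribution.R'
    'depth-harmonization.R'
    'grid.R'
    'pipeline.R'
    'ptf.R'
    'quantile-model.R'
    'scenarios.R'
    'serialize.R'
    'stocks.R'
    'synthetic-data.R'
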