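Package: shadrange
Title: Mechanistic and Correlative Range Modelling for Anadromous Fish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and project the distribution of anadromous fish
    (such as allis shad, Alosa alosa) along a network of river basins under
    climate forcing. Provides a seasonal, temperature-dependent life-cycle
    simulator with Beverton-Holt recruitment modified by an Allee effect,
    von Bertalanffy growth, sea and river survival, and a three-stage
    homing/straying dispersal process; calibration machinery built on summary
    statistics, complete two-level factorial sensitivity analysis, and
    rejection-based approximate Bayesian computation; a correlative
    presence-absence habitat-suitability model (binomial additive models with
    restricted degrees of freedom, exhaustive AIC selection, Cohen's kappa,
    AUC and kappa-maximizing thresholds); and guidelines-style joint analysis
    of the two model families. A synthetic-data generator produces basin
    networks, seasonal climates and virtual-species distributions so the full
    tool chain runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    geosphere,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
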