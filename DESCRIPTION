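Package: phenosync
Title: Environmental Predictability and the Length of Ungulate Birth Seasons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking breeding synchrony in wild herbivore
    populations to the predictability of their resource base. Implements
    anomaly smoothing of satellite vegetation-index (NDVI) time series,
    Colwell's constancy/contingency/predictability statistics on
    discretized seasonal series, phylogenetic generalized least squares
    (PGLS) with maximum-likelihood estimation of Pagel's lambda, AICc
    model comparison across a candidate set of ecological models,
    evolutionary-model selection (Brownian motion, white noise, lambda),
    and Moran's I spatial autocorrelation diagnostics. Includes
    generators for synthetic NDVI series, Yule phylogenies with
    population polytomies and lambda-structured traits, so the whole
    pipeline can be exercised and validated without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    geosphere,
    rlang,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
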