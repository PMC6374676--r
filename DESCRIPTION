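Package: upslope
Title: Elevational Range Shifts of Breeding Birds and Their Climate and
    Habitat Drivers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to estimate yearly elevational response curves of breeding
    birds from heterogeneous point-count surveys, extract curve reference
    points (optimum, central and outer borders) with bootstrap reliability,
    test reference-point time series for upward trends with effort-weighted
    regressions, classify species-level patterns of elevational range change
    (lower boundary contraction, upward shift, upper boundary expansion),
    partition the explained variation of each shifting reference point between
    a minimum-temperature series and a shrub-and-forest cover series, attribute
    range changes to climate or habitat drivers with rule-based calls including
    density-dependent-effect relabelling, and summarise pattern-trait-driver
    associations with Poisson log-linear models. A synthetic-data generator
    (landscape, daily temperature grids with delta-method downscaling, habitat
    encroachment surveys, Bernoulli point-count surveys from known response
    curves) provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
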