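Package: mixray
Title: Interpolation-Based Toxicity Prediction for Binary Chemical Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the toxicity of binary chemical mixtures by spatial
    interpolation over a training set of fixed-ratio (EquRay) mixture rays:
    linear interpolation on a Delaunay triangulation and Sibson natural
    neighbour interpolation on the dual Voronoi tessellation of the
    concentration plane. Includes concentration-response curve fitting for
    monotonic (Weibull, Logit) and hormetic J-shaped responses, the
    concentration addition (CA) and independent action (IA) reference
    models with blind-zone detection, the effect residual ratio (ERR)
    interaction statistic with confidence-interval overlap classification,
    EquRay fixed-ratio mixture design, cross-validation protocols
    (repeated random holdout and leave-one-ray-out) scored by
    confidence-interval overlap accuracy rate, and a synthetic assay-data
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    deldir,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
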