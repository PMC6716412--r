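Package: countysae
Title: County-Level Small Area Estimation by Combining Two Health Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Small area estimation of county-level prevalence of health
    behaviors (smoking, cancer screening) by combining an area-sampled
    in-person survey covering all telephone-status groups with a much larger
    landline telephone survey subject to frame-noncoverage bias.  Provides
    survey-weighted direct estimation with Kish design effects, arcsine
    square-root variance stabilization, a multivariate Fay-Herriot-type
    hierarchical Bayes model with a telephone-survey bias-adjustment factor
    and correlated county random effects fitted by Gibbs sampling,
    phone-composition smoothing and back-transformation to county prevalence
    estimates with credible intervals, a validation battery (funnel ratios,
    national benchmarking, county summaries, weighted external correlation),
    and a synthetic two-survey data generator for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    nnet,
    coda
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
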