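Package: stabdecomp
Title: Decomposition of Community Temporal Stability into
    Statistical-Averaging and Compensatory Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decomposes the temporal stability of an ecological community
    (the inverse coefficient of variation of aggregate biomass) into
    population stability, species asynchrony, and the statistical-averaging,
    evenness, and compensatory effects that make up asynchrony.  The
    compensatory effect is further split into environmental and
    species-interaction components using surrogate communities built from
    replicate plots or from monocultures.  Includes amplitude-adjusted
    Fourier transform (AAFT) surrogate resampling for bootstrap confidence
    intervals, diversity indices, site-level aggregation with log10 ordinary
    least squares regressions against diversity, and a Gaussian community
    simulator with closed-form expected components for estimator validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
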