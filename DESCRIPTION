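Package: befpart
Title: Complementarity and Selection Effects from Complete or Incomplete
    Species Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Additive partition of the net biodiversity effect on ecosystem
    function into complementarity and selection effects from paired
    monoculture and mixture biomass data, together with bias-corrected
    estimators that recover population-level effects when monoculture data
    are available for only a random subset of the species pool. Includes
    Monte-Carlo and exhaustive subsampling experiments quantifying
    estimator bias and sampling error, sampling-error intervals for
    empirical applications, a synthetic-community generator with
    controllable true effects, multiplicative observation-error injection
    calibrated from replicate measurements, and a small command-line
    interface.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
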