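Package: iiwbias
Title: Omission Bias in Inverse-Intensity Weighted GEEs for Irregularly
    Observed Longitudinal Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying what happens to inverse-intensity weighted
    generalized estimating equations (IIW-GEEs) when subjects with no
    follow-up assessments are dropped from the analysis.  Provides a
    simulator for cohorts whose assessment intensity depends on the last
    observed outcome, Andersen-Gill proportional-intensity fits under the
    "everyone" and "follow-up only" inclusion schemes, weighted GEE
    estimation of an outcome trajectory with an area-under-the-curve
    estimand, closed-form bias theory for the intensity-model coefficient
    when the intensity covariate is time-invariant, and a Monte Carlo
    experiment harness comparing the two inclusion schemes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    survival,
    sandwich,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
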