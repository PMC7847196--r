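Package: xenopower
Title: Model-Based Analysis and Power Simulation for Xenograft Tumour Growth Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-arm xenograft tumour-volume studies with a
    linear-radius mixed-effects growth model. Tumour volumes are converted to
    radii under a spherical assumption and modelled as straight lines in time
    with lognormal animal-level baseline and growth-rate random effects and
    proportional residual error. Treatment effects are tested by a likelihood
    ratio test against the nested no-effect model, alongside the conventional
    empirical percent tumour growth inhibition (TGI) with an unpaired t-test on
    final-day volumes. A study simulator, effect-size calibration to target TGI,
    and a Monte-Carlo power engine support the design of patient-derived (PDX)
    and cell-line derived (CDX) xenograft experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nlme,
    optparse,
    jsonlite
Config/testthat/edition: 3
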