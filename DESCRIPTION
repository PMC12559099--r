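Package: huiharm
Title: Cross-Scanner Harmonization of the Hepatocellular Uptake Index from
    Gadoxetate-Enhanced MRI
Version: 0.1.0
Authors@R:
    person("HUI", "Harmonization Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for placing the hepatocellular uptake index (HUI), an
    MR-signal-intensity-based quantitative liver function biomarker measured
    on gadoxetate disodium-enhanced MRI, onto a common scale across MR
    scanners. Implements through-origin calibration of HUI against the
    indocyanine green plasma disappearance rate (ICG-PDR) and the
    albumin-bilirubin linear predictor (ALBI-LP), per-scanner conversion
    factors (CF1, CF2) and the cross-route coefficient (CF3), harmonized HUI
    and estimated ICG-PDR, commutability assessment by confidence-interval
    overlap, residual bias/precision decomposition with bootstrap intervals,
    ICC(2,1) observer concordance, a multi-scanner synthetic cohort
    simulator, minimal NIfTI-1 image I/O for HUI measurement, and a
    command-line interface covering the simulate/fit/harmonize/validate
    workflow.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
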