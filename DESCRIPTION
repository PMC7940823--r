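Package: qcsfsim
Title: Simulation and Validation of Quantitative Contrast Sensitivity Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate Bayesian adaptive estimation of the contrast
    sensitivity function (CSF) and to evaluate the resulting clinical vision
    outcomes in silico. Implements the truncated log-parabola CSF model and
    its scalar features (area under the log CSF, CSF acuity, low-contrast
    cutoff frequencies), a grid-based Bayesian adaptive testing engine with
    information-gain stimulus selection, synthetic observers and cohorts with
    multiple-sclerosis-like and healthy-control-like contrast sensitivity,
    quantized Snellen chart acuity simulation, and test-retest repeatability
    statistics (Bland-Altman coefficient of repeatability and a Mean Average
    Precision metric that penalizes quantized outcomes). Three end-to-end
    experiments reproduce, on synthetic cohorts, the precision/convergence,
    repeatability, and group-discrimination analyses used to validate
    adaptive contrast sensitivity testing as a clinical outcome measure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
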