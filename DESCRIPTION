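Package: flcourse
Title: Microsimulation of the Natural History of Fatty Liver
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-level discrete-time microsimulation of the natural
    history of fatty liver (hepatic steatosis) in adult men.  Derives annual
    transition probabilities for fatty-liver presence from longitudinal
    health-examination panels via main-effects logistic regression on
    dichotomized risk factors (BMI >= 25 kg/m2, LDL-C/HDL-C ratio >= 2),
    evolves risk-factor trajectories with stochastic autoregressive annual
    update rules, and projects cohort prevalence life-courses by Monte Carlo
    with +/- 2 SD uncertainty bands.  Includes a calibrated synthetic-cohort
    generator (open enrollment, attrition, age-band missingness of the
    ultrasonography diagnosis), model validation by calibration, time-shift
    consistency and external comparison, and one-way sensitivity analysis of
    initial cohort composition and annual-update perturbations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
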