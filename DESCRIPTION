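Package: omibayes
Title: Sequential Bayesian Diagnosis of Occlusion Myocardial Infarction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A transparent likelihood-ratio engine for diagnosing acute
    coronary occlusion (occlusion myocardial infarction, OMI) in emergency
    department chest-pain patients. Provides age- and sex-specific anchor
    prevalences, sequential updating of disease odds with published
    likelihood ratios for clinical findings, ECG interpretation tiers and
    troponin assays, action thresholds for catheterization-lab activation
    and fibrinolysis, Fagan nomogram construction and SVG rendering, replay
    of five published case vignettes against their printed probability
    checkpoints, and a synthetic-cohort simulator that measures the
    probabilistic calibration of the serial-multiplication framework,
    including its breakdown under correlated findings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
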