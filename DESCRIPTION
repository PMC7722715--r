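Package: oculorate
Title: Pre-Target Oculomotor Inhibition Analysis for Foreperiod Paradigms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying pre-target oculomotor inhibition in temporal
    expectation (foreperiod) paradigms. Includes a synthetic binocular gaze
    generator with ground-truth fixational drift, main-sequence-compliant
    microsaccades, blinks and a hazard-rate-driven pre-target inhibition
    effect; zero-phase low-pass filtering, trial segmentation and pupil-based
    blink exclusion; Engbert-style velocity-threshold saccade detection with
    binocular conjunction and main-sequence quality control; saccade-rate
    time courses and the pre-target saccade-rate statistic; and the
    statistical battery (repeated-measures ANOVA with sphericity corrections,
    planned contrasts with FDR adjustment, Cohen's dz and partial eta squared
    with confidence intervals, JZS Bayes factors, within-subject standard
    errors) used to discriminate temporal-orienting from certainty accounts
    of the inhibition effect.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car
Suggests:
    testthat (>= 3.0.0),
    signal,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
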