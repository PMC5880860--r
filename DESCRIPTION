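Package: gazeparse
Title: Adaptive Parsing of Eye-Tracking Data into Fixations and Saccades
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parses raw eye-tracker samples into fixations and saccades using
    per-trial, data-driven velocity thresholds. Local speed maxima are compared
    against a uniform null distribution via a gap statistic, smoothed by locally
    weighted quadratic regression with increasing bandwidth until unimodal; the
    smoothed maximum is the velocity threshold. Robustness-aware post-processing
    (gap interpolation, spatial-overlap merging of successive fixations, duration
    thresholding) handles flickery, low-precision recordings such as infant data.
    Includes fixed-threshold velocity and dispersion baselines, per-trial data
    quality metrics (robustness, precision), cross-method fixation-split
    comparison, and a ground-truth scanpath simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
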