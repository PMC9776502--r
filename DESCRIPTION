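Package: pmold
Title: Perfect Matrices of Lagrange Differences for Cardiac Interval Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies the algebraic relationship between beat-wise cardiac
    intervals (JT, QRS, RR) by embedding them in trajectories of second- and
    third-order perfect matrices of Lagrange differences, mapping each matrix
    to a scalar through a matrix norm, and smoothing the resulting sequence.
    Per-subject variances of the smoothed relationship feed a Gaussian cohort
    baseline whose one-sigma variation interval supports a probability
    indicator and a traffic-light semi-gauge for flagging atrial-fibrillation
    risk. Includes a seeded generator of synthetic healthy and AF-like
    interval cohorts, CSV/JSON input and output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    nortest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
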