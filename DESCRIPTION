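Package: proxyrate
Title: Pol II Elongation Kinetics from Nascent Transcription Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies RNA polymerase II elongation kinetics at
    signal-induced genes from time-course nascent-transcription coverage
    (e.g. PRO-Seq). Implements the Rate of Change in Coverage (ROCC)
    estimator: a zero-intercept regression of binned coverage on time that
    yields a per-gene "Proxy Rate" surrogate for elongation speed, together
    with its single-timepoint and gene-quartile variants. Also provides
    strand-aware gene region derivation (promoter-proximal, gene body,
    3' end), bedGraph coverage handling with RPKM/CPM and spike-in
    normalization, immediate early gene classification from fold-change
    thresholds, region density and metagene quantitation, rate benchmarking
    against reference elongation rates, and a seeded wavefront simulator
    that generates induction time courses with known elongation rates for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
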