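Package: spikeburst
Title: Burst Detection, Spike-Train Statistics and Stimulation Protocol Synthesis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for trial-structured single-unit spike trains:
    a two-stage mean inter-spike-interval (ISI) threshold burst detector, a
    suite of per-train burst and firing-rate metrics with group aggregation
    and exemplar-cell selection, rate-matched homogeneous Poisson spike-train
    synthesis with bit-exact stimulation protocol export, synthetic generators
    for burst-structured trains and miniature EPSC samples with known ground
    truth, and a statistical battery (normality-routed two-sample and
    multi-group comparisons with Student-Newman-Keuls or Dunn post-hoc tests,
    and two-sample Kolmogorov-Smirnov distribution comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
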