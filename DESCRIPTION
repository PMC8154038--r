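Package: mgcpn
Title: Spike-Train and Calcium-Imaging Analysis of Macroglomerular-Complex
    Projection Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for odor-evoked activity of moth
    macroglomerular-complex (MGC) projection neurons. Implements Z-scored
    instantaneous firing-rate (ZIFR/MZIFR) spike-train statistics with
    threshold-based response classification, sub-window amplitudes and
    onset/peak latencies; ratiometric calcium-imaging response detection
    against a control-derived threshold; cross-individual response
    consistency correlations; a neuropil-level descriptive framework with
    projection-combination response simulation validated by R-squared; and a
    shuffled-assembly robustness analysis. Ships a synthetic-data generator
    (inhomogeneous-Poisson spike trains, shared-tuning calcium traces) that
    emulates the statistical structure of such recordings so the whole
    pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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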