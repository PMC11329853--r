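Package: mtvalidate
Title: Concurrent Validity of Fabric Skin-Strain Sensors Against Optical Motion Capture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for evaluating the concurrent validity of piezoresistive
    skin-strain sensors ("Motion Tape") against marker-based optical motion
    capture during low back movement. Decodes hex-encoded raw resistance logs
    to strain, applies Hampel outlier filtering and a population quality-control
    rule, computes multisegmental lumbar Euler angles (XYZ sequence) from
    labeled marker trajectories, aligns and normalizes both streams per trial,
    and summarizes zero-phase-shift cross-correlation coefficients per sensor
    and movement as medians and ranges. Includes a synthetic-data module that
    simulates participants, movement protocols, rigid-segment marker motion,
    and sensor physics (gauge-factor response, noise, spikes, saturation,
    fatigue drift, compression-release rebound) so the full pipeline is
    exercisable without access to laboratory data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2,
    rlang,
    signal,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
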