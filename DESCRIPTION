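Package: semgrid
Title: High-Density Surface EMG Processing with Gaussian-Mixture Spatial Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Signal-processing and pattern-recognition chain for high-density
    surface electromyography (HD-sEMG) electrode grids: bandpass and power-line
    notch filtering, sliding-window RMS amplitude features, a one-dimensional
    Gaussian mixture model fitted by expectation-maximization to pooled
    channel amplitudes, discretization of per-channel amplitudes into
    simplified 2D spatial activation patterns on the electrode grid, and
    pattern-based motion classification with a small feed-forward network and
    majority-vote temporal smoothing.  Includes a calibrated synthetic
    HD-sEMG session generator with controllable spatial activation structure,
    delimited-text and EDF signal I/O, and a reproducible end-to-end pipeline
    runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    data.table,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
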