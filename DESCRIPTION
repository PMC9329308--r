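Package: dociR
Title: Dynamic Optical Contrast Imaging Analysis and Phantom Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes per-pixel relative fluorescence lifetime (DOCI) images
    from time-resolved autofluorescence stacks by gated integration: the
    aggregate decay-tail intensity normalised by the aggregate steady-state
    intensity, per band-pass emission channel. Includes a physics-based
    synthetic phantom generator (multi-exponential decays under square-pulse
    excitation, Poisson shot noise plus Gaussian read noise) for labelled
    surgical scenes, ROI statistics with tumor-normalised relative lifetimes
    and per-channel one-sample t-tests, nerve-axis profiling with a
    threshold-plus-run-length caller for perineural invasion, and
    pseudo-color margin rendering with TIFF/YAML/JSON I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    grDevices,
    graphics,
    utils,
    tools,
    tiff,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
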