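Package: mitomotion
Title: Automated Quantification of Fast Mitochondrial Transport in
    Time-Lapse Fluorescence Movies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring fast, microtubule-motor-driven transport of
    mitochondria in time-lapse fluorescence microscopy movies. Provides a
    seeded synthetic-movie simulator with known ground truth; movie
    pre-conditioning (spatial binning, rigid-body registration, quintic
    B-spline temporal stretching, cropping, contrast normalization);
    dense Lucas-Kanade optical flow with Gaussian-derivative gradients and
    a structure-tensor eigenvalue noise gate; log-velocity histogram
    montages with an automated running-standard-deviation artifact mask
    and flow tables; a two-stage difference-filter plus mass-particle
    tracker with motion reports; and screen-level statistics (pooled-control
    Dunnett comparisons, Welch t-tests). A batch runner processes a plate
    manifest end to end with reproducible, seeded outputs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    yaml,
    jsonlite,
    multcomp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
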