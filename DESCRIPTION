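Package: octframe
Title: Frame-Based Reconstruction of Swept-Source OCT Images from
    Redundant and Non-Uniform Spectral Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing optical coherence tomography (OCT)
    A-scans and B-scans from redundant and non-uniformly spaced k-space
    samples using finite frame theory. Implements the scaled non-uniform
    discrete Fourier transform (a sinc-frame dual reconstruction with
    local-spacing weights), an FFT-accelerated gridded evaluation,
    Mach-Zehnder interferometer fringe calibration of swept-laser
    wavelength sweeps by Gauss-Newton nonlinear least squares, an
    oversampling-based noise-reduction analysis with analytic and
    Monte-Carlo frame bounds, and synthetic phantom generators that
    emulate swept-source OCT acquisition at desk scale.
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
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
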