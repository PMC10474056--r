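Package: whiskervib
Title: Modal Analysis of Whisker Vibrations and Dispersive Tactile
    Transduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing high-frequency vibrational micromotions of
    tactile whiskers (vibrissae). Solves the truncated conical fixed-free
    Euler-Bernoulli eigenproblem and simulates base shear forces after
    slip-off events; computes complex Morlet wavelet spectrograms, per-mode
    FFT bandpass filter banks, power envelopes and modal energy partitions;
    estimates modal frequencies, damping ratios (two-regime method), group
    velocities and Young's modulus from trimming series; segments
    pinned-unpinned-collision events from traced whisker shapes and computes
    contact forces and elastic/kinetic energy budgets; and converts modal
    power traces into threshold-crossing spike trains with direct-method and
    jackknife mutual-information estimates. Includes a synthetic-data
    generator with ground-truth labels for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
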