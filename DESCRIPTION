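Package: nystagmetry
Title: Linear and Nonlinear Characterisation of Nystagmus Waveforms
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of eye-position recordings of
    nystagmus (involuntary ocular oscillations). Implements the standard
    clinical assessment (position statistics, per-cycle amplitude, frequency
    and intensity, fixation stability, saccadic-intrusion detection),
    segmented Fourier amplitude spectra with triangular tapering and zero
    padding, unstable-periodic-orbit detection from threshold-crossing
    intervals with shuffled-surrogate significance testing, delay-embedding
    attractor reconstruction with principal-component projection and a
    quantitative attractor classifier, and sliding-window normalized
    permutation entropy with cross-recording rank-sum comparison. A seeded
    synthetic-cohort generator produces periodic, quasiperiodic and
    nonperiodic vertical oscillations with clinically realistic artifacts so
    that every stage of the framework can be exercised without subject data.
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
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
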