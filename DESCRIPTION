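Package: swdkit
Title: Detection and Spectral Analysis of Spike-Wave Complexes in Rodent EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for the analysis of spike-wave discharges
    (SWDs) in epileptic rodent EEG/ECoG. The signal is split into slow and fast
    components by two-pass moving-average detrending; the fast component is
    modelled as an ordered sum of quasi-Gaussian kernels fitted to its
    half-waves (fragmentary decomposition); spike complexes are found by
    template matching on kernel triplets; amplitude spectra of
    arbitrary-length segments are computed by a continuous Fourier transform
    of the piecewise-linear interpolant; and peak frequencies are summarized
    per record and compared across epilepsy models with one-way ANOVA and
    Bonferroni post-hoc tests. A seeded synthetic-EEG generator emulates four
    rat epilepsy-model archetypes (WAG/Rij, GAERS, post-SE, PTE) with ground
    truth, so every stage is testable without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    nortest,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
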