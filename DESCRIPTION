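Package: pupvox
Title: Noise-Playback Bioacoustics Pipeline for Pinniped Pup Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for noise-playback experiments on
    harbour seal pup vocalizations. Synthesizes calibrated bandpass noise beds
    with embedded harmonic pup-like calls and ground-truth annotations; screens
    calls (clipping, overlap, extraneous noise, trackability); tracks
    fundamental frequency by normalized autocorrelation; computes
    noise-compensated call intensity, signal-to-noise ratio and two
    spectral-tilt measures (one-third-octave log-energy slope and the R14 band
    ratio) via gain compensation and spectral subtraction; and runs
    permutation-tested random-intercept models, per-individual Mann-Whitney
    tests with Bonferroni control, and coefficient-of-variation analyses
    across noise conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
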