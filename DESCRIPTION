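Package: semgfatigue
Title: Simulation Framework for Spectral Fatigue Indices of Surface EMG
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing how well mean frequency (MNF) and median
    frequency (MDF), the standard myoelectric fatigue indices, can be
    recovered from short, noisy surface electromyography (sEMG) recordings
    whose power spectrum is compressed into the low-frequency band, as
    happens during severe muscle fatigue.  Provides the band-pass
    Stulen-De Luca spectral model and a minimum-phase shaping filter to
    synthesize fatigued sEMG, first-principles Welch (averaged modified
    periodogram) and Burg (autoregressive lattice) power spectral density
    estimators, MNF/MDF extraction, and a seeded factorial Monte-Carlo
    study over signal duration, signal-to-noise ratio and estimation
    method, summarised by mean absolute error and a cascade of factorial
    ANOVAs with Tukey HSD post-hoc comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
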