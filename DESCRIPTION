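Package: voicechimera
Title: Auditory Chimera Stimuli and Simulated ROI Analyses of Voice Selectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to engineer acoustically matched voice and instrument
    stimulus banks, build auditory chimeras that exchange the per-band auditory
    spectrum between sounds while preserving temporal structure, compute
    auditory-model acoustic descriptors (harmonic-to-noise ratio, spectral
    centroid, dominant spectrotemporal modulation rate and scale), verify
    between-category acoustic matching, generate event-related trial sequences
    with behavioral scoring, and simulate region-of-interest BOLD time series
    for general-linear-model analyses with parameter recovery, including paired
    contrasts and repeated-measures ANOVA with Greenhouse-Geisser correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
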