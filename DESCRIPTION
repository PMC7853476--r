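Package: gawscreen
Title: Glottal Area Waveform and Acoustic Voice Parameter Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing synchronized glottal area waveform (GAW) and
    acoustic recordings of sustained phonation. Detects maximum- and
    minimum-based oscillation cycles, computes a 49-parameter battery of
    fundamental-frequency, perturbation, left-right symmetry, glottal-dynamic
    and noise measures (35 GAW-based, 14 acoustic-based), screens all
    GAW-acoustic parameter pairs with Pearson and distance correlation under
    Benjamini-Yekutieli false-discovery-rate control per gender, and emits
    per-group norm tables. Includes a seeded synthetic-cohort generator that
    emulates sustained /i/ phonation with controllable jitter, shimmer,
    residual glottal gap, left-right asymmetry and acoustic noise, providing
    ground truth for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
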