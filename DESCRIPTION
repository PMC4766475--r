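Package: hrvmap
Title: N-Dimensional Normalized Return Maps for Heart Rate Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generalized N-dimensional normalized return-map analysis of RR-interval
    series. Computes globally (Delta) and locally (delta) normalized distance-to-identity-line
    vector fields over forward moving-average windows, the primary-variability statistic Phi_N
    on the stride-N window subset, a catalog of universal arrhythmic line directions (linear
    ramps, respiratory sinusoids, compensated ectopic pairs, pause-tachycardia runs and their
    displaced and shadow variants), generalized-angle template matching with presence
    percentages, per-record signature vectors, a seeded synthetic RR generator with ground-truth
    event logs, plain-text RR input/output, and 3D-plus-hue variability graphs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    ggplot2,
    lattice
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
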