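Package: eegmicrostates
Title: EEG Microstate Segmentation and Microstate-Conditioned Source Connectivity
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Resting-state EEG microstate analysis: global field power,
    polarity-insensitive modified k-means clustering of GFP-peak
    topographies with global explained variance and cross-validation
    model selection, backfitting, and the classical temporal parameters
    (duration, occurrence, coverage); sLORETA minimum-norm source
    imaging over a toy spherical head model with region parcellation and
    per-microstate Pearson connectivity; nonparametric group comparisons
    (Mann-Whitney asymptotic Z, two-sample Z test); and a ground-truthed
    synthetic cohort generator so every stage is testable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
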