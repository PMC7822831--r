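Package: eegms
Title: EEG Microstate and Task-Related Alpha Power Analysis for Loosely
    Controlled Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multichannel EEG recorded under loosely
    controlled, self-paced task designs. Implements task-related power (TRP)
    in the lower and upper alpha sub-bands (Welch spectra, composite Simpson
    band integration, log power change against a resting reference, cortical
    area aggregation), polarity-invariant modified k-means microstate
    segmentation on global field power peaks with a cross-validation criterion
    for the number of classes, hierarchical full-permutation template
    alignment, backfitting with edge-run removal and coverage/duration
    parameters, topographic randomization tests (TANOVA), repeated-measures
    ANOVA with Greenhouse-Geisser correction, and a synthetic study generator
    with planted ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
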