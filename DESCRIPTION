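Package: whiskgate
Title: Sensory Gating Analysis for Active Whisker Touch Electrophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for quantifying sensory gating in brainstem trigeminal
    recordings during an active whisker touch task. Classifies whisker-object
    contacts as whisking or non-whisking from pre-contact kinematics, performs
    deceleration-matched trial selection, sorts extracellular spikes
    (threshold detection, PCA, k-means), computes peri-contact PSTHs and
    per-unit gating statistics (evoked peak ratios, baseline-rate ratios,
    double-peak extraction), nonparametric AUC effect sizes with bin-wise
    effect profiles and response widths, and whisking-onset triggered firing
    analyses. Includes a synthetic session generator with full ground truth
    for parameter-recovery testing and a pipeline orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
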