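Package: gazecluster
Title: Gaze Cluster Membership and Inter-Subject Correlation for Multi-Viewer Video Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frame-by-frame density-based clustering of multi-subject
    eye-tracking data for dynamic stimuli. Implements gaze cluster membership
    (GCM), a per-video-frame indicator of viewer attention obtained by
    DBSCAN clustering of all viewers' gaze positions with adaptive neighborhood
    parameters, together with inter-subject correlation via correlated
    component analysis (CorrCA) for gaze and EEG signals, the associated
    eye-tracking and EEG preprocessing chains (blink padding, off-screen
    masking, artifact rejection), linear and mixed-effects analysis models,
    and a synthetic multi-observer session generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    lme4,
    yaml,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
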