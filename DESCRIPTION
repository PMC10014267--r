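Package: gaitsource
Title: Gait-Cycle-Resolved EEG Source Imaging and Cerebellum-Cerebrum
    Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for gait-cycle-resolved EEG source imaging
    and scalp-level cerebellum-cerebrum connectivity analysis. Segments
    walking EEG into heel-strike-anchored stride epochs, time-warps them
    onto a common gait-phase axis, inverts a combined cortical plus
    cerebellar spherical head model with weighted-minimum-norm and eLORETA
    estimators, and derives baseline-normalized z-score source maps per
    gait-cycle quartile with maximal-statistic permutation inference.
    Scalp connectivity between occipital reference electrodes and the rest
    of the montage is quantified with phase-locking values and the
    imaginary part of coherency, contrasted against spherical-spline
    interpolated surrogates to isolate locally generated (putatively
    cerebellar) phase-locking. A synthetic gait-EEG generator with planted
    sources provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    MASS,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
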