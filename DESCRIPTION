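Package: efpcouple
Title: EEG-Informed fMRI Coupling Analysis with EFP Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of the coupling between fMRI-informed EEG models
    (EEG fingerprints, "EFPs", trained to predict the BOLD activity of a
    deep target region) and voxel-wise BOLD dynamics during simultaneous
    EEG-fMRI.  Implements EFP time-course computation from raw EEG via the
    discrete Stockwell transform and pluggable time-frequency weight
    models; voxel-wise general linear models with group-level t-tests and
    Benjamini-Hochberg false discovery rate correction; per-subject
    functional region-of-interest selection by seed coactivation
    percentiles; a sliding-window correlation test against a
    shuffled-window permutation null; emotional-reactivity indices from
    continuous ratings; block-design task timelines; and a synthetic
    EEG-fMRI cohort generator with known ground truth for recovery
    testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    RNifti,
    rlang,
    signal,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
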