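Package: faceflow
Title: Intracerebral EEG Analysis of Face, Gaze and Emotion Processing with
    White-Matter Tract Endpoint Overlap
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for multi-patient intracerebral EEG studies of
    the occipitotemporal face-processing network. Provides a synthetic-data
    generator with planted ground truth (trial designs for a Posner-like
    gaze/emotion paradigm, depth-electrode recordings with N200-family ERP
    components and polarity reversals, and white-matter streamline sets);
    preprocessing into artifact-cleaned, baseline z-scored bipolar epochs;
    two-step site responsiveness testing via cluster-based sign-flip
    permutation t-tests with per-region Bonferroni correction; ERP morphology,
    amplitude effect-size and jackknife peak-latency statistics; pointwise
    2-by-2 gaze-by-emotion ANOVAs with cluster correction; and streamline
    endpoint-density mapping with electrode-tract overlap matrices.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    car,
    jsonlite,
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
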