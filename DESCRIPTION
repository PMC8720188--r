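Package: neofc
Title: Resting-State Functional Connectomics for Neonatal
    Music-Intervention Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Connectome-based analysis of pre/post-stimulus resting-state
    fMRI in newborn cohorts: framewise-displacement and DVARS volume
    censoring with guard-window scrubbing, grey-matter atlas masking,
    nuisance regression and band-pass filtering of regional BOLD series,
    accordance functional connectomes, edge-wise paired pre/post
    statistics with between-group z-score fusion, and a dose-response
    partial least squares correlation (PLSC) of delta nodal strength with
    permutation, bootstrap and leave-one-out cross-validation. Includes a
    synthetic cohort generator emulating a three-group neonatal study
    design for calibration and parameter-recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti
Config/testthat/edition: 3
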