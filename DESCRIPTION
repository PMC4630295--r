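Package: phasereg
Title: Phase-Regression Suppression of Large Draining Veins in Complex-Valued BOLD fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for suppressing the contribution of large draining veins to
    gradient-echo BOLD fMRI using the complex-valued signal. Implements the
    phase regressor (PR) with a closed-form chi-squared fit and the
    source-localized phase regressor (sPR), which selects the best phase
    source from a voxel's face-adjacent neighbourhood under an ordinary
    least-squares loss. Includes a single-voxel complex-signal simulator for
    functional SNR grids, a physics-based vein phantom built on the infinite
    cylinder susceptibility field model (with intravoxel dephasing,
    task-modulated blood oxygenation, and venogram minimum-intensity
    projection), slice-wise homodyne phase filtering, polynomial detrending
    and z-scoring, block-design contrast t-maps, threshold-and-cluster ROI
    definition, and vein-contribution and hemisphere-laterality metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    RNifti,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
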