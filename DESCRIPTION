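Package: msasym
Title: Microstate-Based Resting Frontal Alpha Asymmetry and Its Hemodynamic Correlates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments multichannel resting EEG into quasi-stable microstates
    (modified K-means on global-field-power peak maps, GEV/CV diagnostics,
    global-map-dissimilarity back-fitting), computes standard (current source
    density referenced) and microstate re-expressed frontal alpha asymmetry
    indices for the F4/F3 and F8/F7 channel pairs, builds TR-locked asymmetry
    regressors for EEG-informed fMRI parametric-modulation models, estimates
    per-voxel hemodynamic response functions by blind deconvolution and a
    hemodynamic lateralization index for paired left/right regions, and links
    asymmetry to behavioral scores through a robust-correlation battery
    (Pearson, Spearman, 20% percentile-bend, skipped) with percentile
    bootstrap confidence intervals and Bonferroni adjustment. Includes
    synthetic EEG/BOLD/score generators with known ground truth so the whole
    workflow is testable without any acquisition.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    signal,
    pracma,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
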