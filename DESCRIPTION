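Package: lffconn
Title: Seed-Based Low-Frequency Fluctuation Functional Connectivity for
    Rodent Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Seed-based resting-state functional-connectivity analysis of
    rodent BOLD fMRI built around the synchronization of low-frequency
    fluctuations (LFF, below 0.08 Hz). Provides voxel-wise Pearson
    correlation mapping against seed-region reference timecourses,
    significance thresholds calibrated by the effective degrees of freedom
    of low-pass filtered series, supra-threshold voxel counting within
    atlas regions with baseline normalization, Fisher-z group maps,
    interhemispheric timecourse and Fourier comparisons, and a one-way
    ANOVA arm for Y-maze trials-to-criterion. A synthetic 4D BOLD generator
    emulates a longitudinal connectivity-loss-and-recovery design (bilateral
    somatosensory and hippocampal coupling abolished in one hemisphere and
    later restored), including linear and nonlinear baseline drift and
    aliased respiratory/cardiac components, with full ground truth recorded
    for every run.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
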