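Package: csfcoupling
Title: Global BOLD-CSF Coupling Analysis for Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the coupling between the global
    blood-oxygen-level-dependent (gBOLD) signal and the cerebrospinal
    fluid (CSF) inflow signal from resting-state fMRI, a noninvasive
    proxy for glymphatic function.  Provides NIfTI-1 volume and mask
    input, motion-parameter quality control, the two preprocessing
    branches (detrending, 0.01-0.1 Hz zero-phase band-pass filtering,
    Gaussian smoothing, mask-averaged signal extraction), the lagged
    cross-correlation coupling metrics with a subject-shuffling
    permutation null, cohort-level group and correlation statistics
    with Bonferroni control, and a seeded synthetic-cohort generator
    with ground truth for recovery testing.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
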