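Package: xtalmerge
Title: Multi-Crystal Diffraction Data Assembly with Progressive Wedges
    and Iterative Outlier Rejection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles many partial microcrystal rotation data sets into
    complete crystallographic data sets. Each crystal's frames are scored
    as progressive (accumulative) wedges by the half-dataset correlation
    CC1/2 and trimmed to the best wedge; the selected data sets are
    classified by hierarchical clustering of unit-cell parameters; and
    each sufficiently complete class is optimized by iterative rejection
    of incompatible crystals (ranked by their mean smoothed per-frame
    Rmerge) and of radiation-damaged frames (grid search over decay
    cutoffs). An internal statistics engine provides scaling, merging,
    Rmerge/Rmeas, CC1/2, anomalous-difference correlation, completeness
    and per-frame Rmerge profiles, and a seeded synthetic microcrystal
    simulator supplies ground-truth test data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
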