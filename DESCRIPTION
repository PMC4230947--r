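Package: qmrivox
Title: Voxel-Based Group Analysis of Quantitative MRI Parameter Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and voxel-based group analysis of quantitative MRI
    (R1, R2, proton density) brain maps. Provides a digital brain phantom
    with focal lesions, diffuse white-matter change and ventricular
    enlargement; a forward model and per-voxel fitting for multi-delay
    multi-echo saturation-recovery acquisitions; synthetic contrast-weighted
    image reconstruction; partial-volume tissue segmentation and brain
    volumetry; affine spatial normalization to a common 2 mm grid;
    voxel-wise general-linear-model statistics with permutation-based
    family-wise-error control; signed two-dimensional parameter-pair
    difference histograms; and region-of-interest erosion analysis with
    mixed-model group tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    lme4,
    lmerTest,
    ggplot2,
    rlang,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
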