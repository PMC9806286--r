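Package: splenometry
Title: Cavalieri Spleen Volumetry and Single-Slice Morphometry from
    Abdominal MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Stereological estimation of spleen volume from parallel MRI
    sections by the Cavalieri principle, with the Gundersen-Jensen /
    Cruz-Orive coefficient of error, intensity-threshold segmentation,
    single-slice morphometry at the L1 vertebral level (diameters, areas,
    one-pixel boundary circumference, craniocaudal spleen length),
    dual-rater averaging and a from-first-principles multiple linear
    regression of spleen volume on length and single-slice predictors.
    Includes voxelized phantom generators with exact analytic volumes and a
    gender-stratified synthetic cohort generator so the whole pipeline is
    testable against known ground truth, plus DICOM/NIfTI/CSV input-output
    and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    RNifti,
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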