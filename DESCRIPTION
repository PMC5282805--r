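Package: tarsalSSM
Title: Statistical Shape Models of Tarsal Bones via Spherical Harmonics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds statistical shape models (SSMs) of the four largest
    tarsal bones (calcaneus, cuboid, navicular, talus) from volumetric
    images or closed surface meshes. Implements slice-wise region-growing
    segmentation, oriented-normal estimation and star-shaped radial
    remeshing, automatic landmark detection on labelled surface patches,
    landmark-based rigid pose normalization, real spherical-harmonic
    (SPHARM) decomposition of the surface radius function with
    minimum-description-length model-order selection, per-coefficient
    descriptive statistics, mean-shape reconstruction, left/right
    laterality correlation, two-way ANOVA over bones and coefficients,
    and random-forest bone classification with stratified
    cross-validation. Ships a synthetic bone-shape generator with known
    ground-truth coefficients so the whole pipeline is testable end to
    end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    randomForest,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
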