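# tarsalSSM

Statistical shape models (SSMs) of the four largest tarsal bones —
calcaneus, talus, cuboid and navicular — built from volumetric images or
closed surface meshes, with spherical-harmonic (SPHARM) shape
descriptors as the common currency.

**Who it is for.** Researchers in medical image analysis, orthopaedics
and biomechanics who want a compact, parametric, statistically tractable
representation of rear-foot bone shape: for atlas building, morphometric
comparison, automated bone recognition, or as features for downstream
models.

**What it does.** The full model-building chain, end to end:

1. slice-wise CT-like segmentation (contrast enhancement, seeded region
   growing, contour tracing) into a 3D point cloud;
2. oriented-normal estimation and radial remeshing of star-shaped
   clouds onto a subdivided icosahedron;
3. automatic landmark detection (extremal vertices of labelled surface
   patches) with expert-override support;
4. landmark-based rigid pose normalization into a canonical frame
   (no scaling: size stays in the model);
5. SPHARM decomposition of the surface radius function
   `r(θ, φ) = Σ c_lm Y_lm(θ, φ)` in the real orthonormal basis, fitted
   by least squares, with model order selectable by a
   minimum-description-length (MDL) criterion;
6. SSM statistics — per-coefficient quartiles/means/outliers, mean-shape
   reconstruction, left/right correlation of mean coefficient vectors,
   two-way ANOVA over bones × coefficients — and 4-class random-forest
   bone recognition with stratified 10-fold cross-validation.

Since clinical CT data cannot ship with the package, a first-class
synthetic generator produces bone-like populations (4 classes × 15
subjects × 2 sides, mirrored left feet, known ground-truth coefficients,
painted landmark patches, optional noisy voxel phantoms) so that every
stage is testable with known truth.

## Worked example

```r
library(tarsalSSM)

## one synthetic talus-like bone with known truth
pop <- sample_population(default_bone_classes()$talus, 2, seed = 42)
s <- pop[[1]]
s$mesh
#> tri_mesh: 642 vertices, 1280 faces, labelled patches: a, c, b

## SPHARM fit at the generating degree recovers the truth
fit <- fit_spharm(parameterize(s$mesh), 4)
fit
#> spharm_model: L = 4 ( 25 coefficients ), mean radius 12.39 mm, rms residual 1.45e-15 mm
max(abs(fit$coeffs - s$coeffs_true))
#> 6.66e-16

## landmarks and canonical pose
lm <- detect_landmarks(s$mesh, "talus",
                       class_landmark_rules(default_bone_classes()$talus,
                                            s$side))
np <- normalize_pose(s$mesh, lm)
np$transform
#> pose_transform (mode in_plane): alpha = 2.295 rad, beta = 0.7322 rad, C = (-9.056,  5.477, -7.221) mm
np$landmarks
#> landmark_triple (talus):
#>   a = vertex 565 at (  2.178e+01,  8.246e-16, -1.776e-15 ) mm
#>   b = vertex 544 at ( 15.65, 11.80,  0.00 ) mm
#>   c = vertex 492 at ( 0, 0, 0 ) mm
```

The fitted coefficients equal the generating ones to machine precision;
after normalization landmark c sits at the origin, a on the +x axis and
b in the z = 0 plane — the canonical frame every bone is compared in.
The mean radius printed by the model is `c0 / (2·sqrt(pi))`, the
size-term reading of the first coefficient.

## The full experiment

`run_pipeline(pipeline_config("synthetic", seed = 1))` runs the whole
chain on the default 120-bone cohort and writes coefficient tables,
per-group statistics, mean-shape PLY surfaces, laterality/ANOVA/
classifier JSON reports and a hash manifest. The numbered scripts under
`analysis/` walk the same experiment step by step and write summary
tables under `results/`:

```sh
Rscript analysis/01_simulate_population.R
Rscript analysis/02_voxel_segmentation_demo.R
Rscript analysis/03_fit_models.R
Rscript analysis/04_ssm_statistics.R
Rscript analysis/05_classification.R
```

Typical headline numbers on the synthetic cohort: laterality r² per
bone ≥ 0.98 (full coefficient vectors), all three ANOVA effects
significant at p ≪ 0.001, and 0% cross-validated misclassification at
every ensemble size in the {10, …, 160}-tree sweep.

See `vignettes/tarsal-shape-models.Rmd` for the model, the numerical
conventions, the synthetic-data design and known limitations.

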