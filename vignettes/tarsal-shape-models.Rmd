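---
title: "Statistical shape models of tarsal bones: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical shape models of tarsal bones: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tarsalSSM)
```

## The modelling problem

A statistical shape model (SSM) of a bone is a mean shape plus a
description of inter-subject shape variation, built from a sample of
segmented surfaces. For the four largest tarsal bones — calcaneus,
talus, cuboid and navicular — the chain implemented here runs:

1. **Segmentation**: decompose a CT-like volume into sagittal slices,
   enhance contrast per slice, grow a region from a seed pixel, trace
   the region's outer contour, and stack the contours into a 3D point
   cloud in millimetres.
2. **Surface building**: estimate oriented normals by local plane fits
   and resample the cloud onto a subdivided-icosahedron sphere by radial
   interpolation, giving a closed, consistently wound triangle mesh.
3. **Landmarking**: locate three anatomical points a, b, c per bone as
   extremal vertices of labelled surface patches.
4. **Pose normalization**: a rigid (rotation + translation, never
   scaling) map into the canonical landmark frame.
5. **SPHARM decomposition**: expand the surface radius function about
   the centroid in real orthonormal spherical harmonics, with the model
   order selectable by a minimum-description-length criterion.
6. **Statistics and classification**: per-coefficient descriptive
   statistics, mean-shape reconstruction, left/right correlation,
   two-way ANOVA over bones × coefficients, and random-forest bone
   recognition with stratified 10-fold cross-validation.

Because no clinical volumes ship with the package, a first-class
synthetic generator (`sample_population()`) produces bone-like
populations with *known* ground truth at every stage; all tests and the
acceptance analysis run end-to-end on it.

## The SPHARM representation

A closed surface that is star-shaped about an interior origin is fully
described by its radius function $r(\theta, \phi)$. We expand it in the
real orthonormal spherical harmonics (no Condon–Shortley phase):

$$r(\theta,\phi) = \sum_{l=0}^{L}\sum_{m=-l}^{l} c_{lm}
  Y_{lm}(\theta,\phi), \qquad
  \int_{S^2} Y_{lm} Y_{l'm'} \, d\Omega = \delta_{ll'}\delta_{mm'},$$

with $m<0$ the sine harmonics, $m=0$ zonal, $m>0$ cosine, flat-indexed
$k = l^2 + l + m + 1$. The coefficients are estimated by linear least
squares (QR factorization) from the mesh vertices; on the vertices of a
level-3 subdivided icosahedron (642 near-uniform directions) the design
is excellently conditioned up to $L = 6$ (49 coefficients, the default
feature vector), and a unit sphere yields exactly
$c_{00} = 2\sqrt{\pi}$, everything else zero.

This single-channel radial flavour was chosen over the three-channel
(x, y, z) parameterization: it is exact for star-shaped bones, needs no
correspondence optimization, and gives one real number per basis
function — matching per-coefficient box-plots, coefficient-wise ANOVA
and classifier features directly. The price is that genuinely
non-star-shaped anatomy is out of scope; `parameterize()` rejects such
meshes rather than silently folding the surface.

Degree-1 terms deserve a note: to first order a degree-1 radius
perturbation translates the surface rather than deforming it, and
`parameterize()` re-centres every mesh at its vertex centroid, which
absorbs exactly that content. Degree-1 coefficients are therefore not
identifiable shape parameters in this representation, and the synthetic
generator draws them as exactly zero. With that convention the whole
mesh pipeline reproduces generating coefficients to machine precision,
and fits of analytically sampled radius fields recover them to better
than $10^{-6}$.

### Model order by MDL

`select_order_mdl()` scores every degree $0 \le L \le L_{max}$ with the
regression form of the minimum description length,

$$\mathrm{MDL}(L) = \frac{N}{2}\ln\frac{RSS_L}{N} +
  \frac{(L+1)^2}{2}\ln N,$$

taking the smallest minimizing degree, and short-circuiting to the
smallest exact-fitting degree when $RSS$ is numerically zero (the
likelihood term is unbounded below there). On noiseless generated
shapes this recovers the generating degree via the short-circuit; with
radius noise of SD 0.01 on 642 samples it recovers a generating degree
of 3 in 20/20 seeded replicates.

## Pose normalization

Landmarks a, b, c define the canonical frame in three rigid steps:
rotate the landmark plane onto $z = 0$, translate c to the origin, then
fix the direction of a. Two design points matter:

* **Oriented normal.** Step 1 rotates the *oriented* plane normal
  $n = (b-a)\times(c-a)$ onto $+\hat z$ (rotation angle in $[0,\pi]$).
  Aligning whichever normal sign happens to have positive $z$ would be
  cheaper, but it lands half of all starting orientations upside-down:
  two copies of one bone differing only by a rigid motion would
  normalize to mirror-different frames. The oriented convention is what
  makes normalization rigidly invariant to $10^{-9}$, which is the
  contract everything downstream relies on. (`plane_angle()` still
  reports the unsigned angle between the planes, which is the natural
  measurement quantity.)
* **Step 3 modes.** The default `in_plane` mode rotates about $\hat z$
  so that a lands on the $+x$ half-axis. This preserves the landmark
  plane, yields idempotence (normalizing twice is the identity) and
  removes the last rotational degree of freedom. The alternative
  `literal_x` mode rotates about $\hat x$ by the angle between $\hat x$
  and a. After steps 1–2 the configuration retains exactly one free
  azimuth about $\hat z$, and a rotation about $\hat x$ cannot remove
  it — so `literal_x` defines no canonical frame and is *not* rigidly
  invariant. It is kept, clearly flagged, because the textual
  description of this step in the anatomical literature reads that way;
  the suite asserts its determinism and rigidity, and documents the
  invariance failure rather than papering over it.

Scaling is never applied: bone size is biologically meaningful here and
deliberately flows into the $l=0$ coefficient.

## The synthetic population

`default_bone_classes()` defines four classes at generating degree
$L = 4$ (25 coefficients):

* mean radii 14, 12, 10, 9 mm (calcaneus > talus > cuboid > navicular),
  i.e. $c_{00} = 2\sqrt{\pi}\,\bar r$;
* per class, 5–7 degree-2..4 coefficients offset by 0.7–2.0 mm against
  a common inter-subject SD of 0.2 mm — at least 3 SDs of separation,
  emulating the near-perfect separability of real tarsal bones;
* inter-subject variation: Gaussian per coefficient, SD 1.0 mm on the
  size term, 0.2 on degrees ≥ 2, zero on degree 1 (see above);
* three landmark patches per class, painted as 10° geodesic caps around
  pairwise non-parallel directions; the true landmark is the patch
  vertex extremal along the patch direction;
* 15 right plus 15 left samples per class; each left sample is the
  mirror (x → −x, winding flipped) of its *own* independent draw, so
  sides share a class mean without subject-level pairing, as in a
  cohort where left and right feet come from different subjects. A left
  sample's stored true coefficients are the exact reflected expansion
  (cosine harmonics × $(-1)^m$, sine × $(-1)^{m+1}$).

Draws whose radius function is not strictly positive are redrawn up to
100 times and then fail loudly, rather than silently truncating the
distribution (with the default parameters a rejection is essentially
impossible; the guard exists for user-supplied class specs).

What the generator does *not* emulate: anatomically faithful tarsal
geometry (articular facets, tuberosities), non-star-shaped regions,
scanner artefacts, partial-volume effects, or female anatomy. Passing
tests therefore demonstrate the correctness of the machinery and the
statistical design, not clinical performance.

## Segmentation and voxelization choices

* Contrast enhancement is a percentile-clipped (1/99 by default) linear
  rescale onto [0, 1]: deterministic, monotone, parameter-light.
* Region growing uses a fixed band around the *seed* intensity with
  4-connectivity, which is traversal-order independent and therefore
  exactly checkable against a brute-force flood fill (the suite does
  this on 50 random slices, with exact mask equality). An adaptive
  running-mean criterion was rejected precisely because its result
  depends on visit order.
* Slice-to-slice propagation is gated on **raw** intensity continuity:
  per-slice enhancement rescales even a bone-free slice onto [0, 1], so
  an enhanced-scale criterion alone would happily segment noise beyond
  the bone ends (observed as contour rings several mm off the surface).
  The propagated seed must keep its raw value inside the starting
  slice's equivalent raw band.
* `voxelize()` aligns the grid to the world lattice (voxel centres at
  integer multiples of the spacing), like a scanner field of view,
  instead of deriving the grid from the object's bounding box. An
  object-derived grid pins every phantom to one fixed, highly symmetric
  lattice alignment whose discretization error is atypically large (for
  the radius-5 mm sphere at 1 mm spacing, boundary lattice points make
  the centre-aligned count a full 7% off the continuum volume); with a
  world grid and any generic object position the count sits within a
  percent or two, which is what the volume checks measure.
* Indices are 1-based with voxel-centre sampling; physical coordinate
  = origin + (index − 1) · spacing. This is the idiomatic R convention
  and is applied uniformly from pixels to millimetres.

Surface rebuilding replaces volumetric (Poisson-style) reconstruction
with radial remeshing onto a subdivided icosahedron
(inverse-squared-angular-distance interpolation of the k = 6 nearest
cloud directions, 30° coverage guard). For star-shaped bones this is
exactly the geometry the SPHARM stage needs, is deterministic and
testable (ellipsoid volumes to 3%, own-vertex radii to $10^{-3}$), and
drops the external mesh-processing dependency a GUI tool would bring.
Defaults: `k = 12` neighbours for normal estimation, subdivision level
3 (642 vertices ≫ 49 coefficients), `k_interp = 6`.

## Statistics

* Quartiles use the linear-interpolation convention (R type 7);
  outliers are values beyond 1.5 IQR from the quartiles. On 500
  standard-normal draws the flagged fraction lands in the theoretical
  ~0.7% band.
* The two-way ANOVA is the classical balanced fixed-effects
  decomposition with interaction (bone × coefficient index, subjects as
  replicates), fitted via `stats::aov` and verified in the tests
  against hand-computed sums of squares to $10^{-10}$; unbalanced
  layouts are rejected outright instead of silently choosing a
  sum-of-squares type. Identically constant input reports null effects
  (F = 0) rather than the 0/0 artefact of floating-point SS ratios.
  Type-I error, checked over 1000 null simulations, is calibrated at
  the nominal 5% within Monte-Carlo error. A reduced variant excludes
  the dominant coefficient — operationalized as the largest
  \|mean\| coefficient, in practice always the $l=0$ size term.
* Laterality compares left-group and right-group *mean* coefficient
  vectors by squared Pearson correlation, left models staying in their
  own mirrored frames. The full-vector $r^2$ exceeds 0.98 per class by
  construction (shared class mean, dominant common size term). The
  reduced variant (size term dropped) collapses to ~0.03–0.12 on
  synthetic data: mirrored left shapes carry deterministic sign flips
  on odd-order harmonics, which decorrelate the remaining coefficients.
  On real bones, where left/right asymmetry is anatomical rather than
  an exact reflection, intermediate values are expected — the synthetic
  result brackets the mechanism, not the anatomy.

## Classification

The feature matrix is 120 × 49 (4 bones × 15 subjects × 2 sides, all
coefficients of the L = 6 fit). The cross-validation harness is
implemented in-package — stratified fold assignment, pooled confusion
over folds (one rate over all samples, not a per-fold average),
one-vs-rest sensitivity/specificity with undefined cells reported as
`NA`, and a tree-count sweep over {10, 20, 40, 80, 160} on shared
folds with ties resolved to the smaller ensemble — while the forest
itself is `randomForest`. Every stochastic choice is seeded, so a
report is bit-reproducible. On the default population all ensemble
sizes classify essentially perfectly (misclassification 0% over 5 fold
seeds, all sensitivities and specificities 1.0): the designed analog
of near-perfect tarsal recognition, again a statement about the
separation built into the generator, not about clinical data.

## Reproducibility

`run_pipeline()` derives every stage seed from one global seed, writes
all artifacts (coefficient tables, per-group statistics, mean-shape
surfaces as ASCII PLY, laterality/ANOVA/classifier reports as JSON)
into the configured directory, and records their MD5 hashes in a run
manifest. Two runs with the same configuration produce hash-identical
artifacts; the suite asserts this. Aborted runs are simply re-run from
scratch — at the default problem size (120 bones of 642 vertices, the
scale used throughout the analysis scripts and tests) the whole
experiment takes a few seconds, so checkpoint/resume machinery would
be complexity without benefit.

## Known limitations

* Star-shaped surfaces only; concave articular overhangs that break
  radial single-valuedness are rejected, not approximated.
* Landmarks require labelled patches (from the generator, or user
  annotation in real-data modes); the package does not recognize
  anatomy in unlabelled geometry — that is exactly the part expert
  operators contribute in practice.
* The ANOVA ignores within-subject correlation between coefficients,
  as is conventional for this design.
* `literal_x` pose mode defines no canonical frame (see above).
* Synthetic realism is statistical, not anatomical.
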