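---
title: "Surface-based multimodal detection of focal cortical dysplasia: methods"
author: "fcdsurf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-based multimodal detection of focal cortical dysplasia: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Focal cortical dysplasia (FCD) type II is a malformation of cortical
development and a leading cause of drug-resistant focal epilepsy. Its
radiological signature is subtle: local cortical thickening or thinning,
blurring of the gray-matter/white-matter (GM/WM) boundary, FLAIR
hyperintensity, glucose hypometabolism on PET, and asymmetry relative to the
homotopic (mirror-corresponding) cortex of the opposite hemisphere. `fcdsurf`
implements an automated, surface-based detection pipeline: multimodal
features are sampled per vertex on reconstructed cortical meshes, normalized
in two z-scoring stages against a control cohort, classified by a principal
component reduction followed by a feedforward neural network, and converted
into candidate lesion clusters that are evaluated at patient level against
lesion or resection labels.

The package consumes the standard outputs of a surface-reconstruction
pipeline (white/pial meshes with 1:1 vertex correspondence, co-registered
T1/FLAIR/PET volumes, vertex labels, a homotopic left-right vertex
correspondence) and ships a synthetic cohort generator so that every stage -
and the end-to-end pipeline - runs and is testable without any clinical
data.

## Feature set

Per hemisphere and vertex, 40 feature maps are computed:

* **Morphology.** Cortical thickness (Euclidean distance between
  corresponding white and pial vertices); GM/WM intensity contrast
  (T1 sampled 30% through the cortical ribbon divided by T1 sampled 1 mm
  below the GM/WM boundary along the inward white-surface normal); mean
  curvature of the white surface (cotangent-Laplacian estimator of the
  mean-curvature normal; with outward normals, sulcal concavities are
  positive and convex regions negative; a sphere of radius R gives -1/R);
  sulcal depth (geodesic distance to the nearest gyral-crown vertex); local
  cortical deformation (area-weighted mean of |Gaussian curvature|, by
  angle deficit, over a 25 mm geodesic disc; 1/R^2 on a sphere).
* **Intensity.** FLAIR sampled at the GM/WM boundary, at 25/50/75% cortical
  depth, and 0.5 mm and 1 mm below the boundary; the boundary-minus-deep
  difference (the vertical gradient) falls when the interface is blurred.
* **Metabolism.** PET sampled at mid-cortex and divided by the
  area-weighted whole-cortex mean uptake over both hemispheres, making the
  map invariant to global scanner scaling; lesions fall below 1.
* **Doughnut contrast.** For GM/WM contrast, thickness and each FLAIR
  depth: the area-weighted mean over a 6 mm geodesic disc minus the mean
  over the surrounding 6-12 mm annulus, with distances measured on the
  inflated surface so that disc radii are not distorted by folding.
* **Interhemispheric asymmetry.** For every base and doughnut feature,
  `2(L - R)/(L + R)` at homotopic vertex pairs; the PET asymmetry feature
  is the asymmetry of the normalized PET map. The right-hemisphere map is
  the negated left map carried through the correspondence.

Geodesic distances are shortest paths on the mesh edge graph (Dijkstra).
This slightly overestimates exact polyhedral geodesics - by well under the
mesh edge length at the 6 mm and 25 mm scales used here - and is in exchange
simple and exactly checkable against an independent graph library.

Gyral crowns (for sulcal depth) are defined as pial vertices lying within
0.5 mm of a smoothed outer envelope: the pial coordinates are diffused for
200 neighbor-averaging passes, the envelope is rescaled about its area
centroid until it encloses the original surface, and point-to-triangle
distances select the touching vertices. On a plane the envelope is the
plane itself, so every vertex is a crown and depth is identically zero.

## Smoothing and normalization

Before classification every feature map is smoothed with a Gaussian surface
kernel of 10 mm full width at half maximum (FWHM). Smoothing is explicit
Euler integration of the heat equation with the cotangent Laplace-Beltrami
operator and barycentric vertex masses; for diffusion time T the impulse
response approaches a geodesic Gaussian with per-axis variance 2T, so the
step count is calibrated from `sigma^2 = FWHM^2/(8 ln 2)`. Negative
cotangent weights (obtuse triangles) are clamped to zero, keeping every
update a convex combination: smoothing can never overshoot the input
extrema, and the symmetric edge weights conserve the area-weighted mean to
machine precision. On folded cortex the realized FWHM is approximate; the
calibration is exact in the flat limit and is verified on an equilateral
planar lattice (half-height at 5 mm within 15%).

Normalization then proceeds in the pinned order: within-subject z-scoring
(each feature centered and scaled over all valid vertices of both
hemispheres, population-n convention) followed by between-subject z-scoring
(per-vertex mean and SD over the control cohort, same convention; vertices
with fewer than two contributing controls or SD below 1e-6 are masked, not
inflated). The population-SD convention for both stages is pinned by unit
tests ([1,2,3] maps to +-1.2247; control values {0,1,2} with a subject value
of 3 map to z = 2.449). Masked (`NA`) vertices are carried explicitly and
excluded from every statistic, training row and cluster.

## Classifier

Training vertices come from the patients only: lesion-label vertices are the
positive class, and their homotopic counterparts on the contralateral
(healthy) hemisphere the negative class - equal class sizes by
construction, so no reweighting is needed. Row pairs with any masked
feature are dropped symmetrically.

The feature matrix is reduced by PCA to the smallest number of components
reaching 95% cumulative explained variance, then classified by a
fully-connected feedforward network (default one hidden layer of 10
sigmoid units, sigmoid output) trained by full-batch gradient descent with
momentum on the cross-entropy loss. Rows are put into a canonical
(lexicographic) order before the seeded 70/15/15 train/validation/test
split, which makes training bit-reproducible given the seed and exactly
invariant to the order in which rows are presented. Early stopping monitors
the validation loss with a patience of 30 epochs.

Evaluation uses subject-level k-fold cross-validation (k = 5, re-randomized
partitions per iteration). Folds are assigned at subject level because
vertex-level folds would leak the strong within-subject spatial correlation
between training and test sets. Inside each fold the between-subject
normalization is refit on the training controls only, and the probability
threshold is chosen on the training subjects by maximizing Youden's J
(patient detection rate minus control false-positive rate; ties go to the
higher threshold). The 100-iteration default of the full protocol is
configurable downward (the reference validation uses 5 iterations, a
deliberate desk-scale choice).

Probability maps are thresholded and connected components on the mesh
adjacency graph become detection clusters, ranked by peak probability with
ties broken by area (a well-separated network saturates its sigmoid, so
peak ties are common). Clusters smaller than 150 mm^2 are discarded: this
is about half the area of the smallest lesion the reference conditions
plant (a 10 mm geodesic disc, ~314 mm^2) and removes the small spurious
islands produced by control-normalization noise in held-out subjects. The
threshold grid extends to 0.99 for the same saturation reason. A patient
counts as detected when the major (top-ranked) cluster shares at least one
vertex with the lesion (or resection) label; a control counts as a false
positive when any cluster survives. Sensitivity, specificity, accuracy,
Cohen's kappa (with the conventional slight/fair/moderate/substantial/
almost-perfect bands, boundaries inclusive to the lower band), the
uncorrected Pearson chi-square, Fisher's exact test and the Mann-Whitney U
(normal approximation with tie correction) make up the evaluation module.

## Synthetic cohort

The generator emulates the pipeline's inputs, not MRI physics:

* **Geometry.** The pial surface is an icosphere (subdivision 4, 2562
  vertices) of mean radius 45 mm deformed radially by a
  product-of-sinusoids folding field (amplitude 4 mm, angular frequency 10,
  fold wavelength ~28 mm) with a subject-specific random orientation and
  phase. The white surface is the pial offset inward **radially** by the
  3 mm baseline thickness. The radial offset is a deliberate design choice:
  it keeps the phantom star-shaped (self-intersection is impossible at any
  fold amplitude), makes every volume compartment a closed-form function of
  the voxel direction, and makes the thickness feature recover the baseline
  exactly. The right hemisphere is the exact mirror image of the left, so
  the identity map is an exact homotopic correspondence - standing in for
  symmetric interhemispheric registration, which is out of scope. A smooth
  radial displacement field (SD 0.15 mm, independent per hemisphere and per
  surface) emulates surface-reconstruction error; without it the mirror
  construction would make every morphological asymmetry feature identically
  zero, which no real cohort exhibits. Setting it to zero recovers an
  exactly mirror-symmetric subject, which is how the asymmetry-vanishing
  invariant is tested.
* **Volumes.** 1 mm isotropic T1 (WM/GM/CSF = 120/80/30), FLAIR
  (70/100/20) and PET (40/100/10) filled per voxel from the analytic
  compartments, plus i.i.d. Gaussian noise (SD 5 per modality) - chosen to
  give tissue-contrast-to-noise ratios of roughly 8, in the range of
  clinical 3 T imaging after interpolation.
* **Lesions.** A geodesic disc of radius 10 mm on the pial surface.
  Inside it the pial is pushed outward by +1.5 mm; volumes gain the FCD
  signatures within the enclosing angular cap: the T1 interface is blurred
  with a 2 mm Gaussian, FLAIR rises 15% in the ribbon and a 2 mm
  subcortical rind, PET falls 40% in the ribbon. The resection label is the
  lesion disc dilated by a 5 mm geodesic margin. Reference effect sizes
  follow the strong-lesion validation conditions; all are configurable, and
  zero effects produce a patient statistically indistinguishable from a
  control.

What the phantom does *not* model: bias fields, partial-volume structure
beyond trilinear mixing, the transmantle sign, hippocampal pathology (the
control arm is simply lesion-free), registration error between modalities,
and realistic cortical area or curvature distributions. Passing the
end-to-end recovery test therefore demonstrates that the pipeline's stages
compose correctly and recover strong planted effects - not clinical-grade
sensitivity on real data.

## Numerical choices and degenerate inputs

* Meshes must be 2-manifold triangle surfaces; an edge on more than two
  faces, an unreferenced vertex, or a non-positive vertex area is a
  construction-time error. Boundary vertices get `NA` curvature.
* Trilinear volume sampling is exact for affine intensity fields;
  out-of-bounds samples become masked `NA`, never clamped.
* The asymmetry index masks vertices where `|L + R| < 1e-9`.
* PCA drops constant columns with a warning; `retained_variance = 1` keeps
  the full rank.
* All randomness (fold assignment, network initialization, phantom noise,
  lesion placement) derives from explicit seeds through one helper, and
  every generator output records its seed in the manifest; identical
  seed and configuration reproduce manifests, fold assignments and trained
  weights bit-for-bit.
* Reference problem sizes used by the validation suite: subdivision-4
  hemispheres (2562 vertices) for the 10-patient/10-control recovery run
  with 5-fold cross-validation at 5 iterations, and subdivision-3
  hemispheres of radius 30 mm for the effect-size monotonicity sweep (two
  seeds per level). These sizes are the package's reference conditions for
  desk-scale validation.

## Known limitations

* FWHM calibration assumes locally flat geometry; on strongly curved
  cortex the realized kernel is slightly anisotropic.
* Edge-graph geodesics overestimate true geodesics by a resolution-dependent
  factor (empirically < 5% on the meshes used here).
* The crown-vertex rule depends on the smoothing/rescaling heuristic for
  the outer envelope; it is configurable (`eps`, iteration count) and its
  adequacy is verified only on synthetic folds.
* The classifier's operating point (threshold grid, minimal cluster area)
  was designed for saturated, well-separated probability maps; poorly
  separable cohorts may need a finer grid.
* The homotopic correspondence is consumed as-is; no interhemispheric
  registration is performed.
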