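---
title: "Ocular MRI biometry: segmentation model, phantom design, and statistical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ocular MRI biometry: segmentation model, phantom design, and statistical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(oculometry)
```

## What this package computes

`oculometry` implements an end-to-end analysis for population studies of eye
shape on T2-weighted MRI: automated six-region segmentation of both eyes
(posterior segment, lens, and anterior chamber, left and right), 3D biometry
in each eye's own anatomic coordinate system, sphericity-based shape
classification, and the cohort statistics that relate these measurements to
spherical-equivalent refractive error. Because no public orbital-MRI cohort
with ground-truth segmentations exists, the package ships a first-class
synthetic phantom generator that emulates such a cohort, so every stage is
testable end to end.

## The segmentation model

Each scan is segmented by multiplying two independent per-voxel
class-probability maps and taking the per-voxel argmax:

1. **Multi-atlas registration.** Every labelled atlas is registered to the
   target with an affine transform: initialization by intensity-moment
   matching (centroid and second moments of the bright ocular fluid above an
   intensity threshold), then multi-resolution Nelder–Mead refinement of the
   full 12-parameter affine under a mean-squared-error metric (downsampling
   factors 4 and 2). Atlas labels are resampled into target space by
   trilinear interpolation of their one-hot encoding (soft labels;
   nearest-neighbour is available), and the warped label sets are fused by
   per-voxel class frequency, normalized to sum to one. Registrations whose
   bright-voxel overlap falls below a threshold are flagged as diverged and
   excluded from fusion with a warning.
2. **Random-forest voxel classification.** A probability forest (100 trees,
   `mtry = 6`, minimal node size 5, each tree bagging half the rows without
   replacement) maps each voxel's 48 scale-space features to a 7-class
   probability vector. The features, per scale
   $\sigma \in \{1.0, 1.6, 4.0\}$ mm: Gaussian-smoothed intensity, the 3
   first-order and 6 second-order Gaussian derivatives (computed in mm units,
   so anisotropic spacing is handled), the gradient magnitude, the Laplacian,
   the three Hessian eigenvalues in ascending order, and the Hessian
   determinant — 16 per scale. The enumerated derivative families alone give
   15 features per scale; the count of 48 is reached by including the
   smoothed intensity itself at each scale, the only natural per-scale
   complement.
3. **Background bias and map product.** The classifier's background
   probability is multiplied by $\beta \in (0, 1]$ and the vector
   renormalized, so interior eye voxels that locally resemble background are
   not over-ruled. The atlas map gets a small additive floor
   $\varepsilon = 0.01$ before the product, so an atlas zero cannot
   annihilate strong classifier evidence. Ties in the product argmax break
   deterministically toward the lower class code (background first).

**Choice of $\beta$.** The down-weighting strength is not identifiable from
first principles, so it is exposed in `seg_config()`. The default is 0.9: in
development experiments on small phantom cohorts, aggressive values
($\beta \le 0.5$) inflated lens false positives in the orbital tissue —
the map product already protects interior voxels, so only a mild bias is
needed. With $\beta = 1$ the mechanism is disabled.

**Training sampling.** The forest is trained on class-balanced voxel samples
(default 800 per class per training subject, capped at 20 000), with half of
each class's rows drawn from label-boundary voxels (a voxel whose
6-neighbourhood contains another class). Segmentation errors concentrate at
boundaries, so enriching them makes small samples far more informative than
uniform sampling; rare classes such as the ~84-voxel lens are oversampled
with replacement to keep priors flat. Features are extracted on a bounding
box around the labelled anatomy plus the full feature-support margin, which
leaves the feature values identical to a whole-volume computation while
saving most of the convolution cost. At test time the classifier is
evaluated only where the Gaussian-smoothed fused non-background probability
exceeds $10^{-4}$ (a margin of several voxels around the atlas-supported
region); outside it the label is background.

Left and right eyes are distinct classes throughout. Local features carry no
laterality, so the classifier divides each tissue's probability between its
left and right variants; the atlas term of the product resolves the side.

**Evaluation.** Segmentation quality is the Dice similarity coefficient
$2|A \cap B| / (|A| + |B|)$ per class (1 = perfect overlap; two empty masks
score 1 by convention), reported as mean ± SD over all test subjects in all
folds of a seeded, group-stratified k-fold cross-validation in which the
training split supplies both the atlases and the classifier's training
voxels. Per target, a deterministic evenly spaced subset of at most 12
training atlases is fused — fusion quality saturates well before the full
split is used, and registrations dominate the runtime.

## Anatomic axes and biometry

For each eye, the anterior–posterior (AP) axis is the unit vector from the
posterior-segment centroid to the lens centroid (centroids are unweighted
means of voxel centres, in world mm). The superior–inferior (SI) axis is
orthogonal to the plane spanned by the AP axis and the right-PS-to-left-PS
direction, with its sign fixed toward the world superior direction (the
construction defines it only up to sign). The left–right (LR) axis completes
the right-handed frame. Height and width are chords of the PS mask along SI
and LR through the PS centroid; along the AP line through the PS centroid
the package measures PS length, lens thickness, anterior chamber depth, and
axial length as the extent of the union of the three compartments. The AP
measurement line is anchored at the PS centroid (a choice; no anatomical
landmark is prescribed for it). Reporting lens thickness separately keeps the
axial-length decomposition explicit:
`al_mri = ps_length + lens_thickness + acd_mri` for contiguous compartments.

Chords are measured sub-voxel: the distance between the first and last
crossings of the 0.5 level of the trilinearly interpolated mask, sampled at
a quarter of the smallest voxel spacing. Volumes are voxel counts times the
voxel volume.

Sphericity is $S = \text{transverse}^2 / \text{AL}^2 - 1$, with
$S > 0.005$ oblate, $S < -0.005$ prolate, and the closed interval in between
spherical (boundary values are spherical). Following the printed formulas,
*horizontal* sphericity is computed from the *height* and *vertical*
sphericity from the *width*; this reads as swapped relative to anatomical
intuition, and the same quantities are elsewhere labelled "prolateness"
although positive values classify as oblate. The package implements the
formulas exactly as printed and offers `swap_sphericity_labels` for the
alternative reading; the naming question itself cannot be resolved from the
available material.

### Measurement accuracy and its limits

On crisp voxel-centre label maps at 1 mm, a chord's 0.5-crossing has an
irreducible error of up to half a voxel per side, and the error is
*coherent* when a pole of the (near-axis-aligned) surface is locally flat
relative to the grid — no estimator can recover what binarization at voxel
centres has discarded. Rendered-then-measured phantom lengths are therefore
validated at ±1 voxel, and PS volumes at ±3%. Two consequences are worth
stating plainly:

- Lens and anterior-chamber voxel-count volumes quantize at the 20–30% level
  (they are only ~3 voxels thick); no tolerance tighter than that is honest
  at 1 mm, and they are excluded from percentage-level volume checks.
- Sphericity to ±0.01 requires chords accurate to ~0.1 mm. The geometry
  oracle suite therefore runs on anti-aliased analytic ellipsoid masks
  (`analytic_ellipsoid_mask()`, fractional voxel coverage), where that
  information exists. For sphericity the oracle calls
  `chord_length(presmooth_sigma = 1)`: pre-smoothing biases every chord of a
  convex body slightly inward (a curvature effect of order
  $\sigma^2 \kappa$), but the bias is common-mode across directions and
  cancels in the squared-ratio, leaving sphericity accurate to well under
  0.01. On population data the corresponding statement is that per-eye
  sphericity at 1 mm is noisy at the few-hundredths level and averages out
  across a cohort.

Rotation/translation equivariance of the axes construction is exact (it is
built from centroids and cross products in world coordinates); equivariance
of the full measurement chain is validated on the analytic masks under
random rigid poses at the same tolerances.

## The phantom generator

The phantom is a three-compartment geometric eye, not a biophysical one —
sufficient because the downstream pipeline measures exactly these three
compartments:

- posterior segment: an ellipsoid with semi-axes (PS length, height,
  width)/2 along the eye's AP/SI/LR axes;
- lens: a spheroid (equatorial-to-axial aspect 2.43, so the group-mean lens
  volume of 84 mm³ corresponds to a 3.0 mm thickness) stacked on the PS's
  anterior pole;
- anterior chamber: a spherical cap (sphere radius 9.5 mm) anterior to the
  lens whose central axial extent equals the anterior chamber depth.

Both eyes share the subject's dimensions; centres sit ±28 mm from the
midline (jitter SD 1 mm) with a small random globe rotation (SD 2°). The
rendered grid is a 96 × 96 × 64 mm orbital crop at 1 mm isotropic voxels.
Intensities mimic T2 fat-suppressed contrast: vitreous 1000, aqueous 950,
lens 250, orbital tissue 350 (a sphere of radius 18 mm around each globe),
air 50, plus additive Gaussian noise (SD 25 by default; Gaussian motion blur
optional). Labels are assigned at voxel centres with precedence
lens > anterior chamber > posterior segment.

Geometry is sampled from group-conditional normals calibrated to published
group means and SDs for 10-year-olds — PS length 17.7/16.9/16.2 mm, height
24.1/23.5/22.9 mm, width 24.0/23.7/23.3 mm for myopia/emmetropia/hyperopia,
with group proportions 12.3%/80.2%/7.5%. Spherical equivalent is drawn from
truncated group-conditional normals (bands: myopia ≤ −0.5 D, hyperopia
≥ +2.0 D). Within groups, dimensions couple to SE (negative loading: more
myopic, longer eye) and to a single shared latent size factor that also
loads on body height and birth weight — a deliberately simple stand-in for
the joint covariance, which is not available to calibrate against. Axial
growth rate is emulated as 0.21 ± 0.09 mm/y with a configurable SE link; it
is a covariate only. Anterior-chamber depth is derived per group as
AL − PS length − lens thickness with AL tied to the published biometry
values minus the 0.18 mm modality offset; with the fixed 9.5 mm cap radius
this reproduces the emmetropic AC volume (~239 vs 240 mm³) but undershoots
the hyperopic one (~196 vs 220 mm³) — the geometry is over-constrained, and
linear dimensions take precedence because they drive every downstream
statistic.

Two known infidelities matter for interpretation. First, a pole-to-pole
ellipsoid with the published linear dimensions has a volume of ~4900 mm³,
smaller than the published PS volume of 6350 mm³ (a real vitreous chamber is
closer to a truncated globe); phantom volumes are therefore internally
consistent but not calibrated to published volumes, and printed volume
values enter only through the report stage's reference tables. Second, the
phantom's contrast and geometry are far cleaner than real data: no motion
artifacts by default, no intensity inhomogeneity, no corneal/scleral detail
(invisible in the emulated protocol anyway). Passing segmentation tests on
phantoms demonstrates the pipeline's mechanics — registration, fusion,
feature extraction, classification, the map product, and the evaluation
plumbing — not clinical-grade accuracy on real scans; published Dice values
act as *floors* on phantom data for exactly this reason.

**Optical-biometry emulation.** The biometer's axial length is the true
geometric axial length plus 0.18 mm (optical biometry measures to the
retinal pigment epithelium, so it reads longer than the MRI fluid boundary)
plus Gaussian noise with SD 0.454 mm, the value that reproduces published
limits of agreement of (−0.71, 1.07) mm; the whole paired-difference noise
is carried on the biometry side. Sphere and cylinder are drawn consistently
with the subject's true SE; pupil diameter is sampled so 5% of subjects fail
the <6.0 mm cycloplegia criterion, and 14.4% of subjects are flagged as
low-quality scans.

## Statistical stage

- Spherical equivalent: sphere + cylinder/2 (D). Groups: myopia ≤ −0.5 D,
  hyperopia ≥ +2.0 D, emmetropia in between; boundary values belong to
  myopia/hyperopia per the defining inequalities.
- Exclusions: failed scan quality, then pupil < 6.0 mm among the remainder
  (a 6.0 mm pupil is retained); complete-case analysis per table.
- Pearson correlation with the two-sided t-transform p value; one-way ANOVA
  for continuous group differences and Pearson chi-square for shape-class
  proportions. No multiple-testing correction is applied anywhere (noted in
  the report footer).
- Restricted cubic splines: truncated-power basis constrained to linearity
  beyond the boundary knots, knots at the 10th/50th/90th percentiles for 3
  knots, normalized by the squared knot range, fitted by OLS with pointwise
  confidence bands. The basis contains linear functions exactly.
- Bland–Altman: per-pair differences, mean difference, and
  mean ± 1.96 SD limits of agreement.
- Analyses default to the right eye; averaging both eyes is a config switch
  (the per-subject convention is not otherwise determined).

The report stage renders descriptives (with the total eye volume rounded to
10 mm³), the correlation matrix with significance stars, group means with
ANOVA p values, pairwise group differences, and per-group shape percentages.
Reference tables of the published group and cohort means
(`reference_group_biometry()`, `reference_cohort_biometry()`) are provided
as report-stage inputs; feeding them through `group_differences()`
reproduces the published deltas (e.g. 470 mm³ PS-volume difference between
myopic and emmetropic eyes).

On synthetic cohorts the statistics are validated as *sign and coarse
magnitude* recovery (e.g. SE vs PS length strongly negative) — the
generator's couplings are calibrated to published correlations, so treating
exact correlation values as evidence would be circular.

## Problem sizes and numerical choices

The in-package validation uses deliberately desk-scale problems chosen as
adequate for their purpose: unit tests run on a reduced 80 × 64 × 48 mm
orbital FOV with 6–9 subjects; the segmentation cross-validation condition
is 30 phantoms at the full 96 × 96 × 64 grid with 3 folds; the
method-comparison cohort is 2963 subjects (records only, no rendering); the
oracle ellipsoids use ~50³ grids. Numerical details of record: derivative
kernels are sampled Gaussian derivatives truncated at 3.5σ and normalized to
exact polynomial responses (so a ramp's derivative is exact); Hessian
eigenvalues use the closed-form trigonometric solution for symmetric 3 × 3
matrices; registration divergence is declared below 50% bright-voxel
overlap; random-forest training, fold assignment, and all sampling are
seeded, and ranger runs single-threaded for bit-reproducibility.

## Known limitations

- The phantom cannot certify performance on real scans (see above); in
  particular real-data failure modes — motion, braces artifacts, intensity
  bias fields — are out of scope.
- Sub-voxel biometry from crisp 1 mm labels carries ±0.5 mm/side worst-case
  quantization; per-eye sphericity is meaningful at the population level,
  not per subject.
- The generator's covariate structure is a single latent factor; it
  approximates, but cannot match, the unavailable joint covariance of body
  size and ocular dimensions.
- Deformable registration is not implemented (the affine family suffices
  for ellipsoidal anatomy and keeps runs desk-scale); the configuration
  exposes the registration family so a deformable stage could be added
  behind the same interface.
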