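# oculometry

Eye size and shape from orbital MRI, end to end: automated six-region
segmentation of both eyes, 3D biometry in each eye's anatomic coordinate
system, oblate/prolate shape classification, and the cohort statistics that
relate eye shape to refractive error. The package targets population studies
of myopia in children, where MRI supplies dimensions that optical biometry
cannot (height, width, compartment volumes) — and it ships a synthetic
orbital-phantom generator so the whole pipeline runs and validates without
any external data.

## The methods in brief

**Segmentation** combines two per-voxel class-probability maps by
elementwise multiplication and argmax:

- a *multi-atlas* map: labelled atlases are affinely registered to the
  target (intensity-moment initialization, multi-resolution mean-squared
  -error refinement), their labels warped softly into target space and fused
  by per-voxel class frequency;
- a *random-forest* map: 100 trees over 48 Gaussian scale-space features per
  voxel (smoothed intensity, first/second derivatives, gradient magnitude,
  Laplacian, Hessian eigenvalues and determinant at σ = 1.0, 1.6, 4.0 mm),
  with the background probability down-weighted by a bias β before
  renormalization so interior eye voxels are not over-ruled.

Seven classes are used: background plus {posterior segment, lens, anterior
chamber} × {left, right}. Quality is evaluated with per-class Dice overlap
under seeded k-fold cross-validation.

**Biometry**: the anterior–posterior axis joins the vitreous-chamber
centroid to the lens centroid; the superior–inferior axis is orthogonal to
the plane of the AP axis and the inter-eye direction; left–right completes
the right-handed frame. Height and width are sub-voxel chords of the
posterior segment through its centroid; axial length, PS length, lens
thickness and anterior chamber depth are measured along the AP line.
Sphericity S = transverse²/AL² − 1 classifies shape: S > 0.005 oblate,
S < −0.005 prolate, otherwise spherical.

**Statistics**: spherical equivalent (sphere + cylinder/2), refraction
groups (myopia ≤ −0.5 D, hyperopia ≥ +2.0 D), cycloplegia and scan-quality
exclusions, Pearson correlations, ANOVA / chi-square group comparisons,
restricted-cubic-spline regression (3 knots at the 10th/50th/90th
percentiles), Bland–Altman method comparison, and report tables of
descriptives, correlations, group means and shape percentages.

## Worked example

```r
library(oculometry)

# a 6-subject synthetic cohort on a reduced orbital FOV
cfg <- cohort_config(eye_offset_mm = 21, fov_mm = c(80, 64, 48))
set.seed(5)
cohort <- lapply(1:6, function(i) {
  sp <- sample_phantom_spec(cfg, sprintf("S%d", i))
  v <- render_phantom(sp, grid_config(c(80, 64, 48)))
  list(id = sp$subject_id, scan = v$scan, labels = v$labels, group = sp$group)
})

# segmentation cross-validation: train atlases + forest on each training
# split, segment the held-out subjects, score per-class Dice
rep <- cross_validate(cohort, k = 2, config = seg_config(), seed = 3)
tidy(rep)
#> # A tibble: 6 x 4
#>   class      mean_dice sd_dice     n
#>   <chr>          <dbl>   <dbl> <int>
#> 1 ac_left        0.948 0.0574      6
#> 2 ac_right       0.932 0.0847      6
#> 3 lens_left      0.867 0.0333      6
#> 4 lens_right     0.766 0.127       6
#> 5 ps_left        0.996 0.00444     6
#> 6 ps_right       0.997 0.00360     6

# biometry of one subject's label map
measure_biometry(cohort[[1]]$labels, "right")[, c("al_mri", "ps_length",
                                                  "height", "width",
                                                  "sphericity_h", "shape_h")]
#> # A tibble: 1 x 6
#>   al_mri ps_length height width sphericity_h shape_h
#>    <dbl>     <dbl>  <dbl> <dbl>        <dbl> <fct>
#> 1   22.1      16.0   23.0  22.1       0.0921 oblate
```

The Dice table reads as mean ± SD overlap between predicted and true
compartments over all held-out subjects (1 = perfect); the biometry row
gives the eye's axial length and posterior-segment dimensions in mm and its
sphericity — this example eye's transverse dimensions exceed its axial
length, hence oblate. (With only 3 training subjects per fold the lens Dice
is modest; the 30-subject condition in `scripts/acceptance.R` reaches ~0.89.)
Published group means can be pushed through the same report stage:

```r
group_differences(reference_group_biometry())[c(3, 4), ]
#> # A tibble: 2 x 3
#>   variable  myopia_minus_emmetropia myopia_minus_hyperopia
#>   <chr>                       <dbl>                  <dbl>
#> 1 ps_length                   0.800                    1.5
#> 2 ps_volume                 470                      970
```

myopic eyes carry a 470 mm³ (vs emmetropic) and 970 mm³ (vs hyperopic)
larger posterior segment.

A thin CLI wraps the same functions
(`inst/cli/oculometry.R generate|crossval|measure|report|run`).

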