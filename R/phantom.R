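#' Cohort-level configuration for the phantom generator
#'
#' Defines the study conditions emulated by the synthetic orbital-MRI cohort:
#' refraction-group proportions, group-conditional means/SDs of the true ocular
#' geometry, the latent-factor loadings that couple spherical equivalent (SE)
#' and overall body size to eye dimensions, imaging geometry and intensities,
#' and the optical-biometry emulation parameters.
#'
#' Defaults reproduce a population cohort of 10-year-olds: 12.3% myopia and
#' 7.5% hyperopia; group-conditional posterior-segment (PS) length 17.7 / 16.9
#' / 16.2 mm (myopia / emmetropia / hyperopia), height 24.1 / 23.5 / 22.9 mm,
#' width 24.0 / 23.7 / 23.3 mm; optical-biometry axial length exceeding the
#' MRI axial length by `delta_al = 0.18` mm with a paired-difference SD of
#' `al_diff_sd = 0.454` mm (limits of agreement about -0.71 to 1.07 mm).
#'
#' @param group_props Named proportions for `myopia`, `emmetropia`,
#'   `hyperopia`; must sum to 1.
#' @param groups Tibble of group-conditional means/SDs. Columns: `group`,
#'   `se_mean`, `se_sd` (D), `ps_length_*`, `height_*`, `width_*`, `acd_*`
#'   (mm), `lens_volume_*` (mm^3), `cr_*` (mm).
#' @param loadings Named list of `c(size, se)` loading pairs per dimension;
#'   `size` couples to a shared latent body/eye size factor, `se` to the
#'   subject's within-group standardized SE (entering with a negative sign, so
#'   more myopic SE means a larger eye).
#' @param fov_mm,spacing Field of view and voxel spacing (mm) of the rendered
#'   grid; the default 96 x 96 x 64 mm at 1 mm isotropic crops to the orbits.
#' @param eye_offset_mm Lateral distance of each eye centre from the midline.
#' @param eye_center_y,eye_center_z Axial position of the eye centres (mm).
#' @param center_jitter_mm SD of the per-eye centre jitter.
#' @param globe_rotation_sd_deg SD of the small random per-eye rotation.
#' @param lens_aspect Ratio of the lens equatorial to axial semi-axis.
#' @param ac_radius_mm Radius of the sphere whose anterior cap forms the
#'   anterior chamber.
#' @param orbit_radius_mm Radius of the surrounding orbital-tissue sphere.
#' @param intensity Named mean intensities (arbitrary units) mimicking
#'   T2-weighted fat-suppressed contrast: fluid bright, lens dark.
#' @param noise_sd Additive Gaussian intensity noise SD.
#' @param motion_blur_mm Gaussian blur sigma emulating motion (0 = none).
#' @param delta_al Mean optical-biometry minus MRI axial-length offset (mm).
#' @param al_diff_sd SD of the biometry-minus-MRI axial-length difference (mm).
#' @param acd_offset_mm,acd_sd_mm Biometry anterior-chamber-depth offset
#'   (corneal thickness not visible on MRI) and measurement SD.
#' @param cyl_mean,cyl_sd Mean/SD of the (negative) refractive cylinder (D).
#' @param pupil_fail_frac Fraction of subjects with inadequate cycloplegia
#'   (pupil < 6 mm).
#' @param scan_fail_frac Fraction of subjects flagged as low scan quality.
#' @param demo Named list of demographic moments (`age`, `body_height`,
#'   `birth_weight`, `gestational_age`, `al_growth` as `c(mean, sd)`, and
#'   `prop_girls`).
#' @param sd_scale Multiplier on all geometric SDs, jitters, and rotations;
#'   set to 0 for deterministic group-mean phantoms.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(
    group_props = c(myopia = 0.123, emmetropia = 0.802, hyperopia = 0.075),
    groups = default_group_table(),
    loadings = list(ps_length = c(size = 0.45, se = 0.55),
                    height = c(size = 0.55, se = 0.30),
                    width = c(size = 0.60, se = 0.12),
                    acd = c(size = 0.30, se = 0.20),
                    lens_volume = c(size = 0.30, se = 0.10),
                    cr = c(size = 0.30, se = 0.00)),
    fov_mm = c(96, 96, 64), spacing = c(1, 1, 1),
    eye_offset_mm = 28, eye_center_y = -4, eye_center_z = 0,
    center_jitter_mm = 1, globe_rotation_sd_deg = 2,
    lens_aspect = 2.4333, ac_radius_mm = 9.5, orbit_radius_mm = 18,
    intensity = c(vitreous = 1000, aqueous = 950, lens = 250,
                  orbit = 350, air = 50),
    noise_sd = 25, motion_blur_mm = 0,
    delta_al = 0.18, al_diff_sd = 0.454,
    acd_offset_mm = 0.55, acd_sd_mm = 0.1,
    cyl_mean = -0.5, cyl_sd = 0.35,
    pupil_fail_frac = 0.05, scan_fail_frac = 0.144,
    demo = list(age = c(10.1, 0.59), body_height = c(141.7, 6.5),
                birth_weight = c(3434, 564), gestational_age = c(39.8, 1.8),
                al_growth = c(0.21, 0.09), prop_girls = 0.515),
    sd_scale = 1) {
  if (abs(sum(group_props) - 1) > 1e-8)
    abort("`group_props` must sum to 1.")
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  cfg
}

#' @rdname cohort_config
#' @export
default_group_table <- function() {
  tibble::tribble(
    ~group,        ~se_mean, ~se_sd, ~ps_length_mean, ~ps_length_sd,
    ~height_mean, ~height_sd, ~width_mean, ~width_sd, ~acd_mean, ~acd_sd,
    ~lens_volume_mean, ~lens_volume_sd, ~cr_mean, ~cr_sd,
    "myopia",     -1.60, 1.00, 17.7, 0.9, 24.1, 0.9, 24.0, 1.0, 3.05, 0.25,
    88, 10, 7.72, 0.25,
    "emmetropia",  0.74, 0.60, 16.9, 0.7, 23.5, 0.9, 23.7, 0.9, 2.99, 0.25,
    84, 10, 7.79, 0.25,
    "hyperopia",   3.00, 0.80, 16.2, 0.6, 22.9, 0.8, 23.3, 0.9, 2.69, 0.25,
    81, 10, 7.76, 0.25)
}

se_band <- function(group) {
  switch(group,
         myopia = c(-Inf, -0.5),
         emmetropia = c(-0.5 + 1e-9, 2.0 - 1e-9),
         hyperopia = c(2.0, Inf),
         abort(paste0("unknown refraction group: ", group)))
}

# truncated-normal draw by rejection; falls back to clamping after `max_try`
# rejections (with a warning, per the generator's error contract).
rtrunc_norm <- function(mean, sd, lo, hi, max_try = 100L) {
  if (sd <= 0) return(min(max(mean, lo), hi))
  for (i in seq_len(max_try)) {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  warn(sprintf("truncated-normal sampler exceeded %d rejections; clamping",
               max_try))
  min(max(rnorm(1, mean, sd), lo), hi)
}

rotation_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# lens thickness (mm) from lens volume (mm^3) for a spheroidal lens with
# equatorial/axial aspect `aspect`: V = 4/3 pi (t/2)^3 aspect^2
lens_thickness_from_volume <- function(volume, aspect) {
  (volume / (4 / 3 * pi * aspect^2 / 8))^(1 / 3)
}

sample_dim <- function(mean, sd, load, z_size, se_std, sd_scale,
                       what = "dimension") {
  lam_sz <- load[["size"]]; lam_se <- load[["se"]]
  resid <- sqrt(max(0, 1 - lam_sz^2 - lam_se^2))
  n_rej <- 0L
  repeat {
    x <- mean + sd * sd_scale *
      (lam_sz * z_size - lam_se * se_std + resid * rnorm(1))
    if (x > 0) return(x)
    n_rej <- n_rej + 1L
    if (n_rej > 100L) {
      warn(paste0("more than 100 rejections sampling ", what, "; clamping"))
      return(mean * 1e-3)
    }
  }
}

#' Sample the ground-truth geometry of one synthetic subject
#'
#' Draws a refraction group, a true spherical equivalent from the
#' group-conditional (truncated normal) distribution, and the true ocular
#' geometry of both eyes from the configured group-conditional normals,
#' coupled through a shared latent size factor and the subject's SE.
#' With `sd_scale = 0` in the config the spec reproduces the group means
#' exactly.
#'
#' @param config A [cohort_config()].
#' @param subject_id Subject identifier string.
#' @param group Optional fixed refraction group; sampled from
#'   `config$group_props` when `NULL`.
#' @param seed Optional integer seed (otherwise the current RNG stream is
#'   used).
#' @return A list of class `phantom_spec` holding per-eye geometry (ellipsoidal
#'   posterior segment, spheroidal lens, spherical-cap anterior chamber, eye
#'   centre, small globe rotation), the true SE and group, and the rendering
#'   noise settings. See [phantom_truth()] for the implied true biometry.
#' @export
sample_phantom_spec <- function(config = cohort_config(),
                                subject_id = "S0001", group = NULL,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(group)) {
    group <- sample(names(config$group_props), 1, prob = config$group_props)
  }
  g <- config$groups[config$groups$group == group, ]
  if (nrow(g) != 1) abort(paste0("group not in config table: ", group))
  ss <- config$sd_scale

  band <- se_band(group)
  se <- rtrunc_norm(g$se_mean, g$se_sd * ss, band[1], band[2])
  se_std <- if (g$se_sd > 0) (se - g$se_mean) / g$se_sd else 0
  z_size <- rnorm(1)

  ld <- config$loadings
  ps_length <- sample_dim(g$ps_length_mean, g$ps_length_sd, ld$ps_length,
                          z_size, se_std, ss, "PS length")
  height <- sample_dim(g$height_mean, g$height_sd, ld$height,
                       z_size, se_std, ss, "height")
  width <- sample_dim(g$width_mean, g$width_sd, ld$width,
                      z_size, se_std, ss, "width")
  acd <- sample_dim(g$acd_mean, g$acd_sd, ld$acd, z_size, se_std, ss, "ACD")
  lens_volume <- sample_dim(g$lens_volume_mean, g$lens_volume_sd,
                            ld$lens_volume, z_size, se_std, ss, "lens volume")
  cr <- sample_dim(g$cr_mean, g$cr_sd, ld$cr, z_size, se_std, ss,
                   "corneal radius")
  lens_t <- lens_thickness_from_volume(lens_volume, config$lens_aspect)

  make_eye <- function(side) {
    sgn <- if (side == "right") 1 else -1
    center <- c(sgn * config$eye_offset_mm, config$eye_center_y,
                config$eye_center_z) +
      rnorm(3, 0, config$center_jitter_mm * ss)
    angles <- rnorm(3, 0, config$globe_rotation_sd_deg * ss)
    list(side = side, center = center, angles_deg = angles,
         rotation = rotation_matrix(angles),
         ps_semi = c(ap = ps_length / 2, si = height / 2, lr = width / 2),
         lens_semi = c(ap = lens_t / 2,
                       si = lens_t / 2 * config$lens_aspect,
                       lr = lens_t / 2 * config$lens_aspect),
         ac_depth = acd, ac_radius = config$ac_radius_mm)
  }
  eyes_sep <- 2 * config$eye_offset_mm
  if (eyes_sep <= 40)
    abort("eye centres must be separated by more than 40 mm")

  structure(
    list(subject_id = subject_id, group = group, se_true = se,
         z_size = z_size, cr = cr,
         eyes = list(right = make_eye("right"), left = make_eye("left")),
         intensity = config$intensity, orbit_radius = config$orbit_radius_mm,
         noise_sd = config$noise_sd * ss,
         motion_blur_mm = config$motion_blur_mm),
    class = "phantom_spec")
}

#' True biometry implied by a phantom spec
#'
#' @param spec A [sample_phantom_spec()] result.
#' @return A tibble with one row per eye: true PS length, height, width, lens
#'   thickness, anterior chamber depth, axial length (the sum along the AP
#'   axis), and analytic compartment volumes (ellipsoid / spherical cap).
#' @export
phantom_truth <- function(spec) {
  purrr::map_dfr(spec$eyes, function(e) {
    t <- 2 * e$lens_semi[["ap"]]
    h <- e$ac_depth; r <- e$ac_radius
    tibble(
      subject_id = spec$subject_id, side = e$side, group = spec$group,
      se = spec$se_true,
      ps_length = 2 * e$ps_semi[["ap"]],
      height = 2 * e$ps_semi[["si"]],
      width = 2 * e$ps_semi[["lr"]],
      lens_thickness = t, acd = h,
      al = 2 * e$ps_semi[["ap"]] + t + h,
      ps_volume = 4 / 3 * pi * prod(e$ps_semi),
      lens_volume = 4 / 3 * pi * prod(e$lens_semi),
      ac_volume = pi * h^2 * (3 * r - h) / 3)
  })
}

#' Grid settings for phantom rendering
#'
#' @param fov_mm Field of view (mm), default the orbital crop 96 x 96 x 64.
#' @param spacing Voxel spacing (mm), default 1 mm isotropic.
#' @return A list of class `grid_config`.
#' @export
grid_config <- function(fov_mm = c(96, 96, 64), spacing = c(1, 1, 1)) {
  structure(list(fov_mm = fov_mm, spacing = spacing,
                 dim = as.integer(round(fov_mm / spacing))),
            class = "grid_config")
}

eye_reach <- function(e) {
  max(e$ps_semi,
      e$ps_semi[["ap"]] + 2 * e$lens_semi[["ap"]] + e$ac_depth,
      e$lens_semi)
}

#' Render a phantom spec into a scan volume and ground-truth label map
#'
#' Voxelizes the three-compartment geometry (PS ellipsoid, lens spheroid
#' stacked on its anterior pole, anterior-chamber spherical cap anterior to
#' the lens) for both eyes, assigns T2-like intensities (fluid bright, lens
#' dark, orbital tissue mid-low, air dark), and adds Gaussian noise and
#' optional Gaussian motion blur. Voxel labels are assigned at voxel centres
#' with precedence lens > anterior chamber > posterior segment.
#'
#' @param spec A [sample_phantom_spec()] result.
#' @param grid A [grid_config()].
#' @param seed Optional seed for the intensity noise.
#' @return A list with elements `scan` ([scan_volume()]) and `labels`
#'   ([ocular_label_map()]) on the same grid.
#' @export
render_phantom <- function(spec, grid = grid_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dims <- grid$dim
  spacing <- grid$spacing
  origin <- -(dims - 1) * spacing / 2
  codes <- ocular_codebook()

  for (e in spec$eyes) {
    reach <- eye_reach(e)
    if (any(abs(e$center) + reach > grid$fov_mm / 2))
      abort(paste0("eye extends outside the field of view for subject ",
                   spec$subject_id, " (", e$side, ")"))
  }

  labels <- array(0L, dims)
  intens <- array(spec$intensity[["air"]], dims)
  xs <- origin[1] + spacing[1] * (seq_len(dims[1]) - 1)
  ys <- origin[2] + spacing[2] * (seq_len(dims[2]) - 1)
  zs <- origin[3] + spacing[3] * (seq_len(dims[3]) - 1)

  for (e in spec$eyes) {
    right <- e$side == "right"
    code_ps <- if (right) codes[["ps_right"]] else codes[["ps_left"]]
    code_lens <- if (right) codes[["lens_right"]] else codes[["lens_left"]]
    code_ac <- if (right) codes[["ac_right"]] else codes[["ac_left"]]
    reach <- max(eye_reach(e), spec$orbit_radius)

    ix <- which(abs(xs - e$center[1]) <= reach + spacing[1])
    iy <- which(abs(ys - e$center[2]) <= reach + spacing[2])
    iz <- which(abs(zs - e$center[3]) <= reach + spacing[3])
    nb <- c(length(ix), length(iy), length(iz))
    dx <- rep(xs[ix] - e$center[1], times = nb[2] * nb[3])
    dy <- rep(rep(ys[iy] - e$center[2], each = nb[1]), times = nb[3])
    dz <- rep(zs[iz] - e$center[3], each = nb[1] * nb[2])

    # local frame: axis 1 = LR, axis 2 = AP (anterior +), axis 3 = SI
    R <- e$rotation
    l1 <- R[1, 1] * dx + R[2, 1] * dy + R[3, 1] * dz
    l2 <- R[1, 2] * dx + R[2, 2] * dy + R[3, 2] * dz
    l3 <- R[1, 3] * dx + R[2, 3] * dy + R[3, 3] * dz

    ps_ap <- e$ps_semi[["ap"]]
    lt <- 2 * e$lens_semi[["ap"]]
    in_ps <- (l1 / e$ps_semi[["lr"]])^2 + (l2 / ps_ap)^2 +
      (l3 / e$ps_semi[["si"]])^2 <= 1
    lens_c <- ps_ap + lt / 2
    in_lens <- ((l2 - lens_c) / e$lens_semi[["ap"]])^2 +
      (l1 / e$lens_semi[["lr"]])^2 + (l3 / e$lens_semi[["si"]])^2 <= 1
    ac_c <- ps_ap + lt + e$ac_depth - e$ac_radius
    in_ac <- l2 >= ps_ap + lt &
      l1^2 + l3^2 + (l2 - ac_c)^2 <= e$ac_radius^2
    in_orbit <- dx^2 + dy^2 + dz^2 <= spec$orbit_radius^2

    sub_lab <- integer(length(l1))
    sub_lab[in_ps] <- code_ps
    sub_lab[in_ac & sub_lab == 0L] <- code_ac
    sub_lab[in_lens] <- code_lens

    sub_int <- rep(NA_real_, length(l1))
    sub_int[in_orbit] <- spec$intensity[["orbit"]]
    sub_int[sub_lab == code_ps] <- spec$intensity[["vitreous"]]
    sub_int[sub_lab == code_ac] <- spec$intensity[["aqueous"]]
    sub_int[sub_lab == code_lens] <- spec$intensity[["lens"]]

    cur_lab <- labels[ix, iy, iz]
    cur_lab[sub_lab != 0L] <- sub_lab[sub_lab != 0L]
    labels[ix, iy, iz] <- cur_lab
    cur_int <- intens[ix, iy, iz]
    cur_int[!is.na(sub_int)] <- sub_int[!is.na(sub_int)]
    intens[ix, iy, iz] <- cur_int
  }

  if (spec$motion_blur_mm > 0) {
    for (ax in 0:2) {
      k <- gauss_kernel(spec$motion_blur_mm, spacing[ax + 1], order = 0)
      intens <- array(conv_axis_cpp(as.numeric(intens), dims, k, ax), dims)
    }
  }
  if (spec$noise_sd > 0)
    intens <- intens + array(rnorm(prod(dims), 0, spec$noise_sd), dims)

  list(scan = scan_volume(intens, spacing, origin,
                          subject_id = spec$subject_id),
       labels = ocular_label_map(labels, spacing, origin,
                                 subject_id = spec$subject_id))
}

#' Emulate an optical-biometry and refraction record for a phantom subject
#'
#' The biometer axial length is the phantom's true (MRI-geometry) axial length
#' plus a constant offset `delta_al` (optical biometry measures to the retinal
#' pigment epithelium and reads slightly longer than MRI) plus Gaussian noise
#' whose SD calibrates the biometry-vs-MRI limits of agreement. Sphere and
#' cylinder are drawn consistently with the subject's true spherical
#' equivalent; pupil diameter is sampled so a configurable fraction fails the
#' 6.0 mm cycloplegia criterion.
#'
#' @param spec A [sample_phantom_spec()] result.
#' @param config The [cohort_config()] providing offsets and noise SDs.
#' @param delta_al Override for the axial-length offset (mm).
#' @param noise_scale Multiplier on the measurement noise SDs (0 = noiseless).
#' @param seed Optional seed.
#' @return A one-row tibble: `al_biometry`, `cr`, `acd_biometry`, `sphere`,
#'   `cylinder`, `pupil_diameter`, demographics, `al_growth`, and the
#'   pass/fail quality flags.
#' @export
emulate_optical_biometry <- function(spec, config = cohort_config(),
                                     delta_al = config$delta_al,
                                     noise_scale = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  truth <- phantom_truth(spec)
  al_true <- mean(truth$al)
  acd_true <- mean(truth$acd)
  se <- spec$se_true
  d <- config$demo

  cylinder <- -abs(rnorm(1, -config$cyl_mean, config$cyl_sd * noise_scale))
  sphere <- se - cylinder / 2
  fail_pupil <- runif(1) < config$pupil_fail_frac
  pupil <- if (fail_pupil) rtrunc_norm(5.2, 0.3 * noise_scale, 0, 5.99)
           else rtrunc_norm(7.5, 0.6 * noise_scale, 6.0, Inf)
  sex <- if (runif(1) < d$prop_girls) "girl" else "boy"
  z <- spec$z_size
  tibble(
    subject_id = spec$subject_id,
    al_biometry = al_true + delta_al +
      rnorm(1, 0, config$al_diff_sd * noise_scale),
    cr = spec$cr,
    acd_biometry = acd_true + config$acd_offset_mm +
      rnorm(1, 0, config$acd_sd_mm * noise_scale),
    sphere = sphere, cylinder = cylinder,
    pupil_diameter = pupil,
    scan_quality_pass = runif(1) >= config$scan_fail_frac,
    age = rtrunc_norm(d$age[1], d$age[2] * noise_scale, 5, 15),
    sex = sex,
    body_height = d$body_height[1] +
      d$body_height[2] * (0.3 * z + sqrt(1 - 0.3^2) * rnorm(1)),
    birth_weight = d$birth_weight[1] +
      d$birth_weight[2] * (0.25 * z + sqrt(1 - 0.25^2) * rnorm(1)),
    gestational_age = d$gestational_age[1] +
      d$gestational_age[2] * (0.05 * z + sqrt(1 - 0.05^2) * rnorm(1)),
    al_growth = d$al_growth[1] + d$al_growth[2] *
      (-0.4 * (se - 0.74) / 1.30 + sqrt(1 - 0.4^2) * rnorm(1)))
}

sample_subject <- function(config, subject_id, group = NULL) {
  spec <- sample_phantom_spec(config, subject_id = subject_id, group = group)
  truth <- phantom_truth(spec)
  rec <- emulate_optical_biometry(spec, config)
  rec <- dplyr::bind_cols(
    rec,
    tibble(group_true = spec$group, se_true = spec$se_true,
           ps_length_true = truth$ps_length[1], height_true = truth$height[1],
           width_true = truth$width[1], acd_true = mean(truth$acd),
           lens_thickness_true = truth$lens_thickness[1],
           al_mri = mean(truth$al),
           ps_volume_true = truth$ps_volume[1],
           lens_volume_true = truth$lens_volume[1],
           ac_volume_true = truth$ac_volume[1]))
  list(spec = spec, record = rec)
}

#' Sample a cohort of subject records without rendering images
#'
#' Draws `n` phantom specs and their emulated optical-biometry records. This
#' is the fast path for cohort-level statistics (method comparison,
#' correlations, group tests) that do not need voxel data; `al_mri` is the
#' phantom's true geometric axial length, i.e. what an exact MRI measurement
#' would return.
#'
#' @param n Number of subjects.
#' @param config A [cohort_config()].
#' @param seed Integer seed (required for reproducibility).
#' @return A tibble with one row per subject: emulated biometry/refraction
#'   plus the generative ground truth (`*_true`, `al_mri`, `group_true`).
#' @export
sample_cohort_records <- function(n, config = cohort_config(), seed = 1L) {
  set.seed(seed)
  if (n == 0) return(sample_subject(config, "S0")$record[0, ])
  purrr::map_dfr(seq_len(n), function(i) {
    sample_subject(config, sprintf("S%04d", i))$record
  })
}

#' Generate and write a full synthetic cohort
#'
#' Samples `n` subjects, renders their scan volumes and ground-truth label
#' maps, writes them as NIfTI-1 pairs plus one cohort CSV, and returns (and
#' writes) a manifest recording the seed, configuration hash, and file list.
#'
#' @param n Number of subjects.
#' @param out_dir Output directory (created if needed).
#' @param config A [cohort_config()].
#' @param grid A [grid_config()].
#' @param seed Integer seed.
#' @param render Write NIfTI volumes? If `FALSE` only the CSV and manifest are
#'   written.
#' @return The manifest, invisibly, as a list (`seed`, `config_hash`, `n`,
#'   `files`, `subjects`).
#' @export
generate_cohort <- function(n, out_dir, config = cohort_config(),
                            grid = grid_config(), seed = 1L, render = TRUE) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create output directory: ", out_dir))
  }
  if (file.access(out_dir, mode = 2) != 0)
    abort(paste0("output directory not writable: ", out_dir))
  set.seed(seed)
  files <- character()
  records <- vector("list", n)
  ids <- if (n > 0) sprintf("S%04d", seq_len(n)) else character()
  for (i in seq_len(n)) {
    sub <- sample_subject(config, ids[i])
    records[[i]] <- sub$record
    if (render) {
      vols <- render_phantom(sub$spec, grid)
      scan_path <- file.path(out_dir, paste0(ids[i], "_scan.nii.gz"))
      lab_path <- file.path(out_dir, paste0(ids[i], "_labels.nii.gz"))
      write_scan(vols$scan, scan_path)
      write_labels(vols$labels, lab_path, sidecar = i == 1L)
      files <- c(files, scan_path, lab_path)
    }
  }
  csv_path <- file.path(out_dir, "cohort.csv")
  cohort <- if (n > 0) dplyr::bind_rows(records)
            else sample_subject(config, "S0")$record[0, ]
  readr::write_csv(cohort, csv_path)
  files <- c(files, csv_path)
  manifest <- list(seed = seed, n = n,
                   config_hash = rlang::hash(config),
                   package_version = as.character(utils::packageVersion("oculometry")),
                   files = basename(files), subjects = ids)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
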