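class_centroid <- function(label_map, code, what = "compartment") {
  idx <- which(label_map$labels == code)
  if (length(idx) == 0)
    abort(paste0("empty ", what, " (code ", code, ") in label map"))
  ijk <- arrayInd(idx, dim(label_map$labels)) - 1
  colMeans(vox_to_world(label_map, ijk))
}

side_codes <- function(side) {
  codes <- ocular_codebook()
  if (side == "right") {
    list(ps = codes[["ps_right"]], lens = codes[["lens_right"]],
         ac = codes[["ac_right"]], ps_contra = codes[["ps_left"]])
  } else if (side == "left") {
    list(ps = codes[["ps_left"]], lens = codes[["lens_left"]],
         ac = codes[["ac_left"]], ps_contra = codes[["ps_right"]])
  } else {
    abort("`side` must be \"left\" or \"right\"")
  }
}

#' Anatomic coordinate system of one eye
#'
#' The anterior-posterior (AP) axis is the unit vector from the posterior
#' segment (vitreous chamber) centroid to the lens centroid. The
#' superior-inferior (SI) axis is orthogonal to the plane spanned by the AP
#' axis and the inter-eye direction (right-PS centroid to left-PS centroid),
#' with its sign fixed so that it points toward the world superior direction.
#' The left-right (LR) axis completes the right-handed set `LR = AP x SI`.
#' Centroids are unweighted means of voxel centres in world mm.
#'
#' @param label_map An [ocular_label_map()] containing a non-empty PS and
#'   lens for `side` and a non-empty contralateral PS.
#' @param side `"left"` or `"right"`.
#' @return A list of class `eye_axes`: unit vectors `ap`, `si`, `lr`, the
#'   centroids `ps_centroid` and `lens_centroid` (mm), and `side`.
#' @export
compute_axes <- function(label_map, side) {
  sc <- side_codes(side)
  ps_c <- class_centroid(label_map, sc$ps, paste0("PS (", side, ")"))
  lens_c <- class_centroid(label_map, sc$lens, paste0("lens (", side, ")"))
  contra_c <- class_centroid(label_map, sc$ps_contra, "contralateral PS")

  ap <- lens_c - ps_c
  if (sqrt(sum(ap^2)) < 1e-9) abort("PS and lens centroids coincide")
  ap <- ap / sqrt(sum(ap^2))
  u <- if (side == "right") contra_c - ps_c else ps_c - contra_c
  u <- u / sqrt(sum(u^2))  # right-PS -> left-PS direction
  si <- c(ap[2] * u[3] - ap[3] * u[2],
          ap[3] * u[1] - ap[1] * u[3],
          ap[1] * u[2] - ap[2] * u[1])
  nsi <- sqrt(sum(si^2))
  if (nsi < 1e-6)
    abort("degenerate anatomy: AP axis collinear with the inter-eye axis")
  si <- si / nsi
  superior <- label_map$orientation %*% c(0, 0, 1)
  if (sum(si * superior) < 0) si <- -si
  lr <- c(ap[2] * si[3] - ap[3] * si[2],
          ap[3] * si[1] - ap[1] * si[3],
          ap[1] * si[2] - ap[2] * si[1])
  structure(list(ap = ap, si = si, lr = lr, ps_centroid = ps_c,
                 lens_centroid = lens_c, side = side),
            class = "eye_axes")
}

#' @export
print.eye_axes <- function(x, ...) {
  cat("<eye_axes>", x$side, "eye; AP =",
      paste(signif(x$ap, 3), collapse = ", "), "\n")
  invisible(x)
}

# sample a binary mask along the world-space line anchor + t * direction and
# return the supra-0.5 crossing interval (sub-voxel, by linear interpolation
# between samples). Values are NA when the mask never reaches 0.5.
line_profile_extent <- function(label_map, codes, anchor, direction,
                                step = NULL, require_inside = TRUE,
                                presmooth_sigma = 0) {
  direction <- direction / sqrt(sum(direction^2))
  step <- step %||% (0.25 * min(label_map$spacing))
  if (inherits(label_map, "scan_volume")) {
    mask <- as.numeric(label_map$data)  # fractional mask in [0, 1]
    dims <- dim(label_map$data)
  } else {
    dims <- dim(label_map$labels)
    mask <- as.numeric(label_map$labels %in% as.integer(codes))
  }
  if (presmooth_sigma > 0) {
    ks <- lapply(label_map$spacing,
                 function(h) gauss_kernel(presmooth_sigma, h, 0))
    mask <- conv3_sep(mask, dims, ks[[1]], ks[[2]], ks[[3]])
  }
  half <- sqrt(sum((dims * label_map$spacing)^2)) / 2 + 2 * step
  t_grid <- seq(-half, half, by = step)
  pts_w <- outer(t_grid, direction) +
    matrix(anchor, length(t_grid), 3, byrow = TRUE)
  pts_v <- world_to_vox(label_map, pts_w)
  v <- interp3_cpp(mask, dims, pts_v, fill = 0)

  if (require_inside) {
    v0 <- interp3_cpp(as.numeric(mask), dims,
                      matrix(world_to_vox(label_map, anchor), 1, 3), fill = 0)
    if (v0 < 0.5) abort("anchor point lies outside the mask")
  }
  inside <- v >= 0.5
  if (!any(inside)) return(c(NA_real_, NA_real_))
  i_first <- which(inside)[1]
  i_last <- tail(which(inside), 1)
  touches_edge <- function(i) {
    any(pts_v[i, ] < 0.51) || any(pts_v[i, ] > dims - 1.51)
  }
  if (i_first == 1 || i_last == length(v) ||
      touches_edge(i_first) || touches_edge(i_last))
    abort("mask does not exit the field of view along the probe line")
  # linear interpolation of the 0.5 crossing between bracketing samples
  t_in <- t_grid[i_first - 1] +
    step * (0.5 - v[i_first - 1]) / (v[i_first] - v[i_first - 1])
  t_out <- t_grid[i_last] +
    step * (v[i_last] - 0.5) / (v[i_last] - v[i_last + 1])
  c(t_in, t_out)
}

#' Sub-voxel chord length of a mask along a line
#'
#' Measures the distance between the first and last crossings of the 0.5
#' level of the trilinearly interpolated mask along the line through
#' `anchor_point` in `direction`, sampled at a step of at most a quarter of
#' the smallest voxel spacing. This reduces the ~1 voxel quantization error of
#' counting voxels along a ray.
#'
#' @param label_map An [ocular_label_map()] (the mask is
#'   `labels %in% classes`), or a [scan_volume()] carrying a fractional
#'   (anti-aliased) mask in `[0, 1]` — e.g. [analytic_ellipsoid_mask()] —
#'   in which case `classes` is ignored.
#' @param classes Label code(s) forming the mask.
#' @param anchor_point World mm point inside the mask.
#' @param direction World direction vector (normalized internally).
#' @param step Sampling step in mm (default `0.25 * min(spacing)`).
#' @param presmooth_sigma Optional isotropic Gaussian pre-smoothing (mm) of
#'   the mask before taking the 0.5 level. Smoothing biases every chord of a
#'   convex body slightly inward (a curvature effect), but the bias is
#'   common-mode across directions and cancels in sphericity ratios, which is
#'   why the sphericity oracle uses it; the default 0 measures the plain
#'   interpolated mask.
#' @return The chord length in mm.
#' @export
chord_length <- function(label_map, classes = NULL, anchor_point, direction,
                         step = NULL, presmooth_sigma = 0) {
  ext <- line_profile_extent(label_map, classes, anchor_point, direction,
                             step = step, require_inside = TRUE,
                             presmooth_sigma = presmooth_sigma)
  ext[2] - ext[1]
}

#' Sphericity of a spheroid dimension pair
#'
#' `S = transverse^2 / axial_length^2 - 1`: positive when the eye is wider
#' than long (oblate), negative when elongated along the visual axis
#' (prolate).
#'
#' @param transverse Transverse dimension (height or width, mm).
#' @param axial_length Axial length (mm).
#' @return Dimensionless sphericity.
#' @export
#' @examples
#' sphericity(23.57, 22.94)
sphericity <- function(transverse, axial_length) {
  transverse^2 / axial_length^2 - 1
}

#' Classify sphericity into oblate / spherical / prolate
#'
#' `S > 0.005` is oblate, `S < -0.005` prolate, and the closed interval
#' `[-0.005, 0.005]` (boundaries included) spherical.
#'
#' @param S Sphericity value(s); must be finite.
#' @param threshold Classification threshold (default 0.005).
#' @return A factor with levels `oblate`, `spherical`, `prolate`.
#' @export
#' @examples
#' classify_shape(c(0.10, 0.005, -0.02))
classify_shape <- function(S, threshold = 0.005) {
  if (any(!is.finite(S))) abort("sphericity must be finite")
  out <- ifelse(S > threshold, "oblate",
                ifelse(S < -threshold, "prolate", "spherical"))
  factor(out, levels = c("oblate", "spherical", "prolate"))
}

#' Compartment volume from voxel counts
#'
#' @param label_map An [ocular_label_map()].
#' @param class_code A label code from [ocular_codebook()] (or its name).
#' @return Volume in mm^3 (voxel count times voxel volume).
#' @export
compartment_volume <- function(label_map, class_code) {
  codes <- ocular_codebook()
  if (is.character(class_code)) {
    if (!class_code %in% names(codes))
      abort(paste0("unknown class name: ", class_code))
    class_code <- codes[[class_code]]
  }
  if (!class_code %in% codes)
    abort(paste0("unknown class code: ", class_code))
  sum(label_map$labels == as.integer(class_code)) * prod(label_map$spacing)
}

#' Full 3D biometry of one eye from its segmentation
#'
#' Builds the eye's anatomic coordinate system ([compute_axes()]), then
#' measures along lines through the PS centroid: height along the SI axis and
#' width along the LR axis (PS mask chords); and along the AP axis, the PS
#' length, lens thickness, anterior chamber depth, and the axial length as
#' the extent of the union PS + lens + AC. Compartment volumes come from
#' voxel counts. Sphericities are computed as printed in the source formulas
#' — horizontal sphericity from the height, vertical from the width — with
#' `swap_sphericity_labels` available for the alternative reading.
#'
#' @param label_map An [ocular_label_map()].
#' @param side `"left"` or `"right"`.
#' @param threshold Shape-classification threshold (default 0.005).
#' @param swap_sphericity_labels If `TRUE`, swap which transverse dimension
#'   feeds which sphericity label.
#' @return A one-row tibble: `subject_id`, `side`, `al_mri`, `ps_length`,
#'   `acd_mri`, `lens_thickness`, `height`, `width`, `ps_volume`,
#'   `lens_volume`, `ac_volume`, `sphericity_h`, `sphericity_v`, `shape_h`,
#'   `shape_v`.
#' @export
measure_biometry <- function(label_map, side, threshold = 0.005,
                             swap_sphericity_labels = FALSE) {
  axes <- compute_axes(label_map, side)
  sc <- side_codes(side)
  anchor <- axes$ps_centroid

  height <- chord_length(label_map, sc$ps, anchor, axes$si)
  width <- chord_length(label_map, sc$ps, anchor, axes$lr)
  ps_ext <- line_profile_extent(label_map, sc$ps, anchor, axes$ap)
  lens_ext <- line_profile_extent(label_map, sc$lens, anchor, axes$ap,
                                  require_inside = FALSE)
  ac_ext <- line_profile_extent(label_map, sc$ac, anchor, axes$ap,
                                require_inside = FALSE)
  al_ext <- line_profile_extent(label_map, c(sc$ps, sc$lens, sc$ac), anchor,
                                axes$ap)
  ps_length <- ps_ext[2] - ps_ext[1]
  lens_thickness <- lens_ext[2] - lens_ext[1]
  acd <- ac_ext[2] - ac_ext[1]
  al <- al_ext[2] - al_ext[1]
  if (is.na(lens_thickness))
    abort(paste0("lens not crossed by the AP line for the ", side, " eye"))
  if (is.na(acd))
    abort(paste0("anterior chamber not crossed by the AP line for the ",
                 side, " eye"))

  trans_h <- if (swap_sphericity_labels) width else height
  trans_v <- if (swap_sphericity_labels) height else width
  s_h <- sphericity(trans_h, al)
  s_v <- sphericity(trans_v, al)
  tibble(
    subject_id = label_map$subject_id %||% NA_character_,
    side = side,
    al_mri = al, ps_length = ps_length, acd_mri = acd,
    lens_thickness = lens_thickness, height = height, width = width,
    ps_volume = compartment_volume(label_map, sc$ps),
    lens_volume = compartment_volume(label_map, sc$lens),
    ac_volume = compartment_volume(label_map, sc$ac),
    sphericity_h = s_h, sphericity_v = s_v,
    shape_h = classify_shape(s_h, threshold),
    shape_v = classify_shape(s_v, threshold))
}

#' Biometry of both eyes for a list of label maps
#'
#' @param label_maps A list of [ocular_label_map()]s (or a single one).
#' @param sides Sides to measure (default both).
#' @param ... Passed to [measure_biometry()].
#' @return A tibble with one row per eye.
#' @export
measure_cohort <- function(label_maps, sides = c("right", "left"), ...) {
  if (inherits(label_maps, "ocular_label_map")) label_maps <- list(label_maps)
  purrr::map_dfr(label_maps, function(lm) {
    purrr::map_dfr(sides, function(s) measure_biometry(lm, s, ...))
  })
}
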