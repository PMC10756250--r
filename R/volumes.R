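#' Label codes for the six ocular regions
#'
#' The segmentation distinguishes the posterior segment (PS, the vitreous
#' chamber), the lens, and the anterior chamber (AC) of each eye, plus
#' background. Left and right are separate classes; they are not obtained by
#' midline mirroring.
#'
#' @return A named integer vector mapping region names to label codes
#'   (`background = 0`, `ps_right = 1`, `ps_left = 2`, `lens_right = 3`,
#'   `lens_left = 4`, `ac_right = 5`, `ac_left = 6`).
#' @export
#' @examples
#' ocular_codebook()
ocular_codebook <- function() {
  c(background = 0L, ps_right = 1L, ps_left = 2L,
    lens_right = 3L, lens_left = 4L, ac_right = 5L, ac_left = 6L)
}

#' Construct a 3D scan volume
#'
#' A minimal container for a 3D intensity grid with world geometry: voxel
#' spacing in mm, the world position of the first voxel centre, and a 3x3
#' direction (orientation) matrix. World coordinates follow the RAS
#' convention (+x right, +y anterior, +z superior):
#' `world = origin + orientation %*% (spacing * index0)` with 0-based indices.
#'
#' @param data 3D numeric array of intensities (finite).
#' @param spacing Voxel spacing in mm (length 3, all > 0).
#' @param origin World coordinates (mm) of the centre of voxel (0, 0, 0).
#' @param orientation 3x3 direction cosine matrix (columns are the world
#'   directions of the voxel axes).
#' @param subject_id Optional subject identifier.
#' @return An object of class `scan_volume`.
#' @export
scan_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        orientation = diag(3), subject_id = NULL) {
  if (length(dim(data)) != 3L) abort("`data` must be a 3D array.")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    abort("`spacing` must be three positive finite values (mm).")
  if (!all(is.finite(data)))
    abort("scan intensities must be finite (found NA/NaN/Inf).")
  structure(
    list(data = data, spacing = as.numeric(spacing),
         origin = as.numeric(origin),
         orientation = matrix(as.numeric(orientation), 3, 3),
         subject_id = subject_id),
    class = "scan_volume")
}

#' Construct an ocular label map
#'
#' Integer segmentation on the same grid conventions as [scan_volume()], with
#' one code per voxel from [ocular_codebook()].
#'
#' @param labels 3D integer array of label codes.
#' @inheritParams scan_volume
#' @return An object of class `ocular_label_map`.
#' @export
ocular_label_map <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                             orientation = diag(3), subject_id = NULL) {
  if (length(dim(labels)) != 3L) abort("`labels` must be a 3D array.")
  codes <- ocular_codebook()
  bad <- setdiff(unique(as.integer(labels)), unname(codes))
  if (length(bad))
    abort(paste0("label map contains codes outside the codebook: ",
                 paste(bad, collapse = ", ")))
  storage.mode(labels) <- "integer"
  structure(
    list(labels = labels, spacing = as.numeric(spacing),
         origin = as.numeric(origin),
         orientation = matrix(as.numeric(orientation), 3, 3),
         subject_id = subject_id),
    class = "ocular_label_map")
}

#' @export
print.scan_volume <- function(x, ...) {
  cat("<scan_volume>", paste(dim(x$data), collapse = " x "),
      "voxels, spacing", paste(signif(x$spacing, 4), collapse = " x "), "mm\n")
  invisible(x)
}

#' @export
print.ocular_label_map <- function(x, ...) {
  tab <- table(factor(as.vector(x$labels), levels = ocular_codebook(),
                      labels = names(ocular_codebook())))
  cat("<ocular_label_map>", paste(dim(x$labels), collapse = " x "),
      "voxels, spacing", paste(signif(x$spacing, 4), collapse = " x "), "mm\n")
  print(tab)
  invisible(x)
}

grid_dim <- function(x) dim(x$data %||% x$labels)

grid_compatible <- function(a, b) {
  identical(grid_dim(a), grid_dim(b)) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-6)) &&
    isTRUE(all.equal(a$origin, b$origin, tolerance = 1e-4)) &&
    isTRUE(all.equal(a$orientation, b$orientation, tolerance = 1e-6))
}

# 0-based voxel indices (n x 3) -> world mm (n x 3)
vox_to_world <- function(grid, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  sweep(ijk %*% t(grid$orientation %*% diag(grid$spacing)), 2, grid$origin, `+`)
}

# world mm (n x 3) -> 0-based continuous voxel coordinates (n x 3)
world_to_vox <- function(grid, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  rel <- sweep(xyz, 2, grid$origin, `-`) %*% grid$orientation  # R^T via right-mult
  sweep(rel, 2, grid$spacing, `/`)
}

# world coordinates of all voxel centres as three arrays (x, y, z).
# Assumes axis-aligned orientation for speed; general orientation handled
# through vox_to_world where needed.
grid_coord_arrays <- function(dim, spacing, origin) {
  xs <- origin[1] + spacing[1] * (seq_len(dim[1]) - 1)
  ys <- origin[2] + spacing[2] * (seq_len(dim[2]) - 1)
  zs <- origin[3] + spacing[3] * (seq_len(dim[3]) - 1)
  list(x = array(rep(xs, times = dim[2] * dim[3]), dim),
       y = array(rep(rep(ys, each = dim[1]), times = dim[3]), dim),
       z = array(rep(zs, each = dim[1] * dim[2]), dim))
}

nifti_affine <- function(grid) {
  aff <- diag(4)
  aff[1:3, 1:3] <- grid$orientation %*% diag(grid$spacing)
  aff[1:3, 4] <- grid$origin
  aff
}

grid_from_affine <- function(aff) {
  lin <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(lin^2))
  list(spacing = spacing,
       orientation = lin %*% diag(1 / spacing),
       origin = aff[1:3, 4])
}

#' Read and write scan volumes as NIfTI-1
#'
#' Volumes are stored as `.nii.gz` with a float64 data type so that a
#' write/read round trip preserves intensities exactly; grid geometry is
#' carried in the sform/qform affine (RAS).
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param scan A [scan_volume()].
#' @param subject_id Optional identifier attached on read.
#' @return `read_scan()` returns a [scan_volume()]; `write_scan()` returns
#'   `path` invisibly.
#' @export
read_scan <- function(path, subject_id = NULL) {
  if (!file.exists(path)) abort(paste0("scan file not found: ", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) abort(paste0("failed to read NIfTI '",
                                                   path, "': ", e$message)))
  g <- grid_from_affine(structure(RNifti::xform(img), class = NULL))
  scan_volume(array(as.numeric(img), dim(img)[1:3]), spacing = g$spacing,
              origin = g$origin, orientation = g$orientation,
              subject_id = subject_id)
}

#' @rdname read_scan
#' @export
write_scan <- function(scan, path) {
  arr <- scan$data
  attr(arr, "pixdim") <- scan$spacing
  img <- RNifti::asNifti(arr, datatype = "double")
  img <- RNifti::`sform<-`(img, structure(nifti_affine(scan), code = 2L))
  img <- RNifti::`qform<-`(img, structure(nifti_affine(scan), code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read and write ocular label maps as NIfTI-1
#'
#' Label maps use an integer data type; [write_labels()] also writes a JSON
#' sidecar (`<path>.json`) documenting the label codebook.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param labels An [ocular_label_map()].
#' @param subject_id Optional identifier attached on read.
#' @param sidecar Write the codebook sidecar JSON? Default `TRUE`.
#' @return `read_labels()` returns an [ocular_label_map()]; `write_labels()`
#'   returns `path` invisibly.
#' @export
read_labels <- function(path, subject_id = NULL) {
  if (!file.exists(path)) abort(paste0("label file not found: ", path))
  img <- RNifti::readNifti(path)
  g <- grid_from_affine(structure(RNifti::xform(img), class = NULL))
  ocular_label_map(array(as.integer(img), dim(img)[1:3]), spacing = g$spacing,
                   origin = g$origin, orientation = g$orientation,
                   subject_id = subject_id)
}

#' @rdname read_labels
#' @export
write_labels <- function(labels, path, sidecar = TRUE) {
  arr <- labels$labels
  attr(arr, "pixdim") <- labels$spacing
  img <- RNifti::asNifti(arr, datatype = "int16")
  img <- RNifti::`sform<-`(img, structure(nifti_affine(labels), code = 2L))
  img <- RNifti::`qform<-`(img, structure(nifti_affine(labels), code = 2L))
  RNifti::writeNifti(img, path, datatype = "int16")
  if (sidecar) {
    side <- sub("\\.nii(\\.gz)?$", "", path)
    jsonlite::write_json(as.list(ocular_codebook()),
                         paste0(side, ".labels.json"), auto_unbox = TRUE)
  }
  invisible(path)
}

binary_mask <- function(label_map, codes) {
  array(label_map$labels %in% as.integer(codes), dim(label_map$labels))
}
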