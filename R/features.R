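# Sampled Gaussian (derivative) kernels in physical units. Offsets are voxel
# steps of size `spacing_mm`; kernels are normalized to exact polynomial
# responses: order 0 sums to 1, order 1 has unit response to a ramp x, order 2
# has unit response to x^2/2 (and zero response to constants and ramps).
gauss_kernel <- function(sigma_mm, spacing_mm, order = 0) {
  r <- max(1L, as.integer(ceiling(3.5 * sigma_mm / spacing_mm)))
  x <- (-r:r) * spacing_mm
  g <- exp(-x^2 / (2 * sigma_mm^2))
  if (order == 0) {
    g / sum(g)
  } else if (order == 1) {
    k <- x * g
    k <- k - mean(k)
    k / sum(k * x)
  } else if (order == 2) {
    k <- (x^2 - sigma_mm^2) * g
    k <- k - mean(k)      # zero response to constants (odd terms vanish)
    k / sum(k * x^2 / 2)  # unit response to x^2/2
  } else {
    abort("kernel order must be 0, 1 or 2")
  }
}

conv3_sep <- function(vol, dims, kx, ky, kz) {
  v <- conv_axis_cpp(as.numeric(vol), dims, kx, 0L)
  v <- conv_axis_cpp(v, dims, ky, 1L)
  conv_axis_cpp(v, dims, kz, 2L)
}

# names of the 16 per-scale features, in their fixed order
scale_feature_names <- function() {
  c("smooth", "dx", "dy", "dz", "dxx", "dxy", "dxz", "dyy", "dyz", "dzz",
    "gradmag", "laplacian", "hess_ev1", "hess_ev2", "hess_ev3", "hess_det")
}

#' Per-voxel Gaussian scale-space features
#'
#' Computes the 48 features used by the voxel classifier: at each scale
#' sigma in \{1.0, 1.6, 4.0\} mm, the Gaussian-smoothed intensity, the three
#' first-order derivatives, the six second-order derivatives, the gradient
#' magnitude, the Laplacian, the three eigenvalues of the Hessian matrix
#' (ascending), and the determinant of the Hessian — 16 features per scale.
#' Derivatives are computed in physical (mm) units through separable sampled
#' Gaussian-derivative filters, so anisotropic voxel spacing is handled
#' correctly.
#'
#' @param scan A [scan_volume()] with finite intensities.
#' @param scales Scale levels (sigma, mm); default `c(1.0, 1.6, 4.0)`.
#' @return An object of class `feature_stack`: a list with `X` (a voxels x 48
#'   numeric matrix with deterministic column names, e.g. `s1_dx`,
#'   `s4_hess_ev1`), `dim`, `spacing`, `origin`, `orientation`.
#' @export
extract_features <- function(scan, scales = c(1.0, 1.6, 4.0)) {
  stopifnot(inherits(scan, "scan_volume"))
  if (!all(is.finite(scan$data)))
    abort("scan contains non-finite intensities")
  dims <- dim(scan$data)
  sp <- scan$spacing
  n <- prod(dims)
  nms <- as.vector(outer(scale_feature_names(),
                         paste0("s", sub("\\.?0+$", "", format(scales))),
                         function(f, s) paste0(s, "_", f)))
  X <- matrix(NA_real_, n, 16L * length(scales), dimnames = list(NULL, nms))
  v0 <- as.numeric(scan$data)

  col0 <- 0L
  for (sgm in scales) {
    k0 <- lapply(sp, function(h) gauss_kernel(sgm, h, 0))
    k1 <- lapply(sp, function(h) gauss_kernel(sgm, h, 1))
    k2 <- lapply(sp, function(h) gauss_kernel(sgm, h, 2))

    # reuse partial separable passes: x first, then y, then z
    x0 <- conv_axis_cpp(v0, dims, k0[[1]], 0L)
    x1 <- conv_axis_cpp(v0, dims, k1[[1]], 0L)
    x2 <- conv_axis_cpp(v0, dims, k2[[1]], 0L)
    x0y0 <- conv_axis_cpp(x0, dims, k0[[2]], 1L)
    x0y1 <- conv_axis_cpp(x0, dims, k1[[2]], 1L)
    x0y2 <- conv_axis_cpp(x0, dims, k2[[2]], 1L)
    x1y0 <- conv_axis_cpp(x1, dims, k0[[2]], 1L)
    x1y1 <- conv_axis_cpp(x1, dims, k1[[2]], 1L)
    x2y0 <- conv_axis_cpp(x2, dims, k0[[2]], 1L)

    smooth <- conv_axis_cpp(x0y0, dims, k0[[3]], 2L)
    dz  <- conv_axis_cpp(x0y0, dims, k1[[3]], 2L)
    dzz <- conv_axis_cpp(x0y0, dims, k2[[3]], 2L)
    dy  <- conv_axis_cpp(x0y1, dims, k0[[3]], 2L)
    dyz <- conv_axis_cpp(x0y1, dims, k1[[3]], 2L)
    dyy <- conv_axis_cpp(x0y2, dims, k0[[3]], 2L)
    dx  <- conv_axis_cpp(x1y0, dims, k0[[3]], 2L)
    dxz <- conv_axis_cpp(x1y0, dims, k1[[3]], 2L)
    dxy <- conv_axis_cpp(x1y1, dims, k0[[3]], 2L)
    dxx <- conv_axis_cpp(x2y0, dims, k0[[3]], 2L)

    eig <- sym3_eigs_cpp(dxx, dyy, dzz, dxy, dxz, dyz)
    X[, col0 + 1L] <- smooth
    X[, col0 + 2L] <- dx
    X[, col0 + 3L] <- dy
    X[, col0 + 4L] <- dz
    X[, col0 + 5L] <- dxx
    X[, col0 + 6L] <- dxy
    X[, col0 + 7L] <- dxz
    X[, col0 + 8L] <- dyy
    X[, col0 + 9L] <- dyz
    X[, col0 + 10L] <- dzz
    X[, col0 + 11L] <- sqrt(dx^2 + dy^2 + dz^2)
    X[, col0 + 12L] <- dxx + dyy + dzz
    X[, col0 + 13L] <- eig[, 1]
    X[, col0 + 14L] <- eig[, 2]
    X[, col0 + 15L] <- eig[, 3]
    X[, col0 + 16L] <- eig[, 4]
    col0 <- col0 + 16L
  }
  structure(list(X = X, dim = dims, spacing = sp, origin = scan$origin,
                 orientation = scan$orientation,
                 subject_id = scan$subject_id),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  cat("<feature_stack>", nrow(x$X), "voxels x", ncol(x$X), "features\n")
  invisible(x)
}
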