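#' Anti-aliased analytic ellipsoid mask
#'
#' Voxelizes an analytic ellipsoid as a fractional-coverage mask: each voxel
#' carries the fraction of its volume inside the ellipsoid (estimated by
#' regular subsampling of boundary voxels; interior and exterior voxels are
#' exact). This is the analytic oracle used to validate the sub-voxel
#' measurement operators: the 0.5 level of the trilinearly interpolated
#' fractional mask tracks the true surface to a small fraction of a voxel,
#' and the mask sum times the voxel volume converges to the analytic volume.
#'
#' @param semi_axes Semi-axes (mm), in the local x/y/z order.
#' @param center World centre (mm).
#' @param rotation 3x3 rotation applied to the local axes.
#' @param grid A [grid_config()].
#' @param supersample Subsamples per axis for boundary voxels (default 4).
#' @return A [scan_volume()] whose data are coverage fractions in `[0, 1]`.
#' @export
analytic_ellipsoid_mask <- function(semi_axes, center = c(0, 0, 0),
                                    rotation = diag(3),
                                    grid = grid_config(c(48, 48, 48)),
                                    supersample = 4L) {
  dims <- grid$dim
  spacing <- grid$spacing
  origin <- -(dims - 1) * spacing / 2
  co <- grid_coord_arrays(dims, spacing, origin)
  dx <- co$x - center[1]; dy <- co$y - center[2]; dz <- co$z - center[3]
  R <- rotation
  q <- function(ax, ay, az) {
    l1 <- R[1, 1] * ax + R[2, 1] * ay + R[3, 1] * az
    l2 <- R[1, 2] * ax + R[2, 2] * ay + R[3, 2] * az
    l3 <- R[1, 3] * ax + R[2, 3] * ay + R[3, 3] * az
    (l1 / semi_axes[1])^2 + (l2 / semi_axes[2])^2 + (l3 / semi_axes[3])^2
  }
  qq <- q(dx, dy, dz)
  # conservative shell: voxels whose centre quadric is within the band that
  # a half-diagonal step can cross
  margin <- sqrt(sum(spacing^2)) / min(semi_axes)
  mask <- array(0, dims)
  mask[qq <= (1 - margin)^2] <- 1
  shell <- which(qq > (1 - margin)^2 & qq < (1 + margin)^2)
  if (length(shell)) {
    s <- supersample
    offs <- (seq_len(s) - (s + 1) / 2) / s
    sub <- as.matrix(expand.grid(ox = offs * spacing[1],
                                 oy = offs * spacing[2],
                                 oz = offs * spacing[3]))
    frac <- numeric(length(shell))
    sdx <- dx[shell]; sdy <- dy[shell]; sdz <- dz[shell]
    for (j in seq_len(nrow(sub))) {
      frac <- frac + (q(sdx + sub[j, 1], sdy + sub[j, 2],
                        sdz + sub[j, 3]) <= 1)
    }
    mask[shell] <- frac / nrow(sub)
  }
  scan_volume(mask, spacing = spacing, origin = origin)
}
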