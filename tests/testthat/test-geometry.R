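test_that("anatomic axes follow the centroid construction on an axis-aligned phantom", {
  cfg <- small_cfg(sd_scale = 0, noise_sd = 0)
  sp <- sample_phantom_spec(cfg, group = "emmetropia", seed = 1)
  lab <- render_phantom(sp, small_grid())$labels
  ax <- compute_axes(lab, "right")
  # AP along +y (anterior), SI along +z, LR along +x up to voxelization
  expect_equal(as.numeric(ax$ap), c(0, 1, 0), tolerance = 1e-3)
  expect_equal(as.numeric(ax$si), c(0, 0, 1), tolerance = 1e-3)
  expect_equal(as.numeric(ax$lr), c(1, 0, 0), tolerance = 1e-3)
  # orthonormal right-handed frame
  expect_lt(abs(sum(ax$ap * ax$si)), 1e-6)
  expect_lt(abs(sum(ax$ap * ax$lr)), 1e-6)
  expect_lt(abs(sum(ax$si * ax$lr)), 1e-6)
  expect_equal(sqrt(sum(ax$ap^2)), 1, tolerance = 1e-9)
  cross <- c(ax$ap[2] * ax$si[3] - ax$ap[3] * ax$si[2],
             ax$ap[3] * ax$si[1] - ax$ap[1] * ax$si[3],
             ax$ap[1] * ax$si[2] - ax$ap[2] * ax$si[1])
  expect_equal(cross, as.numeric(ax$lr), tolerance = 1e-9)
  # missing compartment errors name the side and tissue
  lab2 <- lab; lab2$labels[lab2$labels == 3L] <- 0L
  expect_error(compute_axes(lab2, "right"), "lens")
})

test_that("rotating the world rotates the axes with it (equivariance)", {
  lab <- small_cohort()[[2]]$labels
  ax0 <- compute_axes(lab, "left")
  set.seed(13)
  R <- random_rotation(40)
  lab_r <- lab
  lab_r$orientation <- R %*% lab$orientation
  lab_r$origin <- as.numeric(R %*% lab$origin)
  ax1 <- compute_axes(lab_r, "left")
  expect_equal(as.numeric(ax1$ap), as.numeric(R %*% ax0$ap),
               tolerance = 1e-9)
  # SI/LR may flip jointly if the rotated SI loses its superior alignment;
  # the frame itself must still be the rotation of the original frame
  s <- sign(sum(ax1$si * (R %*% ax0$si)))
  expect_equal(as.numeric(ax1$si), as.numeric(s * R %*% ax0$si),
               tolerance = 1e-9)
  expect_equal(as.numeric(ax1$lr), as.numeric(s * R %*% ax0$lr),
               tolerance = 1e-9)
})

test_that("chords of analytic masks match closed-form values", {
  # sphere of radius 10: diameter through the centre
  m <- analytic_ellipsoid_mask(c(10, 10, 10), center = c(0.2, -0.3, 0.1))
  expect_equal(chord_length(m, anchor_point = c(0.2, -0.3, 0.1),
                            direction = c(0, 0, 1)), 20, tolerance = 0.5)
  # ellipsoid semi-axes (8, 11, 12) probed along each principal axis
  m2 <- analytic_ellipsoid_mask(c(8, 11, 12))
  ch <- vapply(list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), function(d)
    chord_length(m2, anchor_point = c(0, 0, 0), direction = d), numeric(1))
  expect_equal(ch, c(16, 22, 24), tolerance = 1)
  # off-centre chord of a sphere: 2 sqrt(r^2 - d^2)
  d_off <- 4
  ch_off <- chord_length(m, anchor_point = c(0.2, -0.3 + d_off, 0.1),
                         direction = c(0, 0, 1))
  expect_equal(ch_off, 2 * sqrt(100 - d_off^2), tolerance = 1)
  expect_error(chord_length(m, anchor_point = c(30, 0, 0),
                            direction = c(1, 0, 0)), "outside the mask")
})

test_that("sub-voxel sphericity and shape class are recovered on eye-like ellipsoids", {
  set.seed(4)
  g <- grid_config(c(48, 48, 48))
  for (i in 1:8) {
    ax <- c(11.4, 11.7, 11.9) + runif(3, -0.3, 0.3)
    rot <- random_rotation(20)
    cen <- runif(3, -0.5, 0.5)
    m <- analytic_ellipsoid_mask(ax, center = cen, rotation = rot, grid = g)
    ch <- vapply(1:3, function(a)
      chord_length(m, anchor_point = cen, direction = rot[, a],
                   presmooth_sigma = 1), numeric(1))
    expect_lt(max(abs(ch - 2 * ax)), 1)            # chords within a voxel
    vol <- sum(m$data) * prod(m$spacing)
    expect_lt(abs(vol / (4 / 3 * pi * prod(ax)) - 1), 0.03)
    s_h <- sphericity(ch[2], ch[1])
    s_v <- sphericity(ch[3], ch[1])
    expect_lt(abs(s_h - sphericity(ax[2], ax[1])), 0.01)
    expect_lt(abs(s_v - sphericity(ax[3], ax[1])), 0.01)
    if (abs(sphericity(ax[2], ax[1])) > 0.02)
      expect_identical(as.character(classify_shape(s_h)),
                       as.character(classify_shape(sphericity(ax[2], ax[1]))))
  }
})

test_that("rigid motion leaves analytic-ellipsoid biometry invariant", {
  set.seed(8)
  ax <- c(11.3, 11.8, 12.0)
  g <- grid_config(c(52, 52, 52))
  ref <- NULL
  for (i in 1:10) {
    rot <- random_rotation(30)
    cen <- runif(3, -2, 2)
    m <- analytic_ellipsoid_mask(ax, center = cen, rotation = rot, grid = g)
    ch <- vapply(1:3, function(a)
      chord_length(m, anchor_point = cen, direction = rot[, a],
                   presmooth_sigma = 1), numeric(1))
    vol <- sum(m$data) * prod(m$spacing)
    expect_lt(max(abs(ch - 2 * ax)), 1)
    expect_lt(abs(vol / (4 / 3 * pi * prod(ax)) - 1), 0.03)
    expect_lt(abs(sphericity(ch[2], ch[1]) - sphericity(ax[2], ax[1])), 0.01)
  }
})

test_that("sphericity formula and shape thresholds behave exactly as printed", {
  expect_equal(round(sphericity(23.57, 22.94), 3), 0.056)
  expect_equal(sphericity(10, 10), 0)
  expect_identical(as.character(classify_shape(0.10)), "oblate")
  expect_identical(as.character(classify_shape(0.005)), "spherical")
  expect_identical(as.character(classify_shape(-0.005)), "spherical")
  expect_identical(as.character(classify_shape(-0.02)), "prolate")
  expect_identical(as.character(classify_shape(0.0051)), "oblate")
  expect_error(classify_shape(NaN), "finite")
})

test_that("compartment volumes count voxels times voxel volume", {
  lab <- array(0L, c(20, 20, 20))
  lab[1:10, 1:10, 1:10] <- 1L
  lm <- ocular_label_map(lab)
  expect_equal(compartment_volume(lm, 1), 1000)
  expect_equal(compartment_volume(lm, "ps_right"), 1000)
  expect_equal(compartment_volume(lm, "lens_left"), 0)  # empty class
  expect_error(compartment_volume(lm, 9), "unknown class")
  # halving the spacing with 8x the voxel count preserves the volume
  lab2 <- array(0L, c(40, 40, 40))
  lab2[1:20, 1:20, 1:20] <- 1L
  lm2 <- ocular_label_map(lab2, spacing = c(0.5, 0.5, 0.5))
  expect_equal(compartment_volume(lm2, 1), 1000)
})

test_that("full biometry is internally consistent on rendered phantoms", {
  subs <- small_cohort()
  bio <- measure_biometry(subs[[1]]$labels, "right")
  expect_gt(bio$al_mri, bio$ps_length + bio$acd_mri)  # the lens fills the rest
  expect_equal(bio$al_mri, bio$ps_length + bio$lens_thickness + bio$acd_mri,
               tolerance = 0.6)
  expect_identical(as.character(bio$shape_h),
                   as.character(classify_shape(bio$sphericity_h)))
  # a perfect sphere measures as spherical
  cfg <- small_cfg(sd_scale = 0, noise_sd = 0)
  sp <- sample_phantom_spec(cfg, group = "emmetropia", seed = 1)
  for (s in c("right", "left")) sp$eyes[[s]]$ps_semi[] <- 10
  lab <- render_phantom(sp, small_grid())$labels
  ax <- compute_axes(lab, "right")
  h <- chord_length(lab, oculometry:::side_codes("right")$ps,
                    ax$ps_centroid, ax$si)
  w <- chord_length(lab, oculometry:::side_codes("right")$ps,
                    ax$ps_centroid, ax$lr)
  expect_equal(h, w, tolerance = 0.75)
  # mirror-symmetric phantom: left and right biometry agree
  both <- measure_cohort(lab)
  expect_equal(both$ps_length[1], both$ps_length[2], tolerance = 0.5)
  expect_equal(both$ps_volume[1], both$ps_volume[2], tolerance = 1)
})
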