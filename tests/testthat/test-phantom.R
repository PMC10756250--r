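test_that("zero-variance specs reproduce the configured group means exactly", {
  cfg <- cohort_config(sd_scale = 0)
  hyp <- sample_phantom_spec(cfg, group = "hyperopia", seed = 1)
  expect_equal(2 * hyp$eyes$right$ps_semi[["ap"]], 16.2)
  emm <- sample_phantom_spec(cfg, group = "emmetropia", seed = 1)
  expect_equal(2 * emm$eyes$right$ps_semi[["si"]], 23.5)
  expect_equal(2 * emm$eyes$right$ps_semi[["lr"]], 23.7)
  tr <- phantom_truth(emm)
  expect_equal(tr$ps_length, rep(16.9, 2))
  expect_equal(tr$lens_volume, rep(84, 2), tolerance = 1e-6)
})

test_that("spec sampling is deterministic under a fixed seed", {
  cfg <- cohort_config()
  a <- sample_phantom_spec(cfg, seed = 42)
  b <- sample_phantom_spec(cfg, seed = 42)
  expect_identical(a, b)
  expect_s3_class(a, "phantom_spec")
  expect_true(a$group %in% c("myopia", "emmetropia", "hyperopia"))
})

test_that("truncated group sampler reports excessive rejections", {
  grp <- default_group_table()
  grp$se_mean[grp$group == "myopia"] <- 5   # far outside the myopic band
  grp$se_sd[grp$group == "myopia"] <- 0.01
  cfg <- cohort_config(groups = grp)
  expect_warning(sample_phantom_spec(cfg, group = "myopia", seed = 1),
                 "rejections")
})

test_that("a rendered 10 mm sphere recovers the analytic ellipsoid volume", {
  cfg <- small_cfg(sd_scale = 0, noise_sd = 0)
  sp <- sample_phantom_spec(cfg, group = "emmetropia", seed = 1)
  for (side in c("right", "left")) sp$eyes[[side]]$ps_semi[] <- 10
  v <- render_phantom(sp, small_grid())
  vol <- compartment_volume(v$labels, "ps_right")
  expect_lt(abs(vol / (4 / 3 * pi * 1000) - 1), 0.03)
})

test_that("a mirror-symmetric phantom renders a mid-sagittally symmetric label map", {
  cfg <- small_cfg(sd_scale = 0, noise_sd = 0)
  sp <- sample_phantom_spec(cfg, group = "emmetropia", seed = 1)
  lab <- render_phantom(sp, small_grid())$labels$labels
  flipped <- lab[dim(lab)[1]:1, , ]
  swap <- c(0L, 2L, 1L, 4L, 3L, 6L, 5L)  # exchange left/right codes
  expect_identical(array(swap[flipped + 1L], dim(lab)), lab)
})

test_that("eyes outside the field of view are rejected by name", {
  cfg <- cohort_config(sd_scale = 0, noise_sd = 0)
  sp <- sample_phantom_spec(cfg, subject_id = "BAD", group = "emmetropia",
                            seed = 1)
  expect_error(render_phantom(sp, grid_config(c(40, 40, 40))), "BAD")
})

test_that("rendered-then-measured emmetropic phantom recovers true lengths within a voxel", {
  cfg <- small_cfg(sd_scale = 0, noise_sd = 0)
  sp <- sample_phantom_spec(cfg, group = "emmetropia", seed = 1)
  v <- render_phantom(sp, small_grid())
  bio <- measure_biometry(v$labels, "right")
  truth <- phantom_truth(sp)[1, ]
  expect_lt(abs(bio$ps_length - 16.9), 1)
  expect_lt(abs(bio$height - truth$height), 1)
  expect_lt(abs(bio$width - truth$width), 1)
  expect_lt(abs(bio$al_mri - truth$al), 1)
  expect_lt(abs(bio$ps_volume / truth$ps_volume - 1), 0.03)
})

test_that("label compartments are disjoint by construction and each eye is connected", {
  subs <- small_cohort()
  lab <- subs[[1]]$labels$labels
  expect_true(all(lab %in% 0:6))  # one code per voxel
  expect_true(is_connected(array(lab %in% c(1, 3, 5), dim(lab))))
  expect_true(is_connected(array(lab %in% c(2, 4, 6), dim(lab))))
})

test_that("biometry emulation adds the configured axial-length offset exactly when noiseless", {
  cfg <- cohort_config(sd_scale = 0)
  sp <- sample_phantom_spec(cfg, group = "emmetropia", seed = 1)
  truth_al <- mean(phantom_truth(sp)$al)
  rec <- emulate_optical_biometry(sp, cfg, noise_scale = 0, seed = 2)
  expect_equal(rec$al_biometry - truth_al, 0.18, tolerance = 1e-10)
  expect_equal(spherical_equivalent(rec$sphere, rec$cylinder), sp$se_true,
               tolerance = 1e-10)
  # a spec engineered to a 22.94 mm true length reads 23.12 on the biometer
  delta <- 22.94 - truth_al
  sp2 <- sp
  for (s in c("right", "left"))
    sp2$eyes[[s]]$ps_semi[["ap"]] <- sp$eyes[[s]]$ps_semi[["ap"]] + delta / 2
  rec2 <- emulate_optical_biometry(sp2, cfg, noise_scale = 0, seed = 2)
  expect_equal(rec2$al_biometry, 23.12, tolerance = 1e-10)
})

test_that("zero offset and zero noise give a Bland-Altman difference of zero", {
  cfg <- cohort_config(sd_scale = 0)
  recs <- purrr::map_dfr(1:5, function(i) {
    sp <- sample_phantom_spec(cfg, sprintf("S%d", i), seed = i)
    rec <- emulate_optical_biometry(sp, cfg, delta_al = 0, noise_scale = 0)
    rec$al_mri <- mean(phantom_truth(sp)$al)
    rec
  })
  ba <- glance(bland_altman(recs, al_biometry, al_mri))
  expect_equal(ba$mean_diff, 0, tolerance = 1e-10)
  expect_equal(ba$loa_low, 0, tolerance = 1e-10)
  expect_equal(ba$loa_high, 0, tolerance = 1e-10)
})

test_that("a 500-subject cohort recovers the 0.18 mm biometry-vs-MRI offset", {
  recs <- sample_cohort_records(500, cohort_config(), seed = 11)
  ba <- glance(bland_altman(recs, al_biometry, al_mri))
  mc <- 3 * 0.454 / sqrt(500)
  expect_lt(abs(ba$mean_diff - 0.18), mc)
})

test_that("cohort records reproduce configured proportions and moments at n = 1000", {
  cfg <- cohort_config()
  recs <- sample_cohort_records(1000, cfg, seed = 7)
  expect_equal(nrow(recs), 1000)
  expect_identical(anyDuplicated(recs$subject_id), 0L)
  p_myo <- mean(recs$group_true == "myopia")
  expect_lt(abs(p_myo - 0.123), 3 * sqrt(0.123 * 0.877 / 1000))
  # law-of-large-numbers check against the configured mixture mean
  g <- cfg$groups
  w <- cfg$group_props[g$group]
  mix_mean <- sum(w * g$ps_length_mean)
  mix_sd <- sqrt(sum(w * (g$ps_length_sd^2 + g$ps_length_mean^2)) -
                   mix_mean^2)
  expect_lt(abs(mean(recs$ps_length_true) - mix_mean),
            3 * mix_sd / sqrt(1000))
  mix_h <- sum(w * g$height_mean)
  expect_lt(abs(mean(recs$height_true) - mix_h), 3 * 1.0 / sqrt(1000))
  # refraction-linked geometry: myopic eyes are longer
  expect_gt(mean(recs$ps_length_true[recs$group_true == "myopia"]),
            mean(recs$ps_length_true[recs$group_true == "hyperopia"]))
})

test_that("generate_cohort writes reproducible outputs and handles n = 0", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_cohort(2, d1, small_cfg(), small_grid(), seed = 3)
  generate_cohort(2, d2, small_cfg(), small_grid(), seed = 3)
  expect_identical(readLines(file.path(d1, "cohort.csv")),
                   readLines(file.path(d2, "cohort.csv")))
  expect_true(file.exists(file.path(d1, "S0001_scan.nii.gz")))
  expect_true(file.exists(file.path(d1, "S0001_labels.labels.json")))
  d0 <- withr::local_tempdir()
  man <- generate_cohort(0, d0, small_cfg(), seed = 1)
  expect_identical(man$subjects, character(0))
  expect_identical(man$files, "cohort.csv")
})
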