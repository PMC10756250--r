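test_that("published group means reproduce the printed pairwise differences", {
  gd <- group_differences(reference_group_biometry())
  get <- function(v, col) gd[[col]][gd$variable == v]
  expect_equal(get("ps_volume", "myopia_minus_emmetropia"), 470)
  expect_equal(get("ps_volume", "myopia_minus_hyperopia"), 970)
  expect_equal(get("ps_length", "myopia_minus_hyperopia"), 1.5)
  expect_equal(get("height", "myopia_minus_hyperopia"), 1.2)
  expect_equal(get("width", "myopia_minus_hyperopia"), 0.7, tolerance = 1e-9)
})

test_that("published compartment means sum to the printed total eye volume", {
  rc <- reference_cohort_biometry()
  get <- function(v) rc$mean[rc$variable == v]
  expect_equal(total_eye_volume(get("ps_volume"), get("lens_volume"),
                                get("ac_volume")), 6670)
})

test_that("the report stage summarises a synthetic cohort coherently", {
  recs <- sample_cohort_records(400, cohort_config(), seed = 21)
  # attach a crude per-subject shape class from the generative truth so the
  # shape table is exercised without rendering
  recs$sphericity_h <- sphericity(recs$height_true,
                                  recs$ps_length_true + recs$acd_true +
                                    recs$lens_thickness_true)
  recs$shape_h <- classify_shape(recs$sphericity_h)
  recs$ps_length <- recs$ps_length_true
  recs$height <- recs$height_true
  recs$width <- recs$width_true
  rep <- build_report(recs)
  expect_s3_class(rep, "cohort_report")
  expect_true(all(c("ps_length", "height", "width") %in%
                    rep$descriptives$variable))
  # correlation signs recovered: longer eyes are more myopic
  r_ps <- rep$correlations$r[rep$correlations$measure == "se" &
                               rep$correlations$mri_variable == "ps_length"]
  expect_lt(r_ps, -0.2)
  # shape percentages sum to 100 within each group
  sums <- tapply(rep$shape_by_group$percent, rep$shape_by_group$group, sum)
  expect_equal(as.numeric(sums), rep(100, length(sums)), tolerance = 1e-9)
  # group means ordered as expected for PS length
  gm <- rep$group_means
  expect_gt(gm$ps_length[gm$group == "myopia"],
            gm$ps_length[gm$group == "hyperopia"])
  expect_true(all(rep$anova_p$p >= 0 & rep$anova_p$p <= 1))
})

test_that("an empty cohort produces headers-only tables without error", {
  rep <- build_report(tibble::tibble())
  expect_identical(nrow(rep$descriptives), 0L)
  expect_identical(nrow(rep$correlations), 0L)
  expect_identical(nrow(rep$group_means), 0L)
  expect_identical(nrow(rep$shape_by_group), 0L)
})

test_that("synthetic cohorts recover the generative correlation structure", {
  recs <- sample_cohort_records(600, cohort_config(), seed = 31)
  se_ps <- pearson(recs, sphere, ps_length_true)  # sphere tracks SE
  recs$se <- spherical_equivalent(recs$sphere, recs$cylinder)
  expect_lt(pearson(recs, se, ps_length_true)$r, -0.3)
  s_h <- sphericity(recs$height_true,
                    recs$ps_length_true + recs$lens_thickness_true +
                      recs$acd_true)
  expect_gt(pearson(recs$se, s_h)$r, 0.2)
})
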