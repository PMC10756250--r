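test_that("spherical equivalent is sphere plus half the cylinder", {
  expect_equal(spherical_equivalent(-2, -1), -2.5)
  expect_equal(spherical_equivalent(3, 0), 3)
  expect_equal(spherical_equivalent(3, -2), 2)
  expect_equal(spherical_equivalent(c(1, 2), c(-1, 0)), c(0.5, 2))
})

test_that("refraction grouping places the boundaries exactly as printed", {
  expect_identical(as.character(refraction_group(-0.5)), "myopia")
  expect_identical(as.character(refraction_group(-0.49)), "emmetropia")
  expect_identical(as.character(refraction_group(2.0)), "hyperopia")
  expect_identical(as.character(refraction_group(1.99)), "emmetropia")
  expect_identical(as.character(refraction_group(0.74)), "emmetropia")
})

test_that("exclusion rules drop failed scans and inadequate cycloplegia", {
  cohort <- tibble::tibble(
    subject_id = 1:5,
    scan_quality_pass = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    pupil_diameter = c(5.9, 6.0, 7.0, 7.5, NA))
  out <- apply_exclusions(cohort)
  expect_identical(out$cohort$subject_id, c(2L, 4L))  # 5.9 mm out, 6.0 mm in
  expect_identical(out$log$n[out$log$reason == "low_quality_scan"], 1L)
  expect_identical(out$log$n[out$log$reason == "inadequate_cycloplegia"], 2L)
  all_pass <- tibble::tibble(subject_id = 1:3,
                             scan_quality_pass = TRUE,
                             pupil_diameter = c(6, 7, 8))
  expect_identical(apply_exclusions(all_pass)$cohort, all_pass)
})

test_that("Pearson correlation matches its closed-form cases", {
  x <- 1:20
  expect_equal(pearson(tibble::tibble(a = x, b = 2 * x + 1), a, b)$r, 1)
  set.seed(3)
  null <- pearson(rnorm(1000), rnorm(1000))
  expect_lt(abs(null$r), 0.1)
  expect_error(pearson(1:10, rep(1, 10)), "zero variance")
  # agrees with cor.test as the reference implementation
  set.seed(4)
  u <- rnorm(30); v <- u + rnorm(30)
  expect_equal(pearson(u, v)$p, stats::cor.test(u, v)$p.value)
})

test_that("group comparison runs ANOVA on numbers and chi-square on classes", {
  d0 <- tibble::tibble(v = rep(c(1, 2, 3), 3),
                       group = rep(c("a", "b", "c"), each = 3))
  expect_equal(group_compare(d0, v)$statistic, 0)
  d1 <- tibble::tibble(v = c(1, 2, 3, 1, 2, 3, 11, 12, 13),
                       group = rep(c("a", "b", "c"), each = 3))
  res <- group_compare(d1, v)
  expect_identical(res$test, "anova")
  expect_gt(res$statistic, 50)
  expect_lt(res$p, 0.001)
  # uniform 2x2 table -> chi-square exactly 0
  d2 <- tibble::tibble(s = factor(rep(c("x", "y"), 20)),
                       group = rep(c("a", "a", "b", "b"), 10))
  expect_equal(group_compare(d2, s)$statistic, 0)
  expect_error(group_compare(tibble::tibble(v = 1, group = "a"), v),
               "2 groups")
})

test_that("one-way ANOVA with two groups equals the squared t statistic", {
  set.seed(6)
  for (i in 1:10) {
    d <- tibble::tibble(v = rnorm(24), group = rep(c("a", "b"), each = 12))
    f <- group_compare(d, v)
    tt <- stats::t.test(v ~ group, data = d, var.equal = TRUE)
    expect_equal(f$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(f$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("the restricted cubic spline reproduces linear functions exactly", {
  set.seed(1)
  x <- runif(100, 0, 10)
  d <- tibble::tibble(x = x, y = 3 * x - 2)
  fit <- rcs_regression(d, x, y)
  pr <- predict(fit, newdata = seq(0, 10, 0.25))
  expect_equal(pr$fit, 3 * pr$x - 2, tolerance = 1e-8)
  # spline terms contribute nothing to a linear response
  co <- tidy(fit)
  expect_lt(max(abs(co$estimate[grepl("b2", co$term)])), 1e-6)
  expect_equal(glance(fit)$r_squared, 1, tolerance = 1e-12)
})

test_that("the spline approximates smooth curvature and stays linear beyond the knots", {
  set.seed(2)
  x <- seq(0, 1, length.out = 500)
  fit <- rcs_regression(tibble::tibble(x = x, y = x^2), x, y)
  inside <- predict(fit, newdata = seq(0.1, 0.9, 0.01))
  expect_lt(max(abs(inside$fit - inside$x^2)), 0.02)
  # second differences vanish outside the boundary knots
  lo <- predict(fit, newdata = seq(-1, -0.5, 0.05))$fit
  hi <- predict(fit, newdata = seq(1.5, 2, 0.05))$fit
  expect_lt(max(abs(diff(diff(lo)))), 1e-8)
  expect_lt(max(abs(diff(diff(hi)))), 1e-8)
  expect_error(rcs_regression(tibble::tibble(x = rep(1, 50), y = rnorm(50)),
                              x, y), "knots")
})

test_that("Bland-Altman reports the mean difference and 1.96-SD limits", {
  x <- c(1, 2, 3, 4)
  expect_equal(unlist(glance(bland_altman(x, x))[1, 1:3]),
               c(mean_diff = 0, loa_low = 0, loa_high = 0))
  cst <- glance(bland_altman(x + 0.7, x))
  expect_equal(cst$mean_diff, 0.7)
  expect_equal(cst$loa_low, 0.7)
  set.seed(5)
  d <- rnorm(500, 0.18, 0.454)
  ba <- glance(bland_altman(10 + d, rep(10, 500)))
  expect_equal(ba$mean_diff, mean(d))
  expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * sd(d), tolerance = 1e-12)
})
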