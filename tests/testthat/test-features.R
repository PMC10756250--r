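make_scan <- function(f, dims = c(24, 24, 24), spacing = c(1, 1, 1)) {
  origin <- -(dims - 1) * spacing / 2
  co <- oculometry:::grid_coord_arrays(dims, spacing, origin)
  scan_volume(array(f(co$x, co$y, co$z), dims), spacing = spacing,
              origin = origin)
}

# interior voxels at least `margin[i]` from the faces of axis i (replicate
# borders only disturb features along axes where the field actually varies)
interior <- function(dims, margin) {
  margin <- rep_len(margin, 3)
  a <- array(FALSE, dims)
  a[(margin[1] + 1):(dims[1] - margin[1]),
    (margin[2] + 1):(dims[2] - margin[2]),
    (margin[3] + 1):(dims[3] - margin[3])] <- TRUE
  as.vector(a)
}

test_that("the stack has exactly 48 features in a fixed documented order", {
  sc <- make_scan(function(x, y, z) x + 2 * y)
  fs <- extract_features(sc)
  expect_identical(ncol(fs$X), 48L)
  expect_identical(colnames(fs$X)[1:4], c("s1_smooth", "s1_dx", "s1_dy",
                                          "s1_dz"))
  expect_identical(colnames(fs$X)[33], "s4_smooth")
  expect_true(all(is.finite(fs$X)))
  sc$data[1] <- NA
  expect_error(extract_features(sc), "finite")
})

test_that("a constant image yields zero derivatives and the constant itself", {
  sc <- make_scan(function(x, y, z) rep(7, length(x)))
  fs <- extract_features(sc)
  smooth_cols <- grep("_smooth$", colnames(fs$X))
  expect_equal(unname(fs$X[, smooth_cols]),
               matrix(7, nrow(fs$X), 3), tolerance = 1e-10)
  deriv_cols <- setdiff(seq_len(48), smooth_cols)
  expect_lt(max(abs(fs$X[, deriv_cols])), 1e-8)
})

test_that("a linear ramp has unit-slope first derivatives and zero Laplacian", {
  a <- 3.2
  sc <- make_scan(function(x, y, z) a * x, dims = c(48, 20, 20),
                  spacing = c(1, 1, 2))
  fs <- extract_features(sc)
  keep <- interior(c(48, 20, 20), c(16, 0, 0))
  for (s in c("s1", "s1.6", "s4")) {
    expect_equal(unname(fs$X[keep, paste0(s, "_dx")]),
                 rep(a, sum(keep)), tolerance = 1e-6)
    expect_lt(max(abs(fs$X[keep, paste0(s, "_dy")])), 1e-8)
    expect_equal(unname(fs$X[keep, paste0(s, "_gradmag")]),
                 rep(a, sum(keep)), tolerance = 1e-6)
    expect_lt(max(abs(fs$X[keep, paste0(s, "_laplacian")])), 1e-6)
  }
})

test_that("an isotropic Gaussian blob has equal negative Hessian eigenvalues at its centre", {
  sb <- 5
  sc <- make_scan(function(x, y, z) 100 * exp(-(x^2 + y^2 + z^2) / (2 * sb^2)),
                  dims = c(33, 33, 33))
  fs <- extract_features(sc)
  centre <- which.max(fs$X[, "s1_smooth"])
  ev <- fs$X[centre, c("s1_hess_ev1", "s1_hess_ev2", "s1_hess_ev3")]
  expect_true(all(ev < 0))
  expect_lt(diff(range(ev)) / abs(mean(ev)), 0.01)
  # analytic: smoothing a Gaussian of width sb with sigma gives width
  # sqrt(sb^2 + sigma^2); the central second derivative is -A / width^2
  width2 <- sb^2 + 1^2
  amp <- 100 * (sb^2 / width2)^(3 / 2)
  expect_equal(unname(mean(ev)), -amp / width2, tolerance = 0.02)
  expect_lt(fs$X[centre, "s1_hess_det"], 0)
})
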