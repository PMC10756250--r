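#' Spherical equivalent refractive error
#'
#' `SE = sphere + cylinder / 2`, in diopters.
#'
#' @param sphere,cylinder Refraction components (D), finite, vectorized.
#' @return SE in diopters.
#' @export
#' @examples
#' spherical_equivalent(-2, -1)
spherical_equivalent <- function(sphere, cylinder) {
  sphere + cylinder / 2
}

#' Refractive-error grouping
#'
#' `SE <= -0.5 D` is myopia, `SE >= +2.0 D` hyperopia, anything between is
#' emmetropia. The boundaries belong to myopia and hyperopia respectively,
#' matching the defining inequalities.
#'
#' @param se Spherical equivalent (D), vectorized.
#' @param myopia_cut,hyperopia_cut Group cut-offs (D).
#' @return A factor with levels `myopia`, `emmetropia`, `hyperopia`.
#' @export
#' @examples
#' refraction_group(c(-0.5, 0.74, 2.0))
refraction_group <- function(se, myopia_cut = -0.5, hyperopia_cut = 2.0) {
  out <- ifelse(se <= myopia_cut, "myopia",
                ifelse(se >= hyperopia_cut, "hyperopia", "emmetropia"))
  factor(out, levels = c("myopia", "emmetropia", "hyperopia"))
}

#' Apply the cohort exclusion rules
#'
#' Removes subjects with a failed scan-quality inspection and, among the
#' remainder, subjects with inadequate cycloplegia (pupil diameter < 6.0 mm,
#' so refraction-based analyses only see fully cyclopleged eyes). A pupil of
#' exactly 6.0 mm is retained.
#'
#' @param cohort A tibble with (optionally) `scan_quality_pass` (logical) and
#'   `pupil_diameter` (mm) columns; missing columns skip that rule.
#' @param pupil_min Cycloplegia criterion (mm), default 6.0.
#' @return A list: `cohort` (retained rows) and `log` (a tibble counting
#'   exclusions per reason).
#' @export
apply_exclusions <- function(cohort, pupil_min = 6.0) {
  n0 <- nrow(cohort)
  n_scan <- 0L
  if ("scan_quality_pass" %in% names(cohort)) {
    keep <- cohort$scan_quality_pass %in% TRUE
    n_scan <- sum(!keep)
    cohort <- cohort[keep, , drop = FALSE]
  }
  n_pupil <- 0L
  if ("pupil_diameter" %in% names(cohort)) {
    keep <- !is.na(cohort$pupil_diameter) & cohort$pupil_diameter >= pupil_min
    n_pupil <- sum(!keep)
    cohort <- cohort[keep, , drop = FALSE]
  }
  list(cohort = as_tibble(cohort),
       log = tibble(reason = c("low_quality_scan", "inadequate_cycloplegia",
                               "included"),
                    n = c(n_scan, n_pupil, nrow(cohort)),
                    of = n0))
}

#' Pearson correlation with a two-sided p value
#'
#' Product-moment correlation; the p value comes from the t transform
#' `t = r sqrt((n-2)/(1-r^2))`.
#'
#' @param data Optional data frame (then `x`, `y` are unquoted column names);
#'   or pass two numeric vectors directly.
#' @param x,y Columns or numeric vectors; pairs with missing values are
#'   dropped.
#' @return A tibble with `r`, `p`, `n`.
#' @export
#' @examples
#' pearson(data.frame(a = 1:10, b = (1:10)^2), a, b)
pearson <- function(data, x, y) {
  if (is.data.frame(data)) {
    xv <- eval_tidy(enquo(x), data)
    yv <- eval_tidy(enquo(y), data)
  } else {
    xv <- data
    yv <- x
  }
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3) abort("need at least 3 complete pairs")
  if (sd(xv) == 0 || sd(yv) == 0)
    abort("zero variance: Pearson correlation undefined")
  ct <- stats::cor.test(xv, yv, method = "pearson")
  tibble(r = unname(ct$estimate), p = ct$p.value, n = length(xv))
}

#' Compare a variable between refraction groups
#'
#' One-way ANOVA for continuous variables; Pearson chi-square on the
#' contingency table for categorical variables (e.g. shape class).
#'
#' @param data A data frame.
#' @param variable Unquoted column to test.
#' @param group Unquoted grouping column (default `group`).
#' @return A tibble: `test` (`"anova"` or `"chi-square"`), `statistic`, `df`,
#'   `p`.
#' @export
group_compare <- function(data, variable, group = group) {
  v <- eval_tidy(enquo(variable), data)
  g <- eval_tidy(enquo(group), data)
  ok <- !is.na(v) & !is.na(g)
  v <- v[ok]; g <- droplevels(factor(g[ok]))
  if (nlevels(g) < 2) abort("need at least 2 groups")
  if (any(table(g) == 0)) abort("empty group")
  if (is.numeric(v)) {
    fit <- aov(v ~ g)
    s <- summary(fit)[[1]]
    tibble(test = "anova", statistic = s[["F value"]][1],
           df = s[["Df"]][1], p = s[["Pr(>F)"]][1])
  } else {
    tab <- table(v, g)
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    tibble(test = "chi-square", statistic = unname(ct$statistic),
           df = unname(ct$parameter), p = ct$p.value)
  }
}

#' Restricted cubic spline basis
#'
#' Truncated-power restricted cubic spline basis (linear tails beyond the
#' boundary knots), normalized by the squared knot range. With `k` knots the
#' basis has `k - 1` columns (the linear term plus `k - 2` spline terms).
#'
#' @param x Numeric vector.
#' @param knots Interior + boundary knot locations (ascending).
#' @return A matrix with `length(knots) - 1` columns.
#' @export
rcs_basis <- function(x, knots) {
  k <- length(knots)
  if (k < 3) abort("need at least 3 knots")
  if (any(diff(knots) <= 0))
    abort("duplicate or unsorted knots: x is too degenerate for a spline fit")
  tk <- knots[k]; tk1 <- knots[k - 1]
  norm2 <- (tk - knots[1])^2
  pp <- function(u) pmax(u, 0)^3
  out <- matrix(NA_real_, length(x), k - 1)
  out[, 1] <- x
  for (j in seq_len(k - 2)) {
    tj <- knots[j]
    out[, j + 1] <- (pp(x - tj) - pp(x - tk1) * (tk - tj) / (tk - tk1) +
                       pp(x - tk) * (tk1 - tj) / (tk - tk1)) / norm2
  }
  colnames(out) <- c("x", paste0("x'", seq_len(k - 2)))
  out
}

#' Restricted cubic spline regression
#'
#' Ordinary-least-squares fit of `y` on a restricted cubic spline basis of
#' `x` with knots at stated percentiles (default the 10th, 50th, and 90th).
#' The fitted curve is linear beyond the boundary knots.
#'
#' @param data A data frame.
#' @param x,y Unquoted predictor and response columns.
#' @param n_knots Number of knots (default 3).
#' @param probs Knot percentiles; default `c(0.10, 0.50, 0.90)` for 3 knots,
#'   equally spaced quantiles otherwise.
#' @return An object of class `rcs_fit` with methods [predict.rcs_fit()],
#'   [tidy.rcs_fit()], [glance.rcs_fit()], and [autoplot.rcs_fit()].
#' @export
rcs_regression <- function(data, x, y, n_knots = 3, probs = NULL) {
  xv <- eval_tidy(enquo(x), data)
  yv <- eval_tidy(enquo(y), data)
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) <= 10) abort("need more than 10 complete pairs")
  probs <- probs %||%
    (if (n_knots == 3) c(0.10, 0.50, 0.90)
     else seq(0.05, 0.95, length.out = n_knots))
  knots <- unname(quantile(xv, probs, type = 7))
  if (any(diff(knots) <= 0))
    abort("duplicate knots: x has too few distinct values")
  B <- rcs_basis(xv, knots)
  df <- data.frame(.y = yv, B)
  names(df) <- c(".y", paste0("b", seq_len(ncol(B))))
  fit <- lm(.y ~ ., data = df)
  structure(list(fit = fit, knots = knots, x = xv, y = yv,
                 x_name = as_name(enquo(x)), y_name = as_name(enquo(y))),
            class = "rcs_fit")
}

#' @rdname rcs_regression
#' @param object An `rcs_fit`.
#' @param newdata Numeric vector of predictor values (default: a 200-point
#'   grid over the observed range).
#' @param level Confidence level for the pointwise interval.
#' @param ... Unused.
#' @export
predict.rcs_fit <- function(object, newdata = NULL, level = 0.95, ...) {
  xg <- newdata %||% seq(min(object$x), max(object$x), length.out = 200)
  B <- rcs_basis(xg, object$knots)
  df <- as.data.frame(B)
  names(df) <- paste0("b", seq_len(ncol(B)))
  pr <- predict(object$fit, newdata = df, interval = "confidence",
                level = level)
  tibble(x = xg, fit = unname(pr[, "fit"]), conf_low = unname(pr[, "lwr"]),
         conf_high = unname(pr[, "upr"]))
}

#' @rdname rcs_regression
#' @param x An `rcs_fit` (for `tidy`).
#' @export
tidy.rcs_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std_error = s[, 2],
         statistic = s[, 3], p_value = s[, 4])
}

#' @rdname rcs_regression
#' @export
glance.rcs_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))
  tibble(r_squared = s$r.squared, adj_r_squared = s$adj.r.squared,
         sigma = s$sigma, df_residual = x$fit$df.residual,
         n = length(x$x), n_knots = length(x$knots))
}

#' @rdname rcs_regression
#' @export
autoplot.rcs_fit <- function(object, ...) {
  pr <- predict(object)
  ggplot2::ggplot(pr, ggplot2::aes(x = .data$x, y = .data$fit)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf_low,
                                      ymax = .data$conf_high),
                         alpha = 0.25, fill = "steelblue") +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = object$x_name, y = object$y_name) +
    ggplot2::theme_minimal()
}

#' @export
print.rcs_fit <- function(x, ...) {
  cat("<rcs_fit>", x$y_name, "~ rcs(", x$x_name, "), knots at",
      paste(signif(x$knots, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Bland-Altman method comparison
#'
#' Computes per-pair differences `d = x - y`, the mean difference, and the
#' 95% limits of agreement `mean(d) +/- 1.96 sd(d)`.
#'
#' @param data Optional data frame (then `x`, `y` are unquoted columns); or
#'   two numeric vectors.
#' @param x,y The two paired measurements.
#' @return An object of class `bland_altman`; [glance.bland_altman()] gives
#'   `mean_diff`, `loa_low`, `loa_high`, `sd_diff`, `n`.
#' @export
bland_altman <- function(data, x, y) {
  if (is.data.frame(data)) {
    xv <- eval_tidy(enquo(x), data)
    yv <- eval_tidy(enquo(y), data)
    nms <- c(as_name(enquo(x)), as_name(enquo(y)))
  } else {
    xv <- data; yv <- x
    nms <- c("x", "y")
  }
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3) abort("need at least 3 complete pairs")
  d <- xv - yv
  m <- mean(d)
  s <- sd(d)
  structure(list(data = tibble(mean = (xv + yv) / 2, diff = d),
                 mean_diff = m, sd_diff = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
                 n = length(d), names = nms),
            class = "bland_altman")
}

#' @rdname bland_altman
#' @param x A `bland_altman` object (for `glance`).
#' @param ... Unused.
#' @export
glance.bland_altman <- function(x, ...) {
  tibble(mean_diff = x$mean_diff, loa_low = x$loa_low,
         loa_high = x$loa_high, sd_diff = x$sd_diff, n = x$n)
}

#' @rdname bland_altman
#' @param object A `bland_altman` object.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = object$mean_diff, color = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", color = "firebrick") +
    ggplot2::labs(x = paste0("mean of ", object$names[1], " and ",
                             object$names[2]),
                  y = paste0(object$names[1], " - ", object$names[2])) +
    ggplot2::theme_minimal()
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> n = %d, mean diff = %.3f, LoA = (%.3f, %.3f)\n",
    x$n, x$mean_diff, x$loa_low, x$loa_high))
  invisible(x)
}
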