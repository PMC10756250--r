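# variables summarised in cohort reports, in display order
mri_variables <- function() {
  c("ps_length", "height", "width", "ps_volume", "lens_volume", "ac_volume",
    "sphericity_v", "sphericity_h")
}
ocular_variables <- function() {
  c("se", "al_cr_ratio", "al_biometry", "cr", "acd_biometry", "al_growth")
}
other_variables <- function() {
  c("body_height", "birth_weight", "gestational_age")
}

#' Reference group-mean ocular biometry (published values)
#'
#' Group-conditional means of MRI and optical biometry from a published
#' population-based MRI study of 10-year-old children, one row per refraction
#' group. Volumes are in mm^3, lengths in mm. These printed values serve as
#' inputs to the report stage (e.g. [group_differences()]) and as calibration
#' targets for the phantom generator.
#'
#' @return A tibble with columns `group`, `height`, `width`, `ps_length`,
#'   `ps_volume`, `lens_volume`, `ac_volume`, `al_biometry`, `cr`,
#'   `al_cr_ratio`.
#' @export
reference_group_biometry <- function() {
  tibble::tribble(
    ~group, ~height, ~width, ~ps_length, ~ps_volume, ~lens_volume,
    ~ac_volume, ~al_biometry, ~cr, ~al_cr_ratio,
    "hyperopia",  22.9, 23.3, 16.2, 5800, 81, 220, 22.04, 7.76, 2.84,
    "emmetropia", 23.5, 23.7, 16.9, 6300, 84, 240, 23.07, 7.79, 2.96,
    "myopia",     24.1, 24.0, 17.7, 6770, 88, 250, 23.98, 7.72, 3.11)
}

#' Reference whole-cohort ocular means (published values)
#'
#' Cohort-level means and SDs from the same published study: the key MRI
#' biometrics, the optical-biometry axial length, and the mean MRI axial
#' length. Used as report-stage inputs and generator calibration targets.
#'
#' @return A tibble with columns `variable`, `mean`, `sd`.
#' @export
reference_cohort_biometry <- function() {
  tibble::tribble(
    ~variable, ~mean, ~sd,
    "ps_length", 17.02, 0.80,
    "height", 23.57, 0.95,
    "width", 23.73, 0.95,
    "ps_volume", 6350, 680,
    "lens_volume", 84, 13,
    "ac_volume", 240, 35,
    "al_mri", 22.94, 0.94,
    "al_biometry", 23.11, 0.83,
    "se", 0.74, 1.30,
    "sphericity_v", 0.042, 0.068,
    "sphericity_h", 0.056, 0.066)
}

#' Pairwise refraction-group differences of biometry means
#'
#' Given per-group means (measured, or printed reference values via
#' [reference_group_biometry()]), computes the myopia-minus-emmetropia and
#' myopia-minus-hyperopia differences for every numeric variable.
#'
#' @param group_means A tibble with a `group` column (containing `myopia`,
#'   `emmetropia`, `hyperopia`) and numeric variable columns.
#' @return A tibble: `variable`, `myopia_minus_emmetropia`,
#'   `myopia_minus_hyperopia`.
#' @export
#' @examples
#' group_differences(reference_group_biometry())
group_differences <- function(group_means) {
  num_vars <- names(group_means)[vapply(group_means, is.numeric, logical(1))]
  row_of <- function(g) group_means[group_means$group == g, num_vars,
                                    drop = FALSE]
  myo <- row_of("myopia"); emm <- row_of("emmetropia")
  hyp <- row_of("hyperopia")
  if (nrow(myo) != 1 || nrow(emm) != 1 || nrow(hyp) != 1)
    abort("`group_means` must contain one row per refraction group")
  tibble(variable = num_vars,
         myopia_minus_emmetropia = as.numeric(myo[1, ]) - as.numeric(emm[1, ]),
         myopia_minus_hyperopia = as.numeric(myo[1, ]) - as.numeric(hyp[1, ]))
}

#' Total eye volume from compartment volumes
#'
#' Sum of the posterior segment, lens, and anterior chamber volumes, rounded
#' to the reporting precision of 10 mm^3.
#'
#' @param ps_volume,lens_volume,ac_volume Compartment volumes (mm^3).
#' @param digits Rounding (default nearest 10 mm^3).
#' @return Total volume (mm^3).
#' @export
total_eye_volume <- function(ps_volume, lens_volume, ac_volume,
                             digits = -1) {
  round(ps_volume + lens_volume + ac_volume, digits)
}

prepare_cohort <- function(cohort) {
  cohort <- as_tibble(cohort)
  if (!"se" %in% names(cohort) &&
      all(c("sphere", "cylinder") %in% names(cohort)))
    cohort$se <- spherical_equivalent(cohort$sphere, cohort$cylinder)
  if (!"al_cr_ratio" %in% names(cohort) &&
      all(c("al_biometry", "cr") %in% names(cohort)))
    cohort$al_cr_ratio <- cohort$al_biometry / cohort$cr
  if (!"group" %in% names(cohort) && "se" %in% names(cohort))
    cohort$group <- refraction_group(cohort$se)
  cohort
}

summarise_variables <- function(data, vars) {
  vars <- intersect(vars, names(data))
  purrr::map_dfr(vars, function(v) {
    x <- data[[v]]
    if (!is.numeric(x)) return(tibble())
    x <- x[is.finite(x)]
    tibble(variable = v, mean = mean(x), sd = sd(x), n = length(x))
  })
}

#' Build the cohort report tables
#'
#' Renders the standard report of a refractive-error MRI cohort:
#' descriptives (mean/SD overall and by sex), the correlation matrix between
#' optical/anthropometric measurements and MRI biometrics with significance
#' stars, per-group means with ANOVA p values, pairwise group differences,
#' and the oblate/spherical/prolate percentages per group with a chi-square
#' test. No multiple-testing correction is applied (noted in the footer).
#'
#' @param cohort A tibble with one analysis row per subject (biometry merged
#'   with refraction/biometry records). Columns are picked up by name; absent
#'   columns are skipped. An empty cohort yields headers-only tables.
#' @return A list of class `cohort_report` with elements `descriptives`,
#'   `correlations`, `group_means`, `group_differences`, `shape_by_group`,
#'   and `footer`.
#' @export
build_report <- function(cohort) {
  cohort <- prepare_cohort(cohort)
  empty <- nrow(cohort) == 0
  all_vars <- c(mri_variables(), ocular_variables(), other_variables())

  descriptives <- if (empty) {
    tibble(variable = character(), mean = double(), sd = double(),
           n = integer())
  } else {
    d <- summarise_variables(cohort, all_vars)
    if (all(c("ps_volume", "lens_volume", "ac_volume") %in% d$variable)) {
      gv <- function(v) d$mean[d$variable == v]
      d <- dplyr::bind_rows(d, tibble(
        variable = "total_eye_volume",
        mean = total_eye_volume(gv("ps_volume"), gv("lens_volume"),
                                gv("ac_volume")),
        sd = NA_real_, n = max(d$n)))
    }
    d
  }

  by_sex <- if (!empty && "sex" %in% names(cohort)) {
    cohort |>
      dplyr::group_by(.data$sex) |>
      dplyr::group_modify(~ summarise_variables(.x, all_vars)) |>
      dplyr::ungroup()
  } else {
    tibble(sex = character(), variable = character(), mean = double(),
           sd = double(), n = integer())
  }

  row_vars <- intersect(c(ocular_variables(), other_variables()),
                        names(cohort))
  col_vars <- intersect(mri_variables(), names(cohort))
  correlations <- if (empty || length(row_vars) == 0 ||
                      length(col_vars) == 0) {
    tibble(measure = character(), mri_variable = character(), r = double(),
           p = double(), stars = character())
  } else {
    tidyr::expand_grid(measure = row_vars, mri_variable = col_vars) |>
      dplyr::mutate(purrr::map2_dfr(.data$measure, .data$mri_variable,
        function(a, b) {
          ok <- is.finite(cohort[[a]]) & is.finite(cohort[[b]])
          if (sum(ok) < 3 || sd(cohort[[a]][ok]) == 0 ||
              sd(cohort[[b]][ok]) == 0)
            return(tibble(r = NA_real_, p = NA_real_))
          pearson(cohort[[a]][ok], cohort[[b]][ok])[, c("r", "p")]
        })) |>
      dplyr::mutate(stars = dplyr::case_when(
        is.na(.data$p) ~ "", .data$p < 0.01 ~ "**",
        .data$p < 0.05 ~ "*", TRUE ~ ""))
  }

  have_groups <- !empty && "group" %in% names(cohort) &&
    all(c("myopia", "emmetropia", "hyperopia") %in% cohort$group)
  gm_vars <- intersect(c(mri_variables(), "al_biometry", "cr",
                         "al_cr_ratio"), names(cohort))
  group_means <- if (!have_groups || length(gm_vars) == 0) {
    tibble(group = character())
  } else {
    cohort |>
      dplyr::group_by(group = factor(.data$group,
                                     c("hyperopia", "emmetropia",
                                       "myopia"))) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(gm_vars),
                                     ~ mean(.x[is.finite(.x)])),
                       .groups = "drop")
  }
  anova_p <- if (!have_groups || length(gm_vars) == 0) {
    tibble(variable = character(), p = double())
  } else {
    purrr::map_dfr(gm_vars, function(v) {
      tibble(variable = v,
             p = group_compare(cohort, !!rlang::sym(v))$p)
    })
  }
  gdiff <- if (have_groups && length(gm_vars) > 0)
    group_differences(group_means)
  else tibble(variable = character(), myopia_minus_emmetropia = double(),
              myopia_minus_hyperopia = double())

  shape_by_group <- if (have_groups && "shape_h" %in% names(cohort)) {
    tab <- cohort |>
      dplyr::filter(!is.na(.data$shape_h)) |>
      dplyr::count(group = factor(.data$group,
                                  c("hyperopia", "emmetropia", "myopia")),
                   shape = .data$shape_h) |>
      dplyr::group_by(.data$group) |>
      dplyr::mutate(percent = 100 * .data$n / sum(.data$n)) |>
      dplyr::ungroup()
    tab
  } else {
    tibble(group = character(), shape = character(), n = integer(),
           percent = double())
  }

  structure(list(descriptives = descriptives, by_sex = by_sex,
                 correlations = correlations, group_means = group_means,
                 anova_p = anova_p, group_differences = gdiff,
                 shape_by_group = shape_by_group,
                 footer = paste("Uncorrected p values; no multiple-testing",
                                "adjustment applied.")),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\n-- Descriptives --\n")
  print(dplyr::mutate(x$descriptives,
                      dplyr::across(dplyr::where(is.numeric), ~ signif(.x, 4))),
        n = 30)
  if (nrow(x$group_means)) {
    cat("-- Group means --\n")
    print(dplyr::mutate(x$group_means,
                        dplyr::across(dplyr::where(is.numeric),
                                      ~ signif(.x, 4))))
  }
  cat(x$footer, "\n")
  invisible(x)
}

#' Write the report tables as CSV files
#'
#' @param report A [build_report()] result.
#' @param dir Output directory.
#' @return File paths, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  parts <- c("descriptives", "by_sex", "correlations", "group_means",
             "anova_p", "group_differences", "shape_by_group")
  paths <- purrr::map_chr(parts, function(p) {
    path <- file.path(dir, paste0("report_", p, ".csv"))
    readr::write_csv(report[[p]], path)
    path
  })
  invisible(paths)
}
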