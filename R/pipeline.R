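#' Configuration of a full pipeline run
#'
#' Bundles every stage's settings with the run seed and output location.
#' Thresholds of record: background bias 0.5, atlas probability floor 0.01,
#' sphericity threshold 0.005, refraction cut-offs -0.5 D / +2.0 D.
#'
#' @param out_dir Run directory (created if needed).
#' @param n Number of synthetic subjects.
#' @param k Cross-validation folds.
#' @param seed Integer master seed; stage seeds are derived from it and
#'   recorded in the manifest.
#' @param cohort A [cohort_config()].
#' @param grid A [grid_config()].
#' @param seg A [seg_config()].
#' @param segmentation `"crossval"` runs the full segmentation
#'   cross-validation and measures the predicted label maps; `"none"`
#'   measures the ground-truth label maps (generator validation runs).
#' @param eye Which eye enters the per-subject analysis: `"right"` (default)
#'   or `"mean"` of both.
#' @param sphericity_threshold Shape-classification threshold.
#' @param swap_sphericity_labels See [measure_biometry()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("oculometry_run_"),
                            n = 12L, k = 3L, seed = 1L,
                            cohort = cohort_config(), grid = grid_config(),
                            seg = seg_config(),
                            segmentation = c("crossval", "none"),
                            eye = c("right", "mean"),
                            sphericity_threshold = 0.005,
                            swap_sphericity_labels = FALSE) {
  structure(list(out_dir = out_dir, n = as.integer(n), k = as.integer(k),
                 seed = as.integer(seed), cohort = cohort, grid = grid,
                 seg = seg, segmentation = match.arg(segmentation),
                 eye = match.arg(eye),
                 sphericity_threshold = sphericity_threshold,
                 swap_sphericity_labels = swap_sphericity_labels),
            class = "pipeline_config")
}

stage_fail <- function(stage, e) {
  abort(paste0("pipeline stage '", stage, "' failed: ",
               conditionMessage(e)))
}

#' Run the full pipeline: generate, segment, measure, report
#'
#' Executes the four stages on a synthetic cohort: phantom generation (NIfTI
#' scans, ground-truth labels, cohort CSV), segmentation cross-validation (or
#' none), 3D biometry of the resulting label maps, and the cohort report.
#' All randomness derives from `config$seed`; re-running with the same
#' configuration reproduces all CSV outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list: `out_dir`, `manifest`, `cohort`, `biometry`,
#'   `analysis`, `report`, and (when segmentation ran) `dice_report`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cohort_dir <- file.path(out_dir, "cohort")
  if (config$k > config$n && config$segmentation == "crossval")
    stage_fail("crossval",
               simpleError("k exceeds the number of subjects"))

  manifest <- tryCatch(
    generate_cohort(config$n, cohort_dir, config$cohort, config$grid,
                    seed = config$seed),
    error = function(e) stage_fail("generate", e))
  records <- readr::read_csv(file.path(cohort_dir, "cohort.csv"),
                             show_col_types = FALSE)

  subjects <- purrr::map(manifest$subjects, function(id) {
    list(id = id,
         scan = read_scan(file.path(cohort_dir, paste0(id, "_scan.nii.gz")),
                          subject_id = id),
         labels = read_labels(
           file.path(cohort_dir, paste0(id, "_labels.nii.gz")),
           subject_id = id),
         group = records$group_true[records$subject_id == id])
  })

  dice_report <- NULL
  measured_maps <- purrr::map(subjects, "labels")
  if (config$segmentation == "crossval" && config$n > 0) {
    dice_report <- tryCatch(
      cross_validate(subjects, k = config$k, config = config$seg,
                     seed = config$seed + 1L, return_predictions = TRUE),
      error = function(e) stage_fail("crossval", e))
    measured_maps <- dice_report$predictions
    readr::write_csv(dice_report$summary,
                     file.path(out_dir, "dice_summary.csv"))
    readr::write_csv(dice_report$per_subject,
                     file.path(out_dir, "dice_per_subject.csv"))
  }

  biometry <- tryCatch(
    measure_cohort(measured_maps,
                   threshold = config$sphericity_threshold,
                   swap_sphericity_labels = config$swap_sphericity_labels),
    error = function(e) stage_fail("measure", e))
  readr::write_csv(biometry, file.path(out_dir, "biometry.csv"))

  analysis <- tryCatch({
    bio <- if (config$eye == "right") {
      dplyr::filter(biometry, .data$side == "right")
    } else {
      biometry |>
        dplyr::group_by(.data$subject_id) |>
        dplyr::summarise(dplyr::across(dplyr::where(is.numeric), mean),
                         shape_h = .data$shape_h[1],
                         shape_v = .data$shape_v[1], .groups = "drop")
    }
    dplyr::left_join(records, bio, by = "subject_id")
  }, error = function(e) stage_fail("measure", e))

  excl <- apply_exclusions(analysis)
  report <- tryCatch(build_report(excl$cohort),
                     error = function(e) stage_fail("report", e))
  readr::write_csv(analysis, file.path(out_dir, "analysis_cohort.csv"))
  readr::write_csv(excl$log, file.path(out_dir, "exclusion_log.csv"))
  write_report(report, out_dir)

  run_manifest <- list(
    seed = config$seed,
    config_hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("oculometry")),
    n = config$n, k = config$k, segmentation = config$segmentation,
    stages = c("generate", config$segmentation, "measure", "report"),
    exclusions = as.list(setNames(excl$log$n, excl$log$reason)))
  jsonlite::write_json(run_manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(out_dir = out_dir, manifest = run_manifest,
                 cohort = records, biometry = biometry,
                 analysis = excl$cohort, exclusion_log = excl$log,
                 report = report, dice_report = dice_report))
}
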