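#' Write the cohort report as JSON
#'
#' Serializes the stratified summaries, test results, median splits and
#' separation counts of a [summarize_cohort()] report (the patient-level
#' table is kept out of the JSON; it travels in `patient_metrics.csv` /
#' `d50_fits.csv`).
#'
#' @param report A `cohort_report`.
#' @param path Output path for `cohort_report.json`.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "cohort_report"))
  out <- list(
    n_patients = report$n_patients,
    by_aggressiveness = report$by_aggressiveness,
    by_phase = report$by_phase,
    tests = report$tests,
    splits = report$splits,
    separation_counts = report$separation$counts
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

ledger_to_json <- function(ledger, path) {
  jsonlite::write_json(
    list(n_input = ledger$n_input,
         retained = ledger$retained,
         rules = lapply(ledger$rules, function(r)
           list(count = r$count, patient_ids = r$patient_ids))),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run the full study pipeline
#'
#' One reproducible pass over a cohort: load (or simulate) the input tables,
#' compute the healthy-control baseline, fit the D50 model per patient,
#' apply the exclusion rules, derive M50 / MUSIX200 / CMAP50, and build the
#' stratified cohort report. Artifacts written to `out_dir`: `d50_fits.csv`,
#' `patient_metrics.csv`, `cohort_report.json`, `survival_summary.csv`,
#' `exclusion_ledger.json` and `run_manifest.json`. Identical inputs and
#' seed give identical artifacts.
#'
#' @param input_dir Directory holding `alsfrs.csv`, `munix_panels.csv`,
#'   `survival.csv`, `metadata.csv`, `controls.csv` (e.g. written by
#'   [write_synthetic_cohort()]). Exactly one of `input_dir` and
#'   `generator` must be given.
#' @param generator A [generator_config()]; the cohort is simulated with
#'   `seed` and also written to `out_dir/input/`.
#' @param out_dir Output directory for artifacts (default: no files
#'   written, results only returned).
#' @param seed Seed for the simulation branch.
#' @param exclusion_config Passed to [apply_exclusions()].
#' @return List with `report` (a `cohort_report`), `fits`, `metrics`,
#'   `ledger`, `baseline`, and `truth` (simulation branch only).
#' @export
run_study <- function(input_dir = NULL, generator = NULL, out_dir = NULL,
                      seed = 1, exclusion_config = list()) {
  if (is.null(input_dir) == is.null(generator)) {
    stop("provide exactly one of `input_dir` or `generator`", call. = FALSE)
  }
  truth <- NULL
  if (!is.null(generator)) {
    sim <- generate_cohort(generator, seed = seed)
    input_dir <- file.path(out_dir %||% tempfile("munixd50_"), "input")
    write_synthetic_cohort(sim, input_dir)
    truth <- sim$truth
  }
  need <- c("alsfrs.csv", "munix_panels.csv", "survival.csv", "controls.csv")
  missing <- need[!file.exists(file.path(input_dir, need))]
  if (length(missing) > 0) {
    stop(sprintf("stage cohort_io: missing input file(s) %s in %s",
                 paste(missing, collapse = ", "), input_dir), call. = FALSE)
  }
  meta_path <- file.path(input_dir, "metadata.csv")
  cohort <- read_cohort(file.path(input_dir, "alsfrs.csv"),
                        file.path(input_dir, "munix_panels.csv"),
                        file.path(input_dir, "survival.csv"),
                        if (file.exists(meta_path)) meta_path)
  controls <- utils::read.csv(file.path(input_dir, "controls.csv"),
                              stringsAsFactors = FALSE)
  baseline <- control_baseline(controls)

  fits_all <- fit_d50_cohort(cohort$alsfrs)
  excl <- apply_exclusions(cohort, baseline, fits = fits_all,
                           config = exclusion_config)
  kept <- excl$cohort
  fits <- fits_all[fits_all$patient_id %in% kept$patient_ids, ]
  metrics <- cohort_metrics(kept$panels, baseline)
  report <- summarize_cohort(fits, metrics, kept$survival)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(fits, file.path(out_dir, "d50_fits.csv"),
                     row.names = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "patient_metrics.csv"),
                     row.names = FALSE)
    write_report(report, file.path(out_dir, "cohort_report.json"))
    if (!is.null(report$survival_summary)) {
      utils::write.csv(report$survival_summary,
                       file.path(out_dir, "survival_summary.csv"),
                       row.names = FALSE)
    }
    ledger_to_json(excl$ledger, file.path(out_dir, "exclusion_ledger.json"))
    manifest <- list(
      package = "munixd50",
      version = as.character(utils::packageVersion("munixd50")),
      seed = seed,
      simulated = !is.null(generator),
      n_input = excl$ledger$n_input,
      n_retained = length(excl$ledger$retained))
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  list(report = report, fits = fits, metrics = metrics,
       ledger = excl$ledger, baseline = baseline, truth = truth)
}
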