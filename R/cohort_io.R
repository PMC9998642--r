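#' @importFrom utils read.csv write.csv
NULL

read_table_checked <- function(path, required, label) {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: %s", label, path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing mandatory column(s) %s", label,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df$patient_id <- as.character(df$patient_id)
  df
}

validate_alsfrs <- function(alsfrs) {
  bad <- which(alsfrs$alsfrs_r_total < 0 | alsfrs$alsfrs_r_total > 48)
  if (length(bad) > 0) {
    stop(sprintf("alsfrs: ALSFRS-R total outside the 0-48 scale at row(s) %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  bad_t <- which(alsfrs$t_months < 0)
  if (length(bad_t) > 0) {
    stop(sprintf("alsfrs: negative time since onset at row(s) %s",
                 paste(bad_t, collapse = ", ")), call. = FALSE)
  }
  invisible(alsfrs)
}

validate_panels <- function(panels) {
  bad_m <- which(!panels$muscle %in% MUSCLES)
  if (length(bad_m) > 0) {
    stop(sprintf("munix_panels: unknown muscle at row(s) %s",
                 paste(bad_m, collapse = ", ")), call. = FALSE)
  }
  dup <- duplicated(panels[, c("patient_id", "muscle")])
  if (any(dup)) {
    stop(sprintf("munix_panels: duplicate (patient, muscle) at row(s) %s",
                 paste(which(dup), collapse = ", ")), call. = FALSE)
  }
  bad_t <- which(panels$t_munix_months <= 0)
  if (length(bad_t) > 0) {
    stop(sprintf("munix_panels: non-positive measurement time at row(s) %s",
                 paste(bad_t, collapse = ", ")), call. = FALSE)
  }
  invisible(panels)
}

#' Read and validate a MUNIX/ALSFRS-R cohort
#'
#' Loads the four long-format CSV tables of a study cohort, validates them
#' (score range, muscle panel completeness, positive times), sorts ALSFRS-R
#' observations by time within patient, and keeps only patients present in
#' all three mandatory tables (ALSFRS-R, MUNIX panels, survival). Patients
#' dropped at this stage are recorded in `dropped_incomplete`.
#'
#' @param path_alsfrs CSV with columns `patient_id`, `t_months`,
#'   `alsfrs_r_total` (optional subscores).
#' @param path_panels CSV with columns `patient_id`, `t_munix_months`,
#'   `side`, `muscle`, `munix`, `cmap_mV`, `obtainable`.
#' @param path_survival CSV with columns `patient_id`, `time_months`, `event`.
#' @param path_metadata Optional CSV with `patient_id` plus demographic /
#'   diagnostic flags (`gold_coast`, `juvenile`, `age_at_measurement`, ...).
#' @return Object of class `als_cohort`: list of data frames `alsfrs`,
#'   `panels`, `survival`, `metadata` (NULL if not given), character vector
#'   `patient_ids`, and `dropped_incomplete`.
#' @export
read_cohort <- function(path_alsfrs, path_panels, path_survival,
                        path_metadata = NULL) {
  alsfrs <- read_table_checked(path_alsfrs,
                               c("patient_id", "t_months", "alsfrs_r_total"),
                               "alsfrs")
  panels <- read_table_checked(path_panels,
                               c("patient_id", "t_munix_months", "side",
                                 "muscle", "munix", "cmap_mV", "obtainable"),
                               "munix_panels")
  surv <- read_table_checked(path_survival,
                             c("patient_id", "time_months", "event"),
                             "survival")
  meta <- if (!is.null(path_metadata)) {
    read_table_checked(path_metadata, "patient_id", "metadata")
  }
  validate_alsfrs(alsfrs)
  validate_panels(panels)
  if (any(surv$time_months <= 0)) {
    stop("survival: time_months must be positive", call. = FALSE)
  }
  panels$obtainable <- as.logical(panels$obtainable)
  surv$event <- as.logical(surv$event)

  complete_panel <- names(which(tapply(panels$muscle, panels$patient_id,
                                       function(m) setequal(m, MUSCLES))))
  ids <- Reduce(intersect, list(unique(alsfrs$patient_id), complete_panel,
                                unique(surv$patient_id)))
  all_ids <- unique(c(alsfrs$patient_id, panels$patient_id, surv$patient_id))
  dropped <- setdiff(all_ids, ids)
  if (length(dropped) > 0) {
    message(sprintf("read_cohort: %d patient(s) absent from a mandatory table, dropped: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }

  alsfrs <- alsfrs[alsfrs$patient_id %in% ids, ]
  alsfrs <- alsfrs[order(alsfrs$patient_id, alsfrs$t_months), ]
  rownames(alsfrs) <- NULL
  panels <- panels[panels$patient_id %in% ids, ]
  surv <- surv[surv$patient_id %in% ids, ]
  if (!is.null(meta)) meta <- meta[meta$patient_id %in% ids, ]

  structure(list(alsfrs = alsfrs, panels = panels, survival = surv,
                 metadata = meta, patient_ids = ids,
                 dropped_incomplete = dropped),
            class = "als_cohort")
}

#' @export
print.als_cohort <- function(x, ...) {
  cat(sprintf("ALS cohort: %d patients, %d ALSFRS-R observations\n",
              length(x$patient_ids), nrow(x$alsfrs)))
  if (length(x$dropped_incomplete) > 0) {
    cat(sprintf("  (%d id(s) dropped for incomplete tables)\n",
                length(x$dropped_incomplete)))
  }
  invisible(x)
}

meta_flag <- function(meta, ids, col, default) {
  out <- rep(default, length(ids))
  if (!is.null(meta) && col %in% names(meta)) {
    idx <- match(ids, meta$patient_id)
    val <- meta[[col]][idx]
    out <- ifelse(is.na(val), default, as.logical(val))
  }
  out
}

meta_num <- function(meta, ids, col) {
  out <- rep(NA_real_, length(ids))
  if (!is.null(meta) && col %in% names(meta)) {
    out <- as.numeric(meta[[col]][match(ids, meta$patient_id)])
  }
  out
}

#' Apply the study exclusion rules
#'
#' Screens a cohort with the exclusion rules in their reporting order; the
#' first matching rule claims a patient, so the ledger counts are disjoint
#' and sum with the retained count to the input size:
#' \enumerate{
#'   \item `gold_coast` — Gold Coast diagnostic criteria not fulfilled;
#'   \item `more_affected_side` — MUNIX measured on the clinically more
#'     affected side;
#'   \item `few_alsfrs` — fewer than two ALSFRS-R questionnaires;
#'   \item `juvenile` — juvenile ALS;
#'   \item `no_munix_decrease` — mean MUNIX sum at or above the healthy
#'     control mean, so no M50 can be calculated;
#'   \item `life_expectancy` — M50 beyond any plausible lifespan (onset age
#'     + M50 exceeding `max_age_years` when age is known, otherwise M50 >
#'     `max_m50_months`).
#' }
#' A seventh rule, `non_identifiable_fit`, is applied when D50 fits are
#' supplied: flat or rising ALSFRS-R series carry no decay information.
#'
#' @param cohort An [read_cohort()] object.
#' @param baseline A [control_baseline()] object (for rule 5/6 ratios).
#' @param fits Optional [fit_d50_cohort()] table (enables rule 7).
#' @param config List of cutoffs: `max_age_years` (default 100),
#'   `max_m50_months` (default 720).
#' @return List with `cohort` (the retained subset, still an `als_cohort`)
#'   and `ledger` (class `exclusion_ledger`).
#' @export
apply_exclusions <- function(cohort, baseline, fits = NULL,
                             config = list()) {
  stopifnot(inherits(cohort, "als_cohort"))
  max_age <- config$max_age_years %||% 100
  max_m50 <- config$max_m50_months %||% 720
  ids <- cohort$patient_ids
  meta <- cohort$metadata

  metrics <- if (length(ids) > 0) cohort_metrics(cohort$panels, baseline)
  midx <- function(id) match(id, metrics$patient_id)

  n_obs <- table(factor(cohort$alsfrs$patient_id, levels = ids))
  side <- tapply(cohort$panels$side, cohort$panels$patient_id, `[`, 1)[ids]
  gold <- meta_flag(meta, ids, "gold_coast", TRUE)
  juvenile <- meta_flag(meta, ids, "juvenile", FALSE)
  age_meas <- meta_num(meta, ids, "age_at_measurement")

  rules <- c("gold_coast", "more_affected_side", "few_alsfrs", "juvenile",
             "no_munix_decrease", "life_expectancy", "non_identifiable_fit")
  assigned <- setNames(rep(NA_character_, length(ids)), ids)

  for (i in seq_along(ids)) {
    id <- ids[i]
    m <- metrics[midx(id), ]
    t_meas <- m$t_munix_months
    rule <- if (!gold[i]) {
      "gold_coast"
    } else if (identical(side[[i]], "more_affected")) {
      "more_affected_side"
    } else if (n_obs[[id]] < 2) {
      "few_alsfrs"
    } else if (juvenile[i]) {
      "juvenile"
    } else if (m$munix_ratio >= 1) {
      "no_munix_decrease"
    } else if (!is.na(age_meas[i]) &&
               (age_meas[i] - t_meas / 12) + m$m50 / 12 > max_age) {
      "life_expectancy"
    } else if (is.na(age_meas[i]) && m$m50 > max_m50) {
      "life_expectancy"
    } else if (!is.null(fits) &&
               !fits$identifiable[match(id, fits$patient_id)]) {
      "non_identifiable_fit"
    } else {
      NA_character_
    }
    assigned[i] <- rule
  }

  retained_ids <- ids[is.na(assigned)]
  ledger <- structure(list(
    rules = lapply(setNames(rules, rules), function(r) {
      hit <- ids[!is.na(assigned) & assigned == r]
      list(count = length(hit), patient_ids = hit)
    }),
    retained = retained_ids,
    n_input = length(ids)
  ), class = "exclusion_ledger")

  kept <- cohort
  kept$alsfrs <- cohort$alsfrs[cohort$alsfrs$patient_id %in% retained_ids, ]
  kept$panels <- cohort$panels[cohort$panels$patient_id %in% retained_ids, ]
  kept$survival <- cohort$survival[cohort$survival$patient_id %in% retained_ids, ]
  if (!is.null(meta)) kept$metadata <- meta[meta$patient_id %in% retained_ids, ]
  kept$patient_ids <- retained_ids

  list(cohort = kept, ledger = ledger)
}

#' @export
print.exclusion_ledger <- function(x, ...) {
  cat(sprintf("Exclusion ledger: %d in, %d retained\n",
              x$n_input, length(x$retained)))
  for (r in names(x$rules)) {
    if (x$rules[[r]]$count > 0) {
      cat(sprintf("  %-22s %d\n", r, x$rules[[r]]$count))
    }
  }
  invisible(x)
}

#' Write the cohort tables back to CSV
#'
#' Inverse of [read_cohort()]; used for round-tripping retained cohorts.
#'
#' @param cohort An `als_cohort` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "als_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(alsfrs = file.path(dir, "alsfrs.csv"),
             panels = file.path(dir, "munix_panels.csv"),
             survival = file.path(dir, "survival.csv"))
  utils::write.csv(cohort$alsfrs, paths["alsfrs"], row.names = FALSE)
  utils::write.csv(cohort$panels, paths["panels"], row.names = FALSE)
  utils::write.csv(cohort$survival, paths["survival"], row.names = FALSE)
  if (!is.null(cohort$metadata)) {
    paths <- c(paths, metadata = file.path(dir, "metadata.csv"))
    utils::write.csv(cohort$metadata, paths["metadata"], row.names = FALSE)
  }
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
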