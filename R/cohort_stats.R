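#' Median split of a patient-level metric
#'
#' Splits patients at the cohort median of a metric into `low` (strictly
#' below the cutoff) and `high` (at or above it). Ties at the cutoff go to
#' `high`, matching the "under X months" labelling of the low group.
#'
#' @param values Numeric metric values; `NA`s (undefined metrics) are
#'   dropped before splitting.
#' @param ids Patient identifiers parallel to `values`.
#' @return Object of class `median_split`: list with `cutoff`, `assignment`
#'   (named character vector over the defined patients) and `degenerate`
#'   (TRUE when every value ties at the cutoff).
#' @export
median_split <- function(values, ids) {
  keep <- !is.na(values)
  values <- values[keep]; ids <- as.character(ids[keep])
  if (length(values) < 2) {
    stop("median split needs at least 2 defined values", call. = FALSE)
  }
  cutoff <- stats::median(values)
  assignment <- ifelse(values < cutoff, "low", "high")
  names(assignment) <- ids
  structure(list(cutoff = cutoff, assignment = assignment,
                 degenerate = all(values == cutoff)),
            class = "median_split")
}

#' Classify patients by M50/D50 median separation
#'
#' Patients whose M50 and D50 fall on the same side of their respective
#' cohort medians form the `same` separation group; the rest split into
#' `low_m50_high_d50` (early electrophysiological loss relative to clinical
#' course) and `high_m50_low_d50`.
#'
#' @param m50_split,d50_split [median_split()] objects over the same patients.
#' @return Named character vector patient -> separation group.
#' @export
separation_classify <- function(m50_split, d50_split) {
  ids <- names(m50_split$assignment)
  if (!setequal(ids, names(d50_split$assignment))) {
    stop("splits cover different patients", call. = FALSE)
  }
  m <- m50_split$assignment[ids]
  d <- d50_split$assignment[ids]
  out <- ifelse(m == d, "same",
                ifelse(m == "low" & d == "high",
                       "low_m50_high_d50", "high_m50_low_d50"))
  names(out) <- ids
  out
}

#' Kruskal-Wallis test with pairwise Bonferroni post-hocs
#'
#' Omnibus rank test across three groups (tie-corrected H statistic,
#' chi-square p with df = groups - 1), followed by all pairwise rank tests
#' with Bonferroni adjustment `p_adj = min(1, 3 * p_raw)`.
#'
#' @param values Numeric vector of metric values.
#' @param groups Grouping factor (3 non-empty levels).
#' @return List with `statistic`, `p_value`, `group_sizes`, and `pairwise`
#'   (data frame: group_a, group_b, statistic, p_raw, p_adj).
#' @export
kruskal_bonferroni <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- droplevels(groups[keep])
  sizes <- table(groups)
  if (length(sizes) < 2 || any(sizes == 0)) {
    stop("each group must be non-empty", call. = FALSE)
  }
  omni <- stats::kruskal.test(values, groups)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  n_pairs <- ncol(pairs)
  pw <- do.call(rbind, lapply(seq_len(n_pairs), function(k) {
    sel <- groups %in% pairs[, k]
    kt <- stats::kruskal.test(values[sel], droplevels(groups[sel]))
    data.frame(group_a = pairs[1, k], group_b = pairs[2, k],
               statistic = unname(kt$statistic), p_raw = kt$p.value,
               p_adj = min(1, n_pairs * kt$p.value),
               stringsAsFactors = FALSE)
  }))
  list(statistic = unname(omni$statistic), p_value = omni$p.value,
       group_sizes = as.integer(sizes), pairwise = pw)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; pairs with a missing value
#' on either side are dropped.
#'
#' @param x,y Paired numeric vectors.
#' @return List with `r`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator of the survivor function; the median is the
#' smallest event time at which the curve falls to 0.5 or below (undefined
#' when the curve never does).
#'
#' @param time_months Follow-up times from symptom onset (> 0).
#' @param event Logical; TRUE = death observed, FALSE = censored.
#' @return Object of class `km_curve`: list with `time`, `surv`, `n_risk`,
#'   `n_event`, `median` (NA when undefined), `n`.
#' @export
kaplan_meier <- function(time_months, event) {
  if (length(time_months) == 0) stop("empty survival input", call. = FALSE)
  if (any(time_months <= 0)) stop("survival times must be positive", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time_months, event) ~ 1)
  med <- if (any(fit$surv <= 0.5)) fit$time[which(fit$surv <= 0.5)[1]] else NA_real_
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, median = med,
                 n = length(time_months)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d events, median %s months\n",
              x$n, sum(x$n_event),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Log-rank test between two survival groups
#'
#' Two-sample log-rank chi-square (1 df) on the pooled event-time grid.
#' When neither group has any event the comparison is degenerate and the
#' statistic is reported as 0 with p = 1 and `degenerate = TRUE`.
#'
#' @param time_months Follow-up times (> 0).
#' @param event Logical event indicator.
#' @param group Two-level grouping vector.
#' @return List with `statistic`, `p_value`, `group_sizes`, `degenerate`.
#' @export
log_rank <- function(time_months, event, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2 || any(table(group) == 0)) {
    stop("log-rank needs two non-empty groups", call. = FALSE)
  }
  if (!any(event)) {
    return(list(statistic = 0, p_value = 1,
                group_sizes = as.integer(table(group)), degenerate = TRUE))
  }
  sd <- survival::survdiff(survival::Surv(time_months, event) ~ group)
  list(statistic = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       group_sizes = as.integer(table(group)), degenerate = FALSE)
}

med_iqr <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(list(n = 0L, median = NA_real_,
                                  q1 = NA_real_, q3 = NA_real_))
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(n = length(x), median = q[2], q1 = q[1], q3 = q[3])
}

#' Stratified cohort report
#'
#' Builds the cohort-level summary: median/IQR (quartiles by linear
#' interpolation) of M50, MUSIX200, CMAP50, D50 and rD50-at-measurement per
#' aggressiveness subgroup and per rD50 phase, with per-metric defined n;
#' Kruskal-Wallis comparisons across aggressiveness subgroups; Spearman
#' correlations of each biomarker with D50; median splits with Kaplan-Meier
#' median survival and log-rank tests per split; and the M50/D50 separation
#' groups.
#'
#' @param fits [fit_d50_cohort()] table.
#' @param metrics [cohort_metrics()] table.
#' @param surv Survival data frame (`patient_id`, `time_months`, `event`).
#' @return Object of class `cohort_report`: nested list (see the JSON
#'   emitted by [write_report()]).
#' @export
summarize_cohort <- function(fits, metrics, surv) {
  ids <- Reduce(intersect, list(fits$patient_id, metrics$patient_id,
                                surv$patient_id))
  fits <- fits[match(ids, fits$patient_id), ]
  metrics <- metrics[match(ids, metrics$patient_id), ]
  surv <- surv[match(ids, surv$patient_id), ]

  rd50_at <- rd50(metrics$t_munix_months, fits$d50)
  tab <- data.frame(patient_id = ids, d50 = fits$d50,
                    rd50_at_munix = rd50_at,
                    subgroup = aggressiveness(fits$d50),
                    phase = rd50_phase(rd50_at),
                    m50 = metrics$m50, musix200 = metrics$musix200,
                    cmap50 = metrics$cmap50,
                    time_months = surv$time_months, event = surv$event,
                    stringsAsFactors = FALSE)
  metric_cols <- c("m50", "musix200", "cmap50", "d50", "rd50_at_munix")

  strat <- function(by) {
    lapply(split(tab, tab[[by]], drop = FALSE), function(sub) {
      if (nrow(sub) == 0) return(NULL)
      c(list(n = nrow(sub)),
        lapply(setNames(metric_cols, metric_cols),
               function(mc) med_iqr(sub[[mc]])))
    })
  }

  tests <- list()
  for (mc in c("m50", "musix200", "cmap50")) {
    ok <- !is.na(tab[[mc]])
    tests[[paste0("kruskal_", mc, "_by_aggressiveness")]] <-
      if (length(unique(tab$subgroup[ok])) >= 2) {
        kruskal_bonferroni(tab[[mc]][ok], tab$subgroup[ok])
      }
    tests[[paste0("spearman_", mc, "_vs_d50")]] <-
      if (sum(ok) >= 3) spearman_cor(tab[[mc]][ok], tab$d50[ok])
  }

  splits <- list(); survival_summary <- NULL
  for (mc in c("d50", "m50", "musix200", "cmap50")) {
    vals <- tab[[mc]]
    if (sum(!is.na(vals)) < 2) next
    sp <- median_split(vals, tab$patient_id)
    grp <- sp$assignment[tab$patient_id]
    keep <- !is.na(grp)
    lr <- if (length(unique(grp[keep])) == 2) {
      log_rank(tab$time_months[keep], tab$event[keep], grp[keep])
    }
    km_rows <- do.call(rbind, lapply(c("low", "high"), function(g) {
      sel <- keep & grp == g
      if (!any(sel)) return(NULL)
      km <- kaplan_meier(tab$time_months[sel], tab$event[sel])
      data.frame(split = mc, group = g, n = km$n,
                 median_survival = km$median, stringsAsFactors = FALSE)
    }))
    survival_summary <- rbind(survival_summary, km_rows)
    splits[[mc]] <- list(cutoff = sp$cutoff, degenerate = sp$degenerate,
                         log_rank = lr)
  }

  separation <- NULL
  if (all(c("m50", "d50") %in% names(splits)) && sum(!is.na(tab$m50)) >= 2) {
    m50_sp <- median_split(tab$m50, tab$patient_id)
    d50_sp <- median_split(tab$d50, tab$patient_id)
    common <- intersect(names(m50_sp$assignment), names(d50_sp$assignment))
    m50_sp$assignment <- m50_sp$assignment[common]
    d50_sp$assignment <- d50_sp$assignment[common]
    sep <- separation_classify(m50_sp, d50_sp)
    separation <- list(
      assignment = sep,
      counts = as.list(table(factor(sep, levels = c(
        "same", "low_m50_high_d50", "high_m50_low_d50")))))
  }

  structure(list(
    n_patients = length(ids),
    by_aggressiveness = strat("subgroup"),
    by_phase = strat("phase"),
    tests = tests,
    splits = splits,
    survival_summary = survival_summary,
    separation = separation,
    patient_table = tab
  ), class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort report: %d patients\n", x$n_patients))
  for (g in names(x$by_aggressiveness)) {
    s <- x$by_aggressiveness[[g]]
    if (is.null(s)) next
    cat(sprintf("  %s aggressiveness (n = %d): M50 %.1f, D50 %.1f months\n",
                g, s$n, s$m50$median, s$d50$median))
  }
  if (!is.null(x$survival_summary)) {
    m50s <- x$survival_summary[x$survival_summary$split == "m50", ]
    if (nrow(m50s) == 2) {
      cat(sprintf("  KM median survival by M50 split: low %.0f, high %.0f months\n",
                  m50s$median_survival[m50s$group == "low"],
                  m50s$median_survival[m50s$group == "high"]))
    }
  }
  invisible(x)
}
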