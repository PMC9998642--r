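MUSCLES <- c("APB", "ADM", "TA")

# Floor substitutions for unobtainable measurements (MUNIX guideline bound
# CMAP > 0.5 mV): MUNIX 2, CMAP 0.5 mV, MUSIX 500/2 = 250.
FLOOR_MUNIX <- 2
FLOOR_CMAP_MV <- 0.5
FLOOR_MUSIX <- 250

#' Motor unit size index (MUSIX)
#'
#' MUSIX is the quotient of CMAP (in microvolts) and MUNIX, a surrogate for
#' the size of surviving motor units (reinnervation).
#'
#' @param cmap_mV CMAP amplitude in millivolts.
#' @param munix MUNIX value; must be positive.
#' @return MUSIX (unitless): `cmap_mV * 1000 / munix`.
#' @examples
#' musix(0.5, 2) # the floor value, 250
#' @export
musix <- function(cmap_mV, munix) {
  if (any(munix <= 0)) stop("`munix` must be positive", call. = FALSE)
  cmap_mV * 1000 / munix
}

#' Apply floor substitution to a muscle measurement
#'
#' When no sufficiently high CMAP could be recorded in an advanced-disease
#' muscle (CMAP <= 0.5 mV) or the measurement was unobtainable altogether,
#' the measurement is replaced by fixed floor values (MUNIX 2, CMAP 0.5 mV,
#' MUSIX 250) instead of dropping the patient, which would bias the cohort
#' toward falsely high values. Otherwise MUSIX is derived by [musix()].
#'
#' @param munix_raw Raw MUNIX value(s), >= 0.
#' @param cmap_mV Raw CMAP value(s) in mV, >= 0.
#' @param obtainable Logical: was the measurement obtainable at all?
#' @return Data frame with columns `munix`, `cmap_mV`, `musix`, `floored`.
#' @export
apply_floors <- function(munix_raw, cmap_mV, obtainable = TRUE) {
  n <- max(length(munix_raw), length(cmap_mV), length(obtainable))
  munix_raw <- rep_len(as.numeric(munix_raw), n)
  cmap_mV <- rep_len(as.numeric(cmap_mV), n)
  obtainable <- rep_len(obtainable, n)
  # unobtainable rows may carry NA raw values; they are floored anyway
  munix_raw[!obtainable & is.na(munix_raw)] <- 0
  cmap_mV[!obtainable & is.na(cmap_mV)] <- 0
  if (anyNA(munix_raw) || anyNA(cmap_mV) ||
      any(munix_raw < 0) || any(cmap_mV < 0)) {
    stop("raw MUNIX and CMAP must be non-negative (NA only if unobtainable)",
         call. = FALSE)
  }
  floored <- !obtainable | cmap_mV <= FLOOR_CMAP_MV | munix_raw <= 0
  data.frame(
    munix = ifelse(floored, FLOOR_MUNIX, munix_raw),
    cmap_mV = ifelse(floored, FLOOR_CMAP_MV, cmap_mV),
    musix = ifelse(floored, FLOOR_MUSIX, cmap_mV * 1000 / pmax(munix_raw, 1e-300)),
    floored = floored
  )
}

#' Three-muscle sum scores of a MUNIX panel
#'
#' Sums MUNIX, CMAP and MUSIX over the APB, ADM and TA muscles of one panel
#' (floors already applied; floored values are included in the sums).
#'
#' @param panel Data frame with columns `muscle`, `munix`, `cmap_mV`,
#'   `musix`, containing each of APB, ADM, TA exactly once.
#' @return Named list: `munix_sum`, `cmap_sum_mV`, `musix_sum`.
#' @export
sum_scores <- function(panel) {
  if (!setequal(panel$muscle, MUSCLES) || nrow(panel) != 3) {
    stop("panel must contain exactly the muscles APB, ADM, TA", call. = FALSE)
  }
  list(munix_sum = sum(panel$munix),
       cmap_sum_mV = sum(panel$cmap_mV),
       musix_sum = sum(panel$musix))
}

#' Healthy-control baseline (the 100% reference level)
#'
#' Computes per-muscle means and SDs of MUNIX, CMAP and MUSIX over a
#' healthy-control table, plus the summed means that define the 100%
#' reference level for M50, CMAP50 and MUSIX200. The summed MUSIX baseline
#' is, by default, the mean over controls of their per-control three-muscle
#' MUSIX sums (equivalently the sum of per-muscle means).
#'
#' @param controls Data frame with columns `control_id`, `muscle`, `munix`,
#'   `cmap_mV`; every control must have all three muscles.
#' @return Object of class `munix_baseline`: list with `per_muscle` (data
#'   frame: muscle, munix_mean, munix_sd, cmap_mean_mV, cmap_sd_mV,
#'   musix_mean, musix_sd), `munix_sum_mean`, `cmap_sum_mean_mV`,
#'   `musix_sum_mean`, `n_controls`.
#' @export
control_baseline <- function(controls) {
  if (is.null(controls) || nrow(controls) == 0) {
    stop("control table is empty", call. = FALSE)
  }
  ids <- unique(controls$control_id)
  per_ctrl <- table(controls$control_id, controls$muscle)
  if (!all(per_ctrl == 1) || !setequal(colnames(per_ctrl), MUSCLES)) {
    stop("every control needs each of APB, ADM, TA exactly once", call. = FALSE)
  }
  controls$musix <- musix(controls$cmap_mV, controls$munix)
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  per_muscle <- do.call(rbind, lapply(MUSCLES, function(m) {
    sub <- controls[controls$muscle == m, ]
    data.frame(muscle = m,
               munix_mean = mean(sub$munix), munix_sd = sd0(sub$munix),
               cmap_mean_mV = mean(sub$cmap_mV), cmap_sd_mV = sd0(sub$cmap_mV),
               musix_mean = mean(sub$musix), musix_sd = sd0(sub$musix),
               stringsAsFactors = FALSE)
  }))
  structure(list(
    per_muscle = per_muscle,
    munix_sum_mean = sum(per_muscle$munix_mean),
    cmap_sum_mean_mV = sum(per_muscle$cmap_mean_mV),
    musix_sum_mean = sum(per_muscle$musix_mean),
    n_controls = length(ids)
  ), class = "munix_baseline")
}

#' @export
print.munix_baseline <- function(x, ...) {
  cat(sprintf("MUNIX control baseline (n = %d controls)\n", x$n_controls))
  print(x$per_muscle, row.names = FALSE)
  cat(sprintf("sum means: MUNIX %.1f, CMAP %.2f mV, MUSIX %.1f\n",
              x$munix_sum_mean, x$cmap_sum_mean_mV, x$musix_sum_mean))
  invisible(x)
}

#' Linear time-to-threshold estimation
#'
#' The core estimator behind M50, CMAP50 and MUSIX200. A patient's summed
#' measurement, expressed as a ratio to the control-mean sum, is assumed to
#' move linearly from 1.0 (the 100% base level) at symptom onset through the
#' observed `(t_obs, observed_ratio)` point; the function returns the time at
#' which that line reaches `target_ratio`:
#' `t_obs * (1 - target_ratio) / (1 - observed_ratio)`.
#'
#' @param t_obs_months Measurement time in months since symptom onset (> 0).
#' @param observed_ratio Observed sum / control mean sum; must differ from 1.
#' @param target_ratio Target level as a ratio of the baseline (0.5 for
#'   halving, 2.0 for doubling); must lie on the same side of 1 as
#'   `observed_ratio`.
#' @return Estimated months from onset to the target level (> 0).
#' @examples
#' time_to_fraction_linear(10, 0.75, 0.5) # 20 months to halving
#' @export
time_to_fraction_linear <- function(t_obs_months, observed_ratio, target_ratio) {
  if (any(t_obs_months <= 0)) stop("`t_obs_months` must be positive", call. = FALSE)
  if (any(observed_ratio == 1)) {
    stop("observed ratio equals 1: no change from baseline", call. = FALSE)
  }
  if (any(sign(target_ratio - 1) != sign(observed_ratio - 1))) {
    stop("target not reachable: observed change is in the opposite direction",
         call. = FALSE)
  }
  t_obs_months * (1 - target_ratio) / (1 - observed_ratio)
}

metric_one <- function(t_obs, ratio, target, no_change_status) {
  reachable <- if (target < 1) ratio < 1 else ratio > 1
  if (!reachable) {
    list(months = NA_real_, status = no_change_status)
  } else {
    list(months = time_to_fraction_linear(t_obs, ratio, target),
         status = "defined")
  }
}

#' M50, CMAP50 and MUSIX200 for one patient
#'
#' Computes the three time-to-threshold biomarkers from a patient's
#' floor-corrected three-muscle panel sums and the control baseline:
#' \describe{
#'   \item{M50}{months from onset until the MUNIX sum reaches 50% of the
#'     control-mean MUNIX sum; undefined (`no_decrease`) when the patient's
#'     sum is at or above the control mean.}
#'   \item{CMAP50}{the same for the CMAP sum.}
#'   \item{MUSIX200}{months until the MUSIX sum doubles the control-mean
#'     MUSIX sum; undefined (`no_increase`) when the patient's sum is at or
#'     below the control mean.}
#' }
#'
#' @param panel Floor-corrected panel data frame (columns `muscle`, `munix`,
#'   `cmap_mV`, `musix`), one row per muscle.
#' @param t_munix_months Disease duration at the MUNIX measurement (months).
#' @param baseline A [control_baseline()] object.
#' @return One-row data frame: `m50`, `cmap50`, `musix200` (months, `NA`
#'   when undefined), `m50_status`, `cmap50_status`, `musix200_status`,
#'   `munix_ratio`, `cmap_ratio`, `musix_ratio`, `t_munix_months`.
#' @export
patient_metrics <- function(panel, t_munix_months, baseline) {
  stopifnot(inherits(baseline, "munix_baseline"))
  s <- sum_scores(panel)
  r_mun <- s$munix_sum / baseline$munix_sum_mean
  r_cmap <- s$cmap_sum_mV / baseline$cmap_sum_mean_mV
  r_mus <- s$musix_sum / baseline$musix_sum_mean
  m50 <- metric_one(t_munix_months, r_mun, 0.5, "no_decrease")
  c50 <- metric_one(t_munix_months, r_cmap, 0.5, "no_decrease")
  m200 <- metric_one(t_munix_months, r_mus, 2.0, "no_increase")
  data.frame(
    m50 = m50$months, cmap50 = c50$months, musix200 = m200$months,
    m50_status = m50$status, cmap50_status = c50$status,
    musix200_status = m200$status,
    munix_ratio = r_mun, cmap_ratio = r_cmap, musix_ratio = r_mus,
    t_munix_months = t_munix_months,
    stringsAsFactors = FALSE
  )
}

#' Biomarkers for a whole cohort of panels
#'
#' @param panels Long-format panel table (columns `patient_id`,
#'   `t_munix_months`, `muscle`, `munix`, `cmap_mV`, `obtainable`), three
#'   rows per patient; floors are applied here.
#' @param baseline A [control_baseline()] object.
#' @return Data frame with one row per patient (see [patient_metrics()]),
#'   plus `patient_id` and `n_floored`.
#' @export
cohort_metrics <- function(panels, baseline) {
  ids <- unique(panels$patient_id)
  rows <- lapply(ids, function(id) {
    sub <- panels[panels$patient_id == id, ]
    fl <- apply_floors(sub$munix, sub$cmap_mV, sub$obtainable)
    panel <- cbind(data.frame(muscle = sub$muscle, stringsAsFactors = FALSE), fl)
    out <- patient_metrics(panel, sub$t_munix_months[1], baseline)
    cbind(data.frame(patient_id = id, stringsAsFactors = FALSE),
          out, n_floored = sum(fl$floored))
  })
  do.call(rbind, rows)
}
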