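#' Sigmoidal ALSFRS-R decay curve
#'
#' Evaluates the individual sigmoidal decay curve of the D50 disease
#' progression model. The curve starts at the full ALSFRS-R score of 48,
#' declines monotonically, and passes through its turning point at
#' `t = d50`, where the predicted score equals 24 (50% of full motor
#' function). `dx` is the time-scale parameter of the sigmoid: small `dx`
#' means a steep functional collapse around D50.
#'
#' @param t_months Time since symptom onset in months (vectorized).
#' @param d50 Sigmoid turning point in months; must be positive.
#' @param dx Sigmoid slope/scale parameter in months; must be positive.
#' @return Predicted ALSFRS-R total score(s) in (0, 48).
#' @examples
#' alsfrs_sigmoid(28.4, d50 = 28.4, dx = 6) # exactly 24
#' @export
alsfrs_sigmoid <- function(t_months, d50, dx) {
  if (!is.numeric(d50) || any(d50 <= 0)) {
    stop("`d50` must be positive", call. = FALSE)
  }
  if (!is.numeric(dx) || any(dx <= 0)) {
    stop("`dx` must be positive", call. = FALSE)
  }
  48 / (1 + exp((t_months - d50) / dx))
}

#' Relative D50 (disease accumulation)
#'
#' Maps calendar time since symptom onset onto the unitless rD50 scale:
#' 0 at symptom onset, 0.5 at `t = d50` (50% functional loss), linear in
#' between and beyond, i.e. `t / (2 * d50)`. rD50 makes patients with very
#' different disease aggressiveness comparable at the same relative point of
#' their course.
#'
#' @param t_months Time since symptom onset in months; non-negative.
#' @param d50 Individual D50 in months; must be positive.
#' @return rD50 value(s), unitless, >= 0.
#' @export
rd50 <- function(t_months, d50) {
  if (!is.numeric(d50) || any(d50 <= 0)) {
    stop("`d50` must be positive", call. = FALSE)
  }
  if (any(t_months < 0)) stop("`t_months` must be non-negative", call. = FALSE)
  t_months / (2 * d50)
}

#' Classify rD50 into disease-accumulation phases
#'
#' Phase I (semi-stable early disease): 0 <= rD50 < 0.25; Phase II (early
#' progressive): 0.25 <= rD50 < 0.5; Phase III/IV (late progressive and
#' stable): rD50 >= 0.5. Intervals are half-open, closed on the left.
#'
#' @param x rD50 value(s), >= 0.
#' @return Factor with levels `I`, `II`, `III_IV`.
#' @export
rd50_phase <- function(x) {
  if (any(x < 0)) stop("rD50 must be non-negative", call. = FALSE)
  cut(x, breaks = c(0, 0.25, 0.5, Inf), labels = c("I", "II", "III_IV"),
      right = FALSE, include.lowest = TRUE)
}

#' Classify D50 into disease-aggressiveness subgroups
#'
#' high: 0 <= D50 < 20 months; intermediate: 20 <= D50 < 40; low: D50 >= 40.
#' Small D50 means aggressive disease (fast functional loss).
#'
#' @param d50 D50 value(s) in months, >= 0.
#' @return Factor with levels `high`, `intermediate`, `low`.
#' @export
aggressiveness <- function(d50) {
  if (any(d50 < 0)) stop("`d50` must be non-negative", call. = FALSE)
  cut(d50, breaks = c(0, 20, 40, Inf), labels = c("high", "intermediate", "low"),
      right = FALSE, include.lowest = TRUE)
}

# Initial D50 guess: first downward crossing of 24 on the piecewise-linear
# interpolation of the observations; falls back to the last observation time.
d50_init <- function(t, score) {
  below <- which(score <= 24)
  if (length(below) == 0 || below[1] == 1) {
    if (length(below) > 0 && below[1] == 1) return(max(t[1], 0.5))
    return(max(t))
  }
  i <- below[1]
  t0 <- t[i - 1]; t1 <- t[i]; s0 <- score[i - 1]; s1 <- score[i]
  if (s0 == s1) return(t1)
  t0 + (s0 - 24) * (t1 - t0) / (s0 - s1)
}

#' Fit the D50 model to one patient's ALSFRS-R series
#'
#' Least-squares fit of [alsfrs_sigmoid()] to longitudinal ALSFRS-R totals
#' by bounded Levenberg-Marquardt (D50 in \[0.1, 600\], dx in \[0.1, 120\]).
#' D50 is initialized where a piecewise-linear interpolation of the series
#' crosses 24 (fallback: last observation time) and dx at a quarter of the
#' observation span; up to 5 restarts jitter the D50 start by +/-50% before
#' the fit is declared non-converged. Series with non-decreasing scores carry
#' no information about a decay curve and are flagged `identifiable = FALSE`
#' (parameters are still returned from the formal optimum but should not be
#' interpreted).
#'
#' @param t_months Observation times in months since symptom onset.
#' @param score ALSFRS-R totals (0-48) at `t_months`.
#' @return An object of class `d50_fit`: list with `d50`, `dx`, `rss`,
#'   `n_obs`, `converged`, `identifiable`, `subgroup` (aggressiveness label).
#' @examples
#' t <- seq(3, 30, by = 3)
#' fit <- fit_d50(t, alsfrs_sigmoid(t, 28.4, 6))
#' fit$d50
#' @export
fit_d50 <- function(t_months, score) {
  if (length(t_months) < 2) {
    stop("at least 2 ALSFRS-R observations are required", call. = FALSE)
  }
  if (length(score) != length(t_months)) {
    stop("`t_months` and `score` must have equal length", call. = FALSE)
  }
  o <- order(t_months)
  t <- as.numeric(t_months[o]); s <- as.numeric(score[o])
  identifiable <- any(diff(s) < 0)

  lower <- c(d50 = 0.1, dx = 0.1)
  upper <- c(d50 = 600, dx = 120)
  span <- max(diff(range(t)), 1)
  d50_0 <- min(max(d50_init(t, s), lower[1]), upper[1])
  dx_0 <- min(max(span / 4, lower[2]), upper[2])

  resid_fun <- function(p) s - 48 / (1 + exp((t - p[1]) / p[2]))
  # multi-start over jittered D50 and a ladder of dx scales; the sigmoid RSS
  # surface has step-function local minima (dx -> 0) that a single start can
  # fall into on steep trajectories
  starts <- expand.grid(jd50 = c(1, 0.5, 1.5, 0.75, 1.25),
                        jdx = c(1, 0.25, 0.0625))
  best <- NULL
  for (j in seq_len(nrow(starts))) {
    start <- c(d50 = min(max(d50_0 * starts$jd50[j], lower[1]), upper[1]),
               dx = min(max(dx_0 * starts$jdx[j], lower[2]), upper[2]))
    ans <- tryCatch(
      minpack.lm::nls.lm(
        par = start, lower = lower, upper = upper, fn = resid_fun,
        control = minpack.lm::nls.lm.control(
          maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(ans)) next
    rss <- sum(ans$fvec^2)
    conv <- ans$info %in% 1:4
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(par = ans$par, rss = rss, converged = conv)
    }
    if (best$converged && best$rss < 1e-16 * max(1, sum(s^2))) break
  }
  if (is.null(best)) {
    best <- list(par = c(d50 = d50_0, dx = dx_0),
                 rss = sum(resid_fun(c(d50_0, dx_0))^2), converged = FALSE)
  }

  structure(list(
    d50 = unname(best$par[1]),
    dx = unname(best$par[2]),
    rss = best$rss,
    n_obs = length(t),
    converged = best$converged,
    identifiable = identifiable,
    subgroup = as.character(aggressiveness(unname(best$par[1])))
  ), class = "d50_fit")
}

#' @export
print.d50_fit <- function(x, ...) {
  cat(sprintf(
    "D50 model fit: D50 = %.2f months (%s aggressiveness), dx = %.2f\n",
    x$d50, x$subgroup, x$dx))
  cat(sprintf("  n = %d observations, RSS = %.4g, converged: %s%s\n",
              x$n_obs, x$rss, x$converged,
              if (!x$identifiable) ", NOT identifiable" else ""))
  invisible(x)
}

#' Fit the D50 model across a cohort
#'
#' Applies [fit_d50()] to every patient in a long-format ALSFRS-R table.
#'
#' @param alsfrs Data frame with columns `patient_id`, `t_months`,
#'   `alsfrs_r_total`.
#' @return Data frame with one row per patient: `patient_id`, `d50`, `dx`,
#'   `rss`, `n_obs`, `converged`, `identifiable`, `subgroup`.
#' @export
fit_d50_cohort <- function(alsfrs) {
  ids <- unique(alsfrs$patient_id)
  rows <- lapply(ids, function(id) {
    sub <- alsfrs[alsfrs$patient_id == id, ]
    f <- fit_d50(sub$t_months, sub$alsfrs_r_total)
    data.frame(patient_id = id, d50 = f$d50, dx = f$dx, rss = f$rss,
               n_obs = f$n_obs, converged = f$converged,
               identifiable = f$identifiable, subgroup = f$subgroup,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
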