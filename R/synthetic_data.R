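#' Generator configuration for synthetic ALS/MUNIX cohorts
#'
#' Bundles every distributional assumption of the synthetic cohorts: the
#' aggressiveness mixture and per-subgroup D50 distributions (truncated
#' log-normals targeting subgroup medians of 13.8 / 28.0 / 61.5 months),
#' the ALSFRS-R visit process (cadence centred on 2.8 months), measurement
#' noise, the healthy-control MUNIX distribution (APB 168.6 +/- 58.6,
#' ADM 154.4 +/- 40.2, TA 137.2 +/- 28.9), the linear MUNIX/CMAP decline
#' (true M50 = `m50_to_d50` x D50, so the MUNIX sum crosses 50% of the
#' control mean exactly at the true M50), and D50-coupled survival.
#'
#' @param n_patients Cohort size.
#' @param subgroup_weights Mixture weights for high/intermediate/low
#'   aggressiveness (must sum to 1).
#' @param d50_medians Target D50 medians per subgroup (months).
#' @param d50_sdlog Log-scale SD of each subgroup's D50 distribution.
#' @param dx_to_d50 Ratio of the sigmoid scale dx to D50.
#' @param dx_jitter_sdlog Log-normal jitter on dx.
#' @param first_visit_months Range of the first ALSFRS-R visit time.
#' @param cadence_months,cadence_jitter_sd Mean and SD of the inter-visit
#'   interval (truncated at `min_interval_months`).
#' @param min_interval_months Shortest allowed inter-visit interval.
#' @param visit_horizon_months Administrative end of ALSFRS-R follow-up.
#' @param alsfrs_noise_sd SD of additive ALSFRS-R measurement noise (points).
#' @param integer_scores Round scores to the 0-48 integer scale?
#' @param m50_to_d50,cmap50_to_d50 True M50 and CMAP50 as fractions of D50.
#' @param control_munix_mean,control_munix_sd Named per-muscle control MUNIX
#'   moments (APB, ADM, TA).
#' @param control_cmap_mean,control_cmap_sd Control CMAP moments (mV).
#' @param n_controls Healthy-control sample size.
#' @param munix_noise_sdlog,cmap_noise_sdlog Multiplicative (log-normal)
#'   measurement noise on patient MUNIX / CMAP.
#' @param unobtainable_prob Probability a muscle yields no measurement.
#' @param measurement_rd50_mean,measurement_rd50_sd,measurement_rd50_range
#'   Distribution (truncated normal) of rD50 at the MUNIX measurement.
#' @param survival_multiplier,survival_sdlog Survival = multiplier x D50 x
#'   log-normal noise.
#' @param censor_fraction Fraction of patients censored before death.
#' @param decline_floor Lower bound on the linear decline fraction (keeps
#'   simulated raw values positive deep in the disease course).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(
    n_patients = 222,
    subgroup_weights = c(high = 64, intermediate = 92, low = 66) / 222,
    d50_medians = c(high = 13.8, intermediate = 28.0, low = 61.5),
    d50_sdlog = 0.35,
    dx_to_d50 = 0.25,
    dx_jitter_sdlog = 0.2,
    first_visit_months = c(2, 6),
    cadence_months = 2.8,
    cadence_jitter_sd = 0.9,
    min_interval_months = 0.5,
    visit_horizon_months = 72,
    alsfrs_noise_sd = 2,
    integer_scores = TRUE,
    m50_to_d50 = 0.5,
    cmap50_to_d50 = 0.62,
    control_munix_mean = c(APB = 168.6, ADM = 154.4, TA = 137.2),
    control_munix_sd = c(APB = 58.6, ADM = 40.2, TA = 28.9),
    control_cmap_mean = c(APB = 10.5, ADM = 11.0, TA = 6.0),
    control_cmap_sd = c(APB = 2.5, ADM = 2.5, TA = 1.8),
    n_controls = 45,
    munix_noise_sdlog = 0.2,
    cmap_noise_sdlog = 0.2,
    unobtainable_prob = 0.02,
    measurement_rd50_mean = 0.30,
    measurement_rd50_sd = 0.10,
    measurement_rd50_range = c(0.05, 0.60),
    survival_multiplier = 1.8,
    survival_sdlog = 0.3,
    censor_fraction = 0.25,
    decline_floor = 0.02) {
  cfg <- as.list(environment())
  if (abs(sum(cfg$subgroup_weights) - 1) > 1e-8) {
    stop("subgroup weights must sum to 1", call. = FALSE)
  }
  if (cfg$cadence_months <= 0) stop("cadence must be positive", call. = FALSE)
  structure(cfg, class = "generator_config")
}

#' Noise-free generator configuration
#'
#' The deterministic limit of [generator_config()]: every noise SD is 0
#' (including the control SDs, so the sampled control means equal the
#' configured means exactly), scores are left unrounded, no measurement is
#' unobtainable, and the MUNIX measurement falls in the mid-course window
#' (rD50 0.1-0.45) where no floor can trigger. Under this configuration the
#' pipeline must recover every true D50 and true M50 exactly (up to
#' optimizer tolerance).
#'
#' @param ... Overrides passed on to [generator_config()].
#' @return A `generator_config`.
#' @export
noiseless_config <- function(...) {
  generator_config(
    alsfrs_noise_sd = 0, integer_scores = FALSE,
    control_munix_sd = c(APB = 0, ADM = 0, TA = 0),
    control_cmap_sd = c(APB = 0, ADM = 0, TA = 0),
    munix_noise_sdlog = 0, cmap_noise_sdlog = 0,
    dx_jitter_sdlog = 0, unobtainable_prob = 0,
    measurement_rd50_range = c(0.10, 0.45),
    ...)
}

# counter-based per-patient sub-seed so growing the cohort never reshuffles
# already-generated patients
derive_seed <- function(master, counter) {
  as.integer((as.numeric(master) %% 2147483647 * 48271 + counter * 16807) %%
               2147483647)
}

rnorm_trunc <- function(n, mean, sd, lower = 0) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= lower)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

#' Simulate a healthy-control MUNIX table
#'
#' Draws per-control per-muscle MUNIX and CMAP values from truncated-at-zero
#' normal distributions with the configured control moments; MUSIX follows
#' as the CMAP/MUNIX quotient downstream.
#'
#' @param n Number of controls (>= 1).
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return Data frame: `control_id`, `muscle`, `munix`, `cmap_mV`.
#' @export
generate_controls <- function(n, config = generator_config(), seed = 1) {
  if (n < 1) stop("need at least one control", call. = FALSE)
  set.seed(seed)
  rows <- lapply(MUSCLES, function(m) {
    data.frame(
      control_id = sprintf("C%05d", seq_len(n)), muscle = m,
      munix = rnorm_trunc(n, config$control_munix_mean[[m]],
                          config$control_munix_sd[[m]], lower = 1),
      cmap_mV = rnorm_trunc(n, config$control_cmap_mean[[m]],
                            config$control_cmap_sd[[m]], lower = 0.6),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$control_id, match(out$muscle, MUSCLES)), c(
    "control_id", "muscle", "munix", "cmap_mV")]
}

#' Simulate one ALS patient
#'
#' Builds one patient's full record from a true D50: a sigmoidal ALSFRS-R
#' trajectory observed at jittered visit cadence, one three-muscle MUNIX
#' panel whose sums decline linearly from the control-mean level (crossing
#' 50% exactly at the true M50 = `m50_to_d50` x D50; CMAP analogous with
#' `cmap50_to_d50`; MUSIX rises as the induced quotient), a D50-coupled
#' survival time, and metadata. The companion truth row records the
#' generating parameters, including the implied true MUSIX200 (the time at
#' which the induced MUSIX sum doubles the baseline).
#'
#' @param patient_id Identifier string.
#' @param true_d50 True D50 in months (> 0).
#' @param config A [generator_config()].
#' @param seed Integer sub-stream seed.
#' @return List of data frames: `alsfrs`, `panel`, `survival`, `metadata`,
#'   `truth`.
#' @export
generate_patient <- function(patient_id, true_d50,
                             config = generator_config(), seed = 1) {
  if (true_d50 <= 0) stop("true D50 must be positive", call. = FALSE)
  cfg <- config
  set.seed(seed)
  rln <- function(sdlog) if (sdlog == 0) 1 else exp(stats::rnorm(1, 0, sdlog))

  dx <- true_d50 * cfg$dx_to_d50 * rln(cfg$dx_jitter_sdlog)
  m50_true <- cfg$m50_to_d50 * true_d50
  cmap50_true <- cfg$cmap50_to_d50 * true_d50
  # induced MUSIX sum ratio is cmap-fraction / munix-fraction; doubling time:
  musix200_true <- 1 / (1 / m50_true - 1 / (2 * cmap50_true))
  surv_true <- cfg$survival_multiplier * true_d50 * rln(cfg$survival_sdlog)
  censored <- stats::runif(1) < cfg$censor_fraction
  time_obs <- if (censored) surv_true * stats::runif(1, 0.4, 0.95) else surv_true

  # visit schedule: first visit, then jittered cadence until death/horizon,
  # always keeping at least 3 assessments around diagnosis
  t1 <- stats::runif(1, cfg$first_visit_months[1], cfg$first_visit_months[2])
  t_end <- min(surv_true, cfg$visit_horizon_months)
  visits <- t1
  while (TRUE) {
    gap <- max(cfg$min_interval_months,
               stats::rnorm(1, cfg$cadence_months, cfg$cadence_jitter_sd))
    nxt <- visits[length(visits)] + gap
    if (nxt > t_end && length(visits) >= 3) break
    visits <- c(visits, nxt)
    if (length(visits) > 200) break
  }
  score <- alsfrs_sigmoid(visits, true_d50, dx) +
    stats::rnorm(length(visits), 0, cfg$alsfrs_noise_sd)
  score <- pmin(pmax(score, 0), 48)
  if (cfg$integer_scores) score <- round(score)
  alsfrs <- data.frame(patient_id = patient_id, t_months = visits,
                       alsfrs_r_total = score, stringsAsFactors = FALSE)

  rd_m <- if (cfg$measurement_rd50_sd == 0) cfg$measurement_rd50_mean else {
    x <- stats::rnorm(1, cfg$measurement_rd50_mean, cfg$measurement_rd50_sd)
    min(max(x, cfg$measurement_rd50_range[1]), cfg$measurement_rd50_range[2])
  }
  t_munix <- 2 * true_d50 * rd_m
  f_mun <- max(cfg$decline_floor, 1 - 0.5 * t_munix / m50_true)
  f_cmap <- max(cfg$decline_floor, 1 - 0.5 * t_munix / cmap50_true)
  panel <- do.call(rbind, lapply(MUSCLES, function(m) {
    obtainable <- stats::runif(1) >= cfg$unobtainable_prob
    mun <- cfg$control_munix_mean[[m]] * f_mun * rln(cfg$munix_noise_sdlog)
    cm <- cfg$control_cmap_mean[[m]] * f_cmap * rln(cfg$cmap_noise_sdlog)
    data.frame(patient_id = patient_id, t_munix_months = t_munix,
               side = "less_affected", muscle = m,
               munix = if (obtainable) mun else NA_real_,
               cmap_mV = if (obtainable) cm else NA_real_,
               obtainable = obtainable, stringsAsFactors = FALSE)
  }))

  age <- min(max(stats::rnorm(1, 66, 8), 30), 90)
  metadata <- data.frame(
    patient_id = patient_id, age_at_measurement = age,
    sex = sample(c("female", "male"), 1),
    phenotype = sample(c("classic", "bulbar", "other"), 1,
                       prob = c(0.6, 0.33, 0.07)),
    el_escorial = sample(c("definite", "probable", "LSPR", "possible"), 1),
    riluzole = stats::runif(1) < 0.9, gold_coast = TRUE, juvenile = FALSE,
    stringsAsFactors = FALSE)

  list(
    alsfrs = alsfrs,
    panel = panel,
    survival = data.frame(patient_id = patient_id, time_months = time_obs,
                          event = !censored, stringsAsFactors = FALSE),
    metadata = metadata,
    truth = data.frame(patient_id = patient_id, true_d50 = true_d50,
                       true_dx = dx, true_m50 = m50_true,
                       true_cmap50 = cmap50_true,
                       true_musix200 = musix200_true,
                       true_survival = surv_true, stringsAsFactors = FALSE))
}

sample_d50 <- function(subgroup, cfg) {
  bounds <- list(high = c(2, 20), intermediate = c(20, 40), low = c(40, 300))
  b <- bounds[[subgroup]]
  med <- cfg$d50_medians[[subgroup]]
  repeat {
    x <- stats::rlnorm(1, meanlog = log(med), sdlog = cfg$d50_sdlog)
    if (x >= b[1] && x < b[2]) return(x)
  }
}

#' Simulate a full ALS cohort
#'
#' Draws each patient's aggressiveness subgroup from the mixture weights and
#' the true D50 from that subgroup's truncated log-normal (truncation at the
#' subgroup boundaries keeps labels consistent by construction), then builds
#' every patient with [generate_patient()] under an independent counter-based
#' sub-seed, plus a control table via [generate_controls()].
#'
#' @param config A [generator_config()].
#' @param seed Master seed.
#' @return List of class `synthetic_cohort`: data frames `alsfrs`, `panels`,
#'   `survival`, `metadata`, `controls`, `truth`.
#' @export
generate_cohort <- function(config = generator_config(), seed = 1) {
  cfg <- config
  n <- cfg$n_patients
  set.seed(derive_seed(seed, 0))
  subgroups <- sample(names(cfg$subgroup_weights), n, replace = TRUE,
                      prob = cfg$subgroup_weights)
  parts <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(derive_seed(seed, 2 * i))
    d50_i <- sample_d50(subgroups[i], cfg)
    parts[[i]] <- generate_patient(sprintf("P%04d", i), d50_i, cfg,
                                   seed = derive_seed(seed, 2 * i + 1))
  }
  bindp <- function(el) do.call(rbind, lapply(parts, `[[`, el))
  truth <- bindp("truth")
  truth$subgroup <- subgroups
  structure(list(
    alsfrs = bindp("alsfrs"),
    panels = bindp("panel"),
    survival = bindp("survival"),
    metadata = bindp("metadata"),
    controls = generate_controls(cfg$n_controls, cfg,
                                 seed = derive_seed(seed, 1)),
    truth = truth
  ), class = "synthetic_cohort")
}

#' Write a synthetic cohort to CSV files
#'
#' Emits the cohort in the exact schemas [read_cohort()] consumes, plus
#' `controls.csv` and the ground-truth table `truth.csv`.
#'
#' @param sim A [generate_cohort()] result.
#' @param dir Output directory.
#' @return Invisibly, named vector of paths.
#' @export
write_synthetic_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(alsfrs = "alsfrs.csv", panels = "munix_panels.csv",
             survival = "survival.csv", metadata = "metadata.csv",
             controls = "controls.csv", truth = "truth.csv")
  paths <- setNames(file.path(dir, paths), names(paths))
  utils::write.csv(sim$alsfrs, paths["alsfrs"], row.names = FALSE)
  utils::write.csv(sim$panels, paths["panels"], row.names = FALSE)
  utils::write.csv(sim$survival, paths["survival"], row.names = FALSE)
  utils::write.csv(sim$metadata, paths["metadata"], row.names = FALSE)
  utils::write.csv(sim$controls, paths["controls"], row.names = FALSE)
  utils::write.csv(sim$truth, paths["truth"], row.names = FALSE)
  invisible(paths)
}
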