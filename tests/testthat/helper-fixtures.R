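# Shared fixtures and independent oracles, built in code at test time.

# Small healthy-control table with exact known means (no sampling noise).
fixture_controls <- function() {
  expand_ctrl <- function(id, munix, cmap) {
    data.frame(control_id = id, muscle = c("APB", "ADM", "TA"),
               munix = munix, cmap_mV = cmap, stringsAsFactors = FALSE)
  }
  rbind(expand_ctrl("C1", c(160, 150, 130), c(10, 11, 6)),
        expand_ctrl("C2", c(180, 160, 140), c(11, 11, 6)),
        expand_ctrl("C3", c(170, 155, 135), c(10.5, 11, 6)))
}

# One patient's worth of input rows.
fixture_patient <- function(id, t_obs = c(2, 5, 8), scores = c(45, 40, 34),
                            t_munix = 10, munix = c(80, 75, 65),
                            cmap = c(5, 5.5, 3), obtainable = TRUE,
                            side = "less_affected", surv_time = 30,
                            event = TRUE, gold_coast = TRUE, juvenile = FALSE,
                            age = NA_real_) {
  list(
    alsfrs = data.frame(patient_id = id, t_months = t_obs,
                        alsfrs_r_total = scores, stringsAsFactors = FALSE),
    panels = data.frame(patient_id = id, t_munix_months = t_munix, side = side,
                        muscle = c("APB", "ADM", "TA"), munix = munix,
                        cmap_mV = cmap,
                        obtainable = rep_len(obtainable, 3),
                        stringsAsFactors = FALSE),
    survival = data.frame(patient_id = id, time_months = surv_time,
                          event = event, stringsAsFactors = FALSE),
    metadata = data.frame(patient_id = id, age_at_measurement = age,
                          gold_coast = gold_coast, juvenile = juvenile,
                          stringsAsFactors = FALSE))
}

# Write a list of fixture_patient() results as the four cohort CSVs.
write_fixture_cohort <- function(patients, dir = tempfile("cohort_")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tbl in c("alsfrs", "panels", "survival", "metadata")) {
    df <- do.call(rbind, lapply(patients, `[[`, tbl))
    fname <- c(alsfrs = "alsfrs.csv", panels = "munix_panels.csv",
               survival = "survival.csv", metadata = "metadata.csv")[[tbl]]
    write.csv(df, file.path(dir, fname), row.names = FALSE)
  }
  dir
}

read_fixture_cohort <- function(dir) {
  read_cohort(file.path(dir, "alsfrs.csv"),
              file.path(dir, "munix_panels.csv"),
              file.path(dir, "survival.csv"),
              file.path(dir, "metadata.csv"))
}

# One patient per exclusion rule plus two clean patients.
exclusion_fixture <- function() {
  list(
    fixture_patient("KEEP1"),
    fixture_patient("KEEP2", age = 66),
    fixture_patient("GC", gold_coast = FALSE),
    fixture_patient("SIDE", side = "more_affected"),
    fixture_patient("ONEOBS", t_obs = 4, scores = 40),
    fixture_patient("JUV", juvenile = TRUE),
    # MUNIX above the control mean sum (fixture baseline sum = 455)
    fixture_patient("NODEC", munix = c(180, 165, 140)),
    # ratio 0.99 at t = 15 -> M50 = 0.5*15/0.01 = 750 > 720 cap (no age)
    fixture_patient("LONG", munix = c(170, 155, 135) * 0.99 + c(0.002, 0, 0),
                    t_munix = 15))
}

# Incremental line-stepping oracle for the linear time-to-threshold
# estimator: walk the anchored line in fixed steps until it crosses the
# target ratio; independent of the closed form under test.
step_oracle <- function(t_obs, observed_ratio, target_ratio, step = 1e-3) {
  slope <- (1 - observed_ratio) / t_obs
  t <- 0
  repeat {
    t <- t + step
    ratio <- 1 - slope * t
    crossed <- if (target_ratio < 1) ratio <= target_ratio else
      ratio >= target_ratio
    if (crossed) return(t)
    if (t > 1e5) stop("oracle did not converge")
  }
}

# Brute-force tie-corrected Kruskal-Wallis H from the rank definition.
kw_hand <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  groups <- as.factor(groups)
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  H <- 12 / (N * (N + 1)) * sum(n * (rbar - (N + 1) / 2)^2)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Hand tabulation of the two-sample log-rank chi-square over the pooled
# event-time grid.
logrank_hand <- function(time, event, group) {
  group <- as.factor(group)
  stopifnot(nlevels(group) == 2)
  g1 <- levels(group)[1]
  times <- sort(unique(time[event]))
  O <- E <- V <- 0
  for (tt in times) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(event & time == tt)
    d1 <- sum(event & time == tt & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}
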