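test_that("median split halves the cohort with ties going high", {
  sp <- median_split(c(1, 2, 3, 4), c("a", "b", "c", "d"))
  expect_equal(sp$cutoff, 2.5)
  expect_equal(sp$assignment, c(a = "low", b = "low", c = "high", d = "high"))

  # odd n: the patient at the median goes high
  sp2 <- median_split(c(1, 2, 3), c("a", "b", "c"))
  expect_equal(sp2$assignment[["b"]], "high")

  sp3 <- median_split(c(5, 5, 5), c("a", "b", "c"))
  expect_true(sp3$degenerate)
  expect_true(all(sp3$assignment == "high"))
  expect_error(median_split(7, "a"), "at least 2")

  # exhaustive and disjoint over defined patients
  set.seed(9)
  v <- rnorm(31)
  sp4 <- median_split(v, sprintf("p%02d", 1:31))
  expect_length(sp4$assignment, 31)
  expect_true(all(sp4$assignment %in% c("low", "high")))
  expect_equal(sum(sp4$assignment == "low"), 15)
})

test_that("separation groups combine the M50 and D50 split sides", {
  m <- structure(list(cutoff = 10, assignment = c(a = "low", b = "low",
                                                  c = "high", d = "high")),
                 class = "median_split")
  d <- structure(list(cutoff = 20, assignment = c(a = "low", b = "high",
                                                  c = "low", d = "high")),
                 class = "median_split")
  sep <- separation_classify(m, d)
  expect_equal(unname(sep[c("a", "d")]), c("same", "same"))
  expect_equal(unname(sep[["b"]]), "low_m50_high_d50")
  expect_equal(unname(sep[["c"]]), "high_m50_low_d50")
  d$assignment <- d$assignment[1:3]
  expect_error(separation_classify(m, d), "different patients")
})

test_that("Kruskal-Wallis H matches the brute-force rank computation", {
  # fully separated groups, n = (5, 5, 5)
  v <- c(1:5, 11:15, 21:25)
  g <- rep(c("A", "B", "C"), each = 5)
  res <- kruskal_bonferroni(v, g)
  expect_equal(res$statistic, kw_hand(v, g), tolerance = 1e-12)

  # tied data: tie-corrected H still matches
  set.seed(3)
  v2 <- sample(rep(1:6, 4)); g2 <- rep(c("A", "B", "C"), 8)
  expect_equal(kruskal_bonferroni(v2, g2)$statistic, kw_hand(v2, g2),
               tolerance = 1e-12)

  # identical groups: H = 0, p = 1 (up to tie correction degeneracy)
  res0 <- kruskal_bonferroni(rep(c(1, 2, 3), 3), rep(c("A", "B", "C"), each = 3))
  expect_equal(res0$statistic, 0, tolerance = 1e-12)
  expect_equal(res0$p_value, 1, tolerance = 1e-12)

  # Bonferroni caps at 1 and never lowers a p-value
  pw <- res$pairwise
  expect_true(all(pw$p_adj >= pw$p_raw))
  expect_true(all(pw$p_adj <= 1))
  expect_equal(kruskal_bonferroni(v2, g2)$pairwise$p_adj,
               pmin(1, 3 * kruskal_bonferroni(v2, g2)$pairwise$p_raw))
  expect_error(kruskal_bonferroni(1:3, factor(rep("A", 3), levels = c("A", "B"))),
               "non-empty")
})

test_that("Kruskal-Wallis H is invariant under monotone transforms", {
  set.seed(14)
  v <- rexp(30); g <- rep(c("A", "B", "C"), 10)
  h0 <- kruskal_bonferroni(v, g)$statistic
  expect_equal(kruskal_bonferroni(log(v), g)$statistic, h0, tolerance = 1e-12)
  expect_equal(kruskal_bonferroni(v^3, g)$statistic, h0, tolerance = 1e-12)
})

test_that("Spearman correlation handles ranks and self-correlation", {
  expect_equal(spearman_cor(1:6, (1:6)^2)$r, 1)
  expect_equal(spearman_cor(1:6, -(1:6))$r, -1)
  # frozen hand value: d^2 = (1,1,1,1,0), r = 1 - 6*4/120 = 0.8
  expect_equal(spearman_cor(1:5, c(2, 1, 4, 3, 5))$r, 0.8, tolerance = 1e-12)
  set.seed(6)
  x <- rnorm(20)
  expect_equal(spearman_cor(x, x)$r, 1)
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
})

test_that("Kaplan-Meier reproduces the empirical survivor function", {
  km <- kaplan_meier(c(1, 2, 3, 4, 5), rep(TRUE, 5))
  expect_equal(km$surv, c(0.8, 0.6, 0.4, 0.2, 0))
  expect_equal(km$median, 3)

  # no censoring: S(t) equals the empirical proportion still alive
  set.seed(21)
  t <- sample(1:40, 25, replace = TRUE)
  km2 <- kaplan_meier(t, rep(TRUE, 25))
  emp <- vapply(km2$time, function(tt) mean(t > tt), numeric(1))
  expect_equal(km2$surv, emp, tolerance = 1e-12)
  expect_true(all(diff(km2$surv) <= 0))
  expect_equal(km2$surv[1] <= 1, TRUE)

  expect_true(is.na(kaplan_meier(c(3, 7, 9), rep(FALSE, 3))$median))
  expect_equal(kaplan_meier(5, TRUE)$median, 5)
  expect_error(kaplan_meier(numeric(0), logical(0)), "empty")
})

test_that("log-rank matches the hand tabulation and is label-symmetric", {
  t <- c(1, 2, 3, 10, 20, 30)
  e <- rep(TRUE, 6)
  g <- rep(c("A", "B"), each = 3)
  res <- log_rank(t, e, g)
  expect_equal(res$statistic, logrank_hand(t, e, g), tolerance = 1e-10)
  expect_false(res$degenerate)

  swapped <- log_rank(t, e, rep(c("B", "A"), each = 3))
  expect_equal(swapped$statistic, res$statistic, tolerance = 1e-10)

  # identical groups: statistic 0, p = 1
  res0 <- log_rank(rep(c(2, 5, 9), 2), rep(TRUE, 6), rep(c("A", "B"), 3))
  expect_equal(res0$statistic, 0, tolerance = 1e-10)
  expect_equal(res0$p_value, 1, tolerance = 1e-10)

  # all censored: degenerate
  resd <- log_rank(c(1, 2, 3, 4), rep(FALSE, 4), c("A", "A", "B", "B"))
  expect_true(resd$degenerate)
  expect_equal(resd$p_value, 1)
})

make_report_inputs <- function(n = 40, seed = 8) {
  set.seed(seed)
  ids <- sprintf("p%03d", seq_len(n))
  d50 <- exp(runif(n, log(8), log(90)))
  fits <- data.frame(patient_id = ids, d50 = d50, dx = d50 / 4, rss = 0,
                     n_obs = 6, converged = TRUE, identifiable = TRUE,
                     subgroup = as.character(aggressiveness(d50)),
                     stringsAsFactors = FALSE)
  m50 <- 0.5 * d50 * exp(rnorm(n, 0, 0.15))
  metrics <- data.frame(patient_id = ids, m50 = m50, cmap50 = 0.6 * d50,
                        musix200 = 0.6 * d50,
                        m50_status = "defined", cmap50_status = "defined",
                        musix200_status = "defined",
                        munix_ratio = 0.5, cmap_ratio = 0.6, musix_ratio = 1.5,
                        t_munix_months = 0.6 * d50,
                        stringsAsFactors = FALSE)
  surv <- data.frame(patient_id = ids, time_months = 1.8 * d50,
                     event = TRUE, stringsAsFactors = FALSE)
  list(fits = fits, metrics = metrics, surv = surv)
}

test_that("the stratified cohort report has ordered subgroup medians", {
  inp <- make_report_inputs()
  rep <- summarize_cohort(inp$fits, inp$metrics, inp$surv)
  expect_s3_class(rep, "cohort_report")
  agg <- rep$by_aggressiveness
  expect_true(agg$high$m50$median < agg$intermediate$m50$median)
  expect_true(agg$intermediate$m50$median < agg$low$m50$median)
  expect_true(agg$high$d50$median < 20)
  # per-metric n sums to the cohort size within each stratification
  expect_equal(sum(vapply(agg, function(s) s$n, numeric(1))), rep$n_patients)
  # D50 splits low/high by the median with a log-rank result attached
  expect_true(rep$splits$d50$log_rank$statistic > 0)
  expect_equal(sort(unique(rep$survival_summary$split)),
               c("cmap50", "d50", "m50", "musix200"))
  # separation groups cover every patient once
  expect_equal(sum(unlist(rep$separation$counts)), rep$n_patients)
})

test_that("single-patient and undefined-metric strata degrade gracefully", {
  inp <- make_report_inputs(n = 1)
  one <- summarize_cohort(inp$fits, inp$metrics, inp$surv)
  g <- inp$fits$subgroup[1]
  expect_equal(one$by_aggressiveness[[g]]$m50$median, inp$metrics$m50[1])
  expect_equal(one$by_aggressiveness[[g]]$m50$q3 -
                 one$by_aggressiveness[[g]]$m50$q1, 0)

  inp2 <- make_report_inputs(n = 20)
  inp2$metrics$musix200 <- NA_real_
  inp2$metrics$musix200_status <- "no_increase"
  rep2 <- summarize_cohort(inp2$fits, inp2$metrics, inp2$surv)
  for (g in names(rep2$by_aggressiveness)) {
    s <- rep2$by_aggressiveness[[g]]
    if (!is.null(s)) expect_equal(s$musix200$n, 0)
  }
  expect_false("musix200" %in% names(rep2$splits))
})
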