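test_that("MUSIX is the CMAP/MUNIX quotient in microvolts", {
  expect_identical(musix(0.5, 2), 250)
  expect_identical(musix(10, 100), 100)
  expect_identical(musix(6, 100), 60)
  expect_error(musix(5, 0), "positive")
})

test_that("floor substitution triggers on unobtainable or sub-guideline CMAP", {
  fl <- apply_floors(NA_real_, NA_real_, obtainable = FALSE)
  expect_equal(unlist(fl[c("munix", "cmap_mV", "musix")]),
               c(munix = 2, cmap_mV = 0.5, musix = 250))
  expect_true(fl$floored)

  # CMAP at or below the 0.5 mV guideline bound is floored even if recorded
  fl2 <- apply_floors(8, 0.4, obtainable = TRUE)
  expect_true(fl2$floored)
  expect_equal(fl2$musix, 250)

  # a clean measurement passes through with derived MUSIX
  fl3 <- apply_floors(100, 6.0, obtainable = TRUE)
  expect_false(fl3$floored)
  expect_equal(unlist(fl3[c("munix", "cmap_mV", "musix")]),
               c(munix = 100, cmap_mV = 6, musix = 60))
})

test_that("floors never raise values that already exceed them", {
  set.seed(5)
  raw_munix <- runif(50, 2.5, 200)
  raw_cmap <- runif(50, 0.6, 12)
  fl <- apply_floors(raw_munix, raw_cmap, obtainable = TRUE)
  expect_true(all(fl$munix <= raw_munix))
  expect_true(all(fl$cmap_mV <= raw_cmap))
  expect_true(all(!fl$floored))
})

test_that("three-muscle sums include floored values", {
  panel <- apply_floors(c(100, 80, 60), c(6, 5, 4))
  panel$muscle <- c("APB", "ADM", "TA")
  s <- sum_scores(panel)
  expect_equal(s$munix_sum, 240)
  expect_equal(s$cmap_sum_mV, 15)

  mixed <- apply_floors(c(NA, NA, 50), c(NA, NA, 4), c(FALSE, FALSE, TRUE))
  mixed$muscle <- c("APB", "ADM", "TA")
  expect_equal(sum_scores(mixed)$munix_sum, 54)  # 2 + 2 + 50

  expect_error(sum_scores(panel[1:2, ]), "exactly")
})

test_that("control baseline means and SDs define the 100% level", {
  ctrl <- fixture_controls()
  b <- control_baseline(ctrl)
  expect_equal(b$n_controls, 3)
  pm <- b$per_muscle
  expect_equal(pm$munix_mean[pm$muscle == "APB"], 170)
  expect_equal(pm$munix_sd[pm$muscle == "APB"], sd(c(160, 180, 170)))
  expect_equal(b$munix_sum_mean, sum(pm$munix_mean))
  expect_equal(b$cmap_sum_mean_mV, (10 + 11 + 10.5) / 3 + 11 + 6)

  # single control: means are that control, SDs reported as 0
  b1 <- control_baseline(ctrl[ctrl$control_id == "C1", ])
  expect_equal(b1$per_muscle$munix_sd, rep(0, 3))
  expect_equal(b1$munix_sum_mean, 160 + 150 + 130)

  # identical controls: SD exactly 0
  same <- rbind(ctrl[ctrl$control_id == "C1", ],
                transform(ctrl[ctrl$control_id == "C1", ], control_id = "C9"))
  expect_equal(control_baseline(same)$per_muscle$munix_sd, rep(0, 3))
  expect_error(control_baseline(ctrl[0, ]), "empty")
})

test_that("linear time-to-threshold matches its closed form and oracle", {
  expect_equal(time_to_fraction_linear(14.9, 0.5, 0.5), 14.9)
  expect_equal(time_to_fraction_linear(10, 0.75, 0.5), 20)
  expect_equal(time_to_fraction_linear(10, 1.5, 2.0), 20)
  expect_equal(time_to_fraction_linear(10, 0.75, 0.5),
               step_oracle(10, 0.75, 0.5), tolerance = 1e-3)
  expect_equal(time_to_fraction_linear(10, 1.5, 2.0),
               step_oracle(10, 1.5, 2.0), tolerance = 1e-3)
  expect_error(time_to_fraction_linear(10, 1, 0.5), "no change")
  expect_error(time_to_fraction_linear(10, 1.2, 0.5), "not reachable")
  expect_error(time_to_fraction_linear(10, 0.8, 2.0), "not reachable")
})

test_that("M50, CMAP50 and MUSIX200 follow the panel ratios", {
  b <- control_baseline(fixture_controls())
  mk_panel <- function(munix_frac, cmap_frac) {
    pm <- b$per_muscle
    p <- apply_floors(pm$munix_mean * munix_frac, pm$cmap_mean_mV * cmap_frac)
    p$muscle <- pm$muscle
    p
  }

  # panel exactly at 50% of baseline at t = 12 -> M50 = 12
  m <- patient_metrics(mk_panel(0.5, 0.5), 12, b)
  expect_equal(m$m50, 12)
  expect_equal(m$cmap50, 12)
  expect_equal(m$m50_status, "defined")

  # 75% at t = 10 -> 20 months to halving
  m2 <- patient_metrics(mk_panel(0.75, 0.8), 10, b)
  expect_equal(m2$m50, 20)
  expect_equal(m2$cmap50, 25)

  # no decrease: MUNIX above the control mean
  m3 <- patient_metrics(mk_panel(1.02, 1.05), 10, b)
  expect_equal(m3$m50_status, "no_decrease")
  expect_equal(m3$cmap50_status, "no_decrease")
  expect_true(is.na(m3$m50))

  # MUSIX doubling against a single-control baseline (exact quotient)
  ctrl1 <- fixture_controls()
  b1 <- control_baseline(ctrl1[ctrl1$control_id == "C1", ])
  pm1 <- b1$per_muscle
  p4 <- apply_floors(pm1$munix_mean * 0.4, pm1$cmap_mean_mV * 0.8)
  p4$muscle <- pm1$muscle
  m4 <- patient_metrics(p4, 9, b1)
  expect_equal(m4$musix_ratio, 2, tolerance = 1e-12)
  expect_equal(m4$musix200, 9)
  m5 <- patient_metrics(mk_panel(0.9, 0.9), 10, b)
  expect_equal(m5$musix200_status, "no_increase")
})

test_that("M50 is invariant to rescaling all MUNIX values", {
  ctrl <- fixture_controls()
  b <- control_baseline(ctrl)
  pm <- b$per_muscle
  p <- apply_floors(pm$munix_mean * 0.6, pm$cmap_mean_mV * 0.7)
  p$muscle <- pm$muscle
  m50_ref <- patient_metrics(p, 11, b)$m50

  for (c_scale in c(0.5, 3, 10)) {
    ctrl2 <- transform(ctrl, munix = munix * c_scale)
    b2 <- control_baseline(ctrl2)
    p2 <- p; p2$munix <- p$munix * c_scale
    p2$musix <- p2$cmap_mV * 1000 / p2$munix
    expect_equal(patient_metrics(p2, 11, b2)$m50, m50_ref, tolerance = 1e-12)
  }
})

test_that("closed form agrees with the stepping oracle over random inputs", {
  set.seed(77)
  for (k in 1:60) {
    t_obs <- runif(1, 4, 30)
    if (k %% 2 == 0) {
      r <- runif(1, 0.2, 0.9); target <- 0.5
    } else {
      r <- runif(1, 1.1, 3); target <- 2.0
    }
    expect_equal(time_to_fraction_linear(t_obs, r, target),
                 step_oracle(t_obs, r, target), tolerance = 1.1e-3)
  }
})
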