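test_that("simulated soil temperature has the requested structure", {
  # zero amplitudes, zero noise: constant series; GDD accrues level/day
  s <- simulate_soil_temperature("2007-01-01", "2007-03-01", level = 10,
                                 seasonal_amplitude = 0,
                                 diurnal_amplitude = 0, noise_sd = 0,
                                 seed = 1)
  expect_true(all(s$temp_c == 10))
  g <- gdd_accumulate(daily_extremes(s),
                      crop_config("c", 0, gdd_start = "2007-01-01"))
  expect_equal(g$gdd_cum, 10 * seq_len(nrow(g)))

  # same seed twice: identical series
  s1 <- simulate_soil_temperature("2007-01-01", "2007-02-15", seed = 4)
  s2 <- simulate_soil_temperature("2007-01-01", "2007-02-15", seed = 4)
  expect_identical(s1, s2)

  # diurnal amplitude 5, no noise: daily range exactly 10
  s3 <- simulate_soil_temperature("2007-01-01", "2007-02-15", level = 12,
                                  seasonal_amplitude = 6,
                                  diurnal_amplitude = 5, noise_sd = 0,
                                  seed = 1)
  d3 <- daily_extremes(s3)
  expect_equal(d3$tmax - d3$tmin, rep(10, nrow(d3)))

  expect_error(simulate_soil_temperature("2007-01-01", "2007-03-01",
                                         diurnal_amplitude = -1),
               "nonnegative")
  expect_error(simulate_soil_temperature("2007-01-01", "2007-01-15"),
               "30 days")
})

test_that("cohort trial respects survival structure", {
  g <- gdd_from_increments(rep(20, 120))
  crops <- list(c1 = crop_config("c1", 0, gdd_start = "2007-01-01"))
  des <- trial_design(crops, plots_per_crop = 2L, plants_per_visit = 5L,
                      n_plants_per_plot = 20L,
                      sampling_start = "2007-04-20", n_visits = 1L)
  # late visit (2400 GDD), no attrition: identical counts at all stages
  pp <- sim_params(lambda = 4, init_median_gdd = 600, init_log_sd = 0.1,
                   stage_dgdd = rep(50, 6), survival = rep(1, 7),
                   plot_effect_sd = 0)
  recs <- simulate_trial(des, pp, g, seed = 5)
  m <- as.matrix(recs[, STAGES])
  expect_true(all(m == m[, 1]))

  # survival zero into T5 blocks all later stages
  pp2 <- sim_params(lambda = 4, init_median_gdd = 600, init_log_sd = 0.1,
                    stage_dgdd = rep(50, 6),
                    survival = c(1, 1, 1, 1, 1e-9, 1, 1))
  recs2 <- simulate_trial(des, pp2, g, seed = 5)
  expect_true(all(recs2[, c("T5", "T6", "T7")] == 0))
  expect_true(any(recs2$T4 > 0))

  # determinism and the cumulative stage invariant
  recs3 <- simulate_trial(des, pp, g, seed = 9)
  expect_identical(recs3, simulate_trial(des, pp, g, seed = 9))

  # destructive sampling cannot exceed the plot
  des_over <- trial_design(crops, plants_per_visit = 6L,
                           n_plants_per_plot = 10L,
                           sampling_start = "2007-04-20", n_visits = 2L)
  expect_error(simulate_trial(des_over, pp, g, seed = 1), "available")
})

test_that("late-visit mean T1 count matches the Poisson intensity", {
  g <- gdd_from_increments(rep(20, 120))
  crops <- list(c1 = crop_config("c1", 0, gdd_start = "2007-01-01"))
  n_big <- 4000L
  des <- trial_design(crops, plots_per_crop = 1L,
                      plants_per_visit = n_big,
                      n_plants_per_plot = n_big,
                      sampling_start = "2007-04-20", n_visits = 1L)
  pp <- sim_params(lambda = 5, init_median_gdd = 600, init_log_sd = 0.05,
                   stage_dgdd = rep(30, 6), survival = rep(1, 7),
                   plot_effect_sd = 0)
  recs <- simulate_trial(des, pp, g, seed = 17)
  se <- sqrt(5 / n_big)
  expect_lt(abs(mean(recs$T1) - 5), 3 * se)
})

test_that("cumulative stage counts never increase with stage index", {
  sc <- build_scenario(seed = 23)
  recs <- simulate_trial(sc$design, sc$params, sc$gdds, seed = 23)
  m <- as.matrix(recs[, STAGES])
  expect_true(all(m[, -1] <= m[, -7]))
})

test_that("population curves plateau at lambda times cumulative survival", {
  pp <- sim_params(lambda = 6, init_median_gdd = 700, init_log_sd = 0.1,
                   stage_dgdd = rep(40, 6),
                   survival = c(1, 0.9, 0.8, 1, 0.7, 0.5, 1))
  xs <- seq(100, 3000, by = 50)
  for (k in c(1, 3, 5)) {
    curve <- cohort_expected_curve(pp, xs, STAGES[k])
    expect_true(all(diff(curve) >= 0))
    expect_equal(curve[length(curve)],
                 6 * prod(pp$survival[1:k]), tolerance = 1e-6)
  }
})

test_that("direct curve simulation is exact at zero noise and seeded", {
  sc <- build_scenario(seed = 29)
  p <- c(a = 0.75, b = -18, x0 = 880)
  pts <- simulate_from_curves(list(T1 = p), sc$design, 0,
                              sc$gdds$faba_bean, seed = 3)
  expect_equal(pts$Y, logistic_eval(p, pts$x))
  fit <- fit_logistic(pts[, c("x", "Y")])
  expect_equal(unname(fit$params), unname(p), tolerance = 1e-6)
  pts_a <- simulate_from_curves(list(T1 = p), sc$design, 0.05,
                                sc$gdds$faba_bean, seed = 3)
  pts_b <- simulate_from_curves(list(T1 = p), sc$design, 0.05,
                                sc$gdds$faba_bean, seed = 3)
  expect_identical(pts_a, pts_b)
})

test_that("fitted x0 uncertainty matches the repeated-fit spread", {
  # noise at the scale reported for a weekly 16-point design: the
  # model-based SE of x0 and the across-replicate SD should agree in order
  # of magnitude
  p <- c(a = 0.7769, b = -22.51, x0 = 826.41)
  rs <- recovery_simulation(p, 0.0561, c(600, 1400), n_points = 16,
                            n_reps = 60, seed = 11)
  set.seed(11 + 1)
  x <- seq(600, 1400, length.out = 16)
  fit1 <- fit_logistic(x, logistic_eval(p, x) + rnorm(16, 0, 0.0561))
  ratio <- fit1$se[["x0"]] / rs$sd[["x0"]]
  expect_gt(ratio, 1 / 3)
  expect_lt(ratio, 3)
})

test_that("study presets reproduce the reference T1 curves they target", {
  sp <- study_sim_params("2007")
  coefs <- reference_coefficients("2007")
  for (crop in names(sp)) {
    r <- coefs[coefs$crop == crop & coefs$stage == "T1", ]
    xs <- seq(300, 1400, length.out = 80)
    truth <- fit_logistic(xs,
                          log10(cohort_expected_curve(sp[[crop]], xs) + 1))
    expect_equal(truth$params[["a"]], r$a, tolerance = 0.02)
    expect_equal(truth$params[["x0"]], r$x0, tolerance = 0.01)
  }
})

test_that("trial pipeline recovers the cohort generator's T1 curve", {
  # the master property: simulate a full trial, transform, fit, and land
  # within 2 SE of the logistic approximation of the generator curve
  # evaluated at the trial's own design points
  sc <- build_scenario(seed = 3)
  crop <- "faba_bean"
  vx <- gdd_at(sc$gdds[[crop]], sc$design$sampling_dates)
  truth <- coef(fit_logistic(
    vx, log10(cohort_expected_curve(sc$params[[crop]], vx) + 1)))
  recs <- simulate_trial(sc$design, sc$params, sc$gdds, seed = 7)
  pts <- transform_counts(recs[recs$crop == crop, ], "T1", sc$gdds[[crop]])
  fit <- fit_logistic(pts)
  for (par in c("a", "b", "x0")) {
    expect_lt(abs(fit$params[[par]] - truth[[par]]), 2 * fit$se[[par]])
  }
})
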