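#' Simulate an hourly soil-temperature record
#'
#' Hourly readings are the sum of a seasonal sinusoid (annual period,
#' minimum in mid-January, as for soil at logger depth in a Mediterranean
#' winter), a diurnal sinusoid (daily maximum mid-afternoon) and Gaussian
#' noise. The seasonal term is evaluated per calendar day, so with zero
#' noise the within-day range is exactly twice the diurnal amplitude.
#'
#' @param start,end Dates bounding the record (inclusive); span must be at
#'   least 30 days.
#' @param level Mean soil temperature over the season, degC.
#' @param seasonal_amplitude Half-range of the annual cycle, degC (>= 0).
#' @param diurnal_amplitude Half-range of the daily cycle, degC (>= 0).
#' @param noise_sd Gaussian noise sd, degC (>= 0).
#' @param seed RNG seed; the series is deterministic given it.
#' @return Data frame with columns `timestamp`, `temp_c` (a temperature
#'   series accepted by [daily_extremes()]).
#' @export
simulate_soil_temperature <- function(start, end, level = 13,
                                      seasonal_amplitude = 7,
                                      diurnal_amplitude = 3,
                                      noise_sd = 0.3, seed = 1L) {
  start <- as.Date(start); end <- as.Date(end)
  if (as.integer(end - start) < 30L) stop("span must be at least 30 days")
  if (seasonal_amplitude < 0 || diurnal_amplitude < 0 || noise_sd < 0) {
    stop("amplitudes and noise sd must be nonnegative")
  }
  days <- seq(start, end, by = "day")
  doy <- as.integer(format(days, "%j"))
  seasonal <- level - seasonal_amplitude * cos(2 * pi * (doy - 15) / 365.25)
  hours <- 0:23
  diurnal <- diurnal_amplitude * cos(2 * pi * (hours - 15) / 24)
  temp <- rep(seasonal, each = 24L) + rep(diurnal, times = length(days))
  ts <- as.POSIXct(paste(rep(format(days), each = 24L),
                         sprintf("%02d:00:00", rep(hours, length(days)))),
                   tz = "UTC")
  set.seed(seed)
  temp <- temp + stats::rnorm(length(temp), 0, noise_sd)
  validate_temperature_series(data.frame(timestamp = ts, temp_c = temp))
}

#' Field-trial layout
#'
#' Defaults mirror a randomized complete block legume trial: four plots per
#' crop, five plants destructively sampled per plot at weekly visits
#' starting the first week of February, sixteen visits.
#'
#' @param crops Named list of [crop_config()] objects.
#' @param plots_per_crop Plots (replicates) per crop.
#' @param plants_per_visit Plants extracted per plot per visit.
#' @param n_plants_per_plot Plants available per plot (destructive sampling
#'   draws without replacement from this pool).
#' @param sampling_start First sampling date.
#' @param n_visits Number of visits.
#' @param cadence_days Days between visits (default 7).
#' @return Object of class `trial_design`.
#' @export
trial_design <- function(crops, plots_per_crop = 4L, plants_per_visit = 5L,
                         n_plants_per_plot = 100L,
                         sampling_start, n_visits = 16L,
                         cadence_days = 7L) {
  stopifnot(length(crops) >= 1L, plots_per_crop >= 1L,
            plants_per_visit >= 1L, cadence_days >= 1L)
  if (is.null(names(crops))) {
    names(crops) <- vapply(crops, function(cc) cc$crop, character(1))
  }
  dates <- as.Date(sampling_start) +
    cadence_days * (seq_len(n_visits) - 1L)
  structure(list(crops = crops, plots_per_crop = as.integer(plots_per_crop),
                 plants_per_visit = as.integer(plants_per_visit),
                 n_plants_per_plot = as.integer(n_plants_per_plot),
                 sampling_dates = dates),
            class = "trial_design")
}

#' Cohort-model parameters for one crop
#'
#' The simulator's mechanistic model: each host plant receives
#' `N ~ Poisson(lambda * plot effect)` attachments; each attachment starts
#' (reaches T1) at a lognormally distributed GDD; it advances through
#' stages separated by fixed thermal-time increments `stage_dgdd`
#' (T1->T2 ... T6->T7) and survives each stage transition k independently
#' with probability `survival[k]` — an attachment that fails is frozen at
#' the last stage reached. Plot effects are multiplicative lognormal with
#' unit mean.
#'
#' @param lambda Mean attachments per plant (> 0).
#' @param init_median_gdd Median GDD at which attachments reach T1.
#' @param init_log_sd Log-scale sd of the initiation GDD (> 0).
#' @param stage_dgdd Length-6 positive vector of GDD between successive
#'   stages.
#' @param survival Length-7 vector of per-stage survival probabilities in
#'   (0, 1].
#' @param plot_effect_sd Lognormal sd of the plot-level multiplier (>= 0).
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(lambda = 5, init_median_gdd = 870,
                       init_log_sd = 0.08,
                       stage_dgdd = c(70, 70, 90, 210, 35, 60),
                       survival = c(1, 0.96, 0.94, 0.98, 0.77, 0.45, 0.8),
                       plot_effect_sd = 0.08) {
  stopifnot(lambda > 0, init_median_gdd > 0, init_log_sd > 0,
            length(stage_dgdd) == 6L, all(stage_dgdd > 0),
            length(survival) == 7L,
            all(survival > 0 & survival <= 1),
            plot_effect_sd >= 0)
  structure(list(lambda = lambda, init_median_gdd = init_median_gdd,
                 init_log_sd = init_log_sd, stage_dgdd = stage_dgdd,
                 survival = survival, plot_effect_sd = plot_effect_sd),
            class = "sim_params")
}

#' Crop-and-season simulator presets calibrated to reference coefficients
#'
#' Builds per-crop [sim_params()] whose emergent T1 logistic curve matches a
#' row of the reference coefficient tables (see
#' [reference_coefficients()]): `lambda` reproduces the T1 asymptote on the
#' count scale (`10^a - 1`), stage increments are the successive
#' differences of the printed half-maximum GDDs, per-stage survivals are
#' the ratios of successive plateau counts, and the initiation median is
#' chosen so that the half-maximum of `log10(mean + 1)` falls at the
#' printed T1 `x0`: with `a = log10(lambda + 1)`, half of `a` on the count
#' scale is `sqrt(lambda + 1) - 1`, reached at the
#' `(sqrt(lambda + 1) - 1)/lambda` quantile of the initiation lognormal.
#'
#' @param season `"2007"` or `"2008"` (harvest-year labels).
#' @param init_log_sd Initiation spread passed through to [sim_params()].
#' @param plot_effect_sd Passed through to [sim_params()].
#' @return Named list of `sim_params`, one per crop
#'   (`faba_bean`, `grass_pea`, `lentil`).
#' @export
study_sim_params <- function(season = c("2007", "2008"),
                             init_log_sd = 0.08, plot_effect_sd = 0.08) {
  season <- match.arg(season)
  coefs <- reference_coefficients(season)
  out <- list()
  for (crop in unique(coefs$crop)) {
    cc <- coefs[coefs$crop == crop, , drop = FALSE]
    cc <- cc[order(match(cc$stage, STAGES)), , drop = FALSE]
    plateau <- 10^cc$a - 1
    lambda <- plateau[1]
    x0 <- cc$x0
    dg <- diff(x0)
    dg <- pmax(dg, 5)                       # keep increments positive
    dg <- c(dg, rep(50, 6 - length(dg)))[1:6]
    surv <- c(1, pmin(1, plateau[-1] / plateau[-length(plateau)]))
    surv <- c(surv, rep(0.8, 7 - length(surv)))[1:7]
    q_half <- (sqrt(lambda + 1) - 1) / lambda
    med <- x0[1] * exp(-init_log_sd * stats::qnorm(q_half))
    out[[crop]] <- sim_params(lambda = lambda, init_median_gdd = med,
                              init_log_sd = init_log_sd,
                              stage_dgdd = dg, survival = surv,
                              plot_effect_sd = plot_effect_sd)
  }
  out
}

#' Expected per-stage population curve of the cohort model
#'
#' Closed form for the mean attachments per plant having reached at least
#' each stage by thermal time `x`: stage k is reached at initiation plus
#' the cumulative stage increments, and survived with the product of
#' per-stage survivals, so the expected count is
#' `lambda * prod(survival[1:k]) * F(x - D_k)` with `F` the initiation
#' lognormal CDF. Used as the generator truth in recovery checks.
#'
#' @param params A [sim_params()].
#' @param x GDD vector.
#' @param stage Stage code.
#' @return Expected mean count per plant at >= `stage`.
#' @export
cohort_expected_curve <- function(params, x, stage = "T1") {
  k <- match(stage, STAGES)
  if (is.na(k)) stop("unknown stage: ", stage)
  d_k <- c(0, cumsum(params$stage_dgdd))[k]
  s_k <- prod(params$survival[seq_len(k)])
  xx <- pmax(x - d_k, 0)
  f <- ifelse(xx > 0,
              stats::plnorm(xx, meanlog = log(params$init_median_gdd),
                            sdlog = params$init_log_sd),
              0)
  params$lambda * s_k * f
}

#' Simulate a stage-structured field sampling campaign
#'
#' Runs the cohort model of [sim_params()] over a [trial_design()]: plot
#' effects, per-plant Poisson attachment numbers, lognormal initiation
#' GDDs, fixed stage increments and per-stage survival, then destructive
#' weekly sampling without replacement within each plot. Each sampled
#' plant's record reports, per stage, the attachments having reached at
#' least that stage by the visit's cumulative GDD.
#'
#' @param design A [trial_design()].
#' @param params A single [sim_params()] applied to all crops, or a named
#'   list with one per crop in the design.
#' @param gdd A `gdd_series`, or a named list of them per crop (base
#'   temperatures differ between crops), covering all sampling dates.
#' @param seed RNG seed; output is deterministic given it.
#' @return Sampling records: data frame `date`, `crop`, `plot`, `plant`,
#'   `T1`..`T7` (cumulative counts), validated.
#' @export
simulate_trial <- function(design, params, gdd, seed = 1L) {
  stopifnot(inherits(design, "trial_design"))
  n_visits <- length(design$sampling_dates)
  need <- n_visits * design$plants_per_visit
  if (need > design$n_plants_per_plot) {
    stop("design samples ", need, " plants per plot but only ",
         design$n_plants_per_plot, " are available")
  }
  set.seed(seed)
  rows <- list()
  for (crop in names(design$crops)) {
    pp <- if (inherits(params, "sim_params")) params else params[[crop]]
    if (is.null(pp)) stop("no sim_params for crop ", crop)
    gs <- if (inherits(gdd, "gdd_series")) gdd else gdd[[crop]]
    if (is.null(gs)) stop("no gdd_series for crop ", crop)
    visit_gdd <- gdd_at(gs, design$sampling_dates)
    d_cum <- c(0, cumsum(pp$stage_dgdd))      # GDD from T1 to each stage
    for (plot in seq_len(design$plots_per_crop)) {
      eff <- stats::rlnorm(1, -pp$plot_effect_sd^2 / 2, pp$plot_effect_sd)
      n_att <- stats::rpois(design$n_plants_per_plot, pp$lambda * eff)
      plant_of <- rep(seq_len(design$n_plants_per_plot), n_att)
      total <- sum(n_att)
      init <- stats::rlnorm(total, log(pp$init_median_gdd), pp$init_log_sd)
      # highest stage each attachment can ever reach (survival chain)
      alive <- matrix(stats::runif(total * 7) <=
                        rep(pp$survival, each = total), total, 7)
      reach_max <- apply(alive, 1L, function(r) {
        w <- which(!r); if (length(w)) w[1] - 1L else 7L
      })
      order_pool <- sample(design$n_plants_per_plot)
      taken <- 0L
      for (v in seq_len(n_visits)) {
        ids <- order_pool[taken + seq_len(design$plants_per_visit)]
        taken <- taken + design$plants_per_visit
        g <- visit_gdd[v]
        sel_att <- plant_of %in% ids
        cnt <- matrix(0L, length(ids), 7,
                      dimnames = list(as.character(ids), STAGES))
        for (k in 1:7) {
          ok <- sel_att & reach_max >= k & init + d_cum[k] <= g
          if (any(ok)) {
            tab <- table(plant_of[ok])
            cnt[names(tab), k] <- as.integer(tab)
          }
        }
        block <- data.frame(date = design$sampling_dates[v], crop = crop,
                            plot = plot, plant = ids)
        block[STAGES] <- cnt
        rows[[length(rows) + 1L]] <- block
      }
    }
  }
  validate_sampling(do.call(rbind, rows))
}

#' Simulate log-scale stage points directly from logistic curves
#'
#' Bypasses the cohort model: for each sampling date and plot,
#' `Y = logistic_eval(params, gdd) + N(0, noise_sd)`. This is the direct
#' generator used to exercise the fitter under known truth.
#'
#' @param params_by_stage Named list (by stage code) of logistic parameter
#'   vectors `c(a, b, x0)`, or a single vector for one unnamed stage.
#' @param design A [trial_design()] (dates and plot count are used).
#' @param noise_sd Gaussian sd on the log10 scale.
#' @param gdd A `gdd_series` covering the sampling dates.
#' @param seed RNG seed.
#' @return Data frame with columns `stage`, `plot`, `date`, `x`, `Y`.
#' @export
simulate_from_curves <- function(params_by_stage, design, noise_sd, gdd,
                                 seed = 1L) {
  if (!is.list(params_by_stage)) {
    params_by_stage <- list(T1 = params_by_stage)
  }
  for (p in params_by_stage) check_params(p)
  stopifnot(noise_sd >= 0)
  x <- gdd_at(gdd, design$sampling_dates)
  set.seed(seed)
  rows <- list()
  for (st in names(params_by_stage)) {
    for (plot in seq_len(design$plots_per_crop)) {
      mu <- logistic_eval(params_by_stage[[st]], x)
      rows[[length(rows) + 1L]] <- data.frame(
        stage = st, plot = plot, date = design$sampling_dates,
        x = x, Y = mu + stats::rnorm(length(mu), 0, noise_sd))
    }
  }
  do.call(rbind, rows)
}

#' Parameter-recovery simulation for the logistic fitter
#'
#' Repeatedly generates `n_points` equally spaced observations over
#' `x_range` from the logistic with the given parameters plus Gaussian
#' noise, refits each replicate with [fit_logistic()], and returns the
#' recovered parameter averages — the standard check that the fitter is
#' unbiased at a given noise level and design.
#'
#' @param params True parameters `c(a, b, x0)`.
#' @param noise_sd Observation noise sd (log10 scale), typically the RMSE
#'   reported for a fitted curve.
#' @param x_range Length-2 GDD range covered by the design.
#' @param n_points Observations per replicate (default 16, one per weekly
#'   visit).
#' @param n_reps Number of replicates (default 200).
#' @param seed Base RNG seed; replicate r uses `seed + r`.
#' @return List with `mean` (named mean of fitted a, b, x0 over converged
#'   replicates), `sd`, `n_converged`, `estimates` (matrix).
#' @export
recovery_simulation <- function(params, noise_sd, x_range,
                                n_points = 16L, n_reps = 200L, seed = 1L) {
  p <- check_params(params)
  x <- seq(x_range[1], x_range[2], length.out = n_points)
  mu <- logistic_eval(p, x)
  est <- matrix(NA_real_, n_reps, 3,
                dimnames = list(NULL, c("a", "b", "x0")))
  for (r in seq_len(n_reps)) {
    set.seed(seed + r)
    y <- mu + stats::rnorm(n_points, 0, noise_sd)
    fit <- tryCatch(fit_logistic(x, y), error = function(e) NULL)
    if (!is.null(fit)) est[r, ] <- fit$params
  }
  ok <- stats::complete.cases(est)
  if (!any(ok)) stop("no recovery replicate converged")
  list(mean = colMeans(est[ok, , drop = FALSE]),
       sd = apply(est[ok, , drop = FALSE], 2, stats::sd),
       n_converged = sum(ok), estimates = est)
}
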