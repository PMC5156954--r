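# Shared fixtures, all generated in code.

# hourly series over consecutive days from a per-hour temperature function
hourly_series <- function(days, temp_fun) {
  ts <- as.POSIXct(character(0), tz = "UTC")
  temps <- numeric(0)
  for (d in seq_along(days)) {
    t_day <- as.POSIXct(paste(days[d], sprintf("%02d:00:00", 0:23)),
                        tz = "UTC")
    ts <- c(ts, t_day)
    temps <- c(temps, temp_fun(d, 0:23))
  }
  data.frame(timestamp = ts, temp_c = temps)
}

# gdd series with known daily increments starting at a given date
gdd_from_increments <- function(increments, start = as.Date("2007-01-01"),
                                tbase = 0, crop = "test") {
  dates <- start + seq_along(increments) - 1L
  structure(data.frame(date = dates, gdd_cum = cumsum(increments)),
            class = c("gdd_series", "data.frame"),
            tbase = tbase, crop = crop, start = start)
}

# minimal cumulative sampling records: one crop, counts per stage given as
# a named list date -> matrix(plants x 7) or a single count vector
records_one_date <- function(date, counts_by_plant, crop = "faba_bean",
                             plot = 1L) {
  df <- data.frame(date = as.Date(date), crop = crop, plot = plot,
                   plant = seq_len(nrow(counts_by_plant)))
  df[broomrape::STAGES] <- counts_by_plant
  df
}

# cumulative row helper: attachments at >= stage k
cum_row <- function(...) {
  v <- c(...)
  stopifnot(length(v) == 7L)
  matrix(v, nrow = 1)
}

# brute-force SSE grid search oracle for the logistic fit
grid_search_sse <- function(x, y, lower, upper, n = 60L) {
  grid_a <- seq(lower[["a"]], upper[["a"]], length.out = n)
  grid_b <- seq(lower[["b"]], upper[["b"]], length.out = n)
  grid_x0 <- seq(lower[["x0"]], upper[["x0"]], length.out = n)
  best <- Inf
  for (a in grid_a) {
    for (b in grid_b) {
      # vectorized over x0
      pred <- a / (1 + outer(grid_x0, x, function(x0, xx) (xx / x0)^b))
      sse <- rowSums(sweep(pred, 2L, y)^2)
      best <- min(best, min(sse))
    }
  }
  best
}

# bisection oracle: GDD where the logistic reaches q * a
bisect_logistic <- function(params, q, lo = 1, hi = 1e5,
                            tol = 1e-9) {
  target <- q * params[["a"]]
  f <- function(x) params[["a"]] / (1 + (x / params[["x0"]])^params[["b"]]) -
    target
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# random valid logistic parameters for property tests
random_params <- function() {
  c(a = stats::runif(1, 0.2, 2), b = stats::runif(1, -40, -2),
    x0 = stats::runif(1, 500, 1500))
}

# small simulated study scenario shared by pipeline tests
build_scenario <- function(season = "2007", seed = 3L) {
  yr <- as.integer(season)
  temp <- simulate_soil_temperature(sprintf("%d-01-01", yr),
                                    sprintf("%d-06-30", yr), seed = seed)
  days <- daily_extremes(temp)
  crops <- list(
    faba_bean = crop_config("faba_bean", 0, year = yr),
    grass_pea = crop_config("grass_pea", 0, year = yr),
    lentil = crop_config("lentil", 1.5, year = yr))
  gdds <- lapply(crops, function(cc) gdd_accumulate(days, cc))
  design <- trial_design(crops,
                         sampling_start = sprintf("%d-02-05", yr))
  list(season = season, temp = temp, days = days, crops = crops,
       gdds = gdds, design = design, params = study_sim_params(season))
}
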