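#' Read an hourly soil-temperature CSV
#'
#' Expects a header row and columns `timestamp` (ISO-8601, naive local time)
#' and `temp_c` (degrees Celsius). Timestamps must be strictly increasing
#' and temperatures within \[-30, 60\] degC; anything else is rejected.
#'
#' @param path Path to the CSV file.
#' @return A data frame with columns `timestamp` (POSIXct) and `temp_c`,
#'   validated as a temperature series.
#' @seealso [daily_extremes()]
#' @export
read_temperature_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "temp_c")
  if (!all(need %in% names(df))) {
    stop("temperature CSV must have columns 'timestamp' and 'temp_c'")
  }
  ts <- as.POSIXct(df$timestamp, tz = "UTC")
  if (anyNA(ts)) stop("unparseable timestamp in temperature CSV")
  validate_temperature_series(data.frame(timestamp = ts,
                                         temp_c = as.numeric(df$temp_c)))
}

validate_temperature_series <- function(series) {
  if (!is.data.frame(series) || nrow(series) == 0L) {
    stop("temperature series is empty")
  }
  if (anyNA(series$temp_c)) stop("missing temperature values")
  if (any(series$temp_c < -30 | series$temp_c > 60)) {
    stop("temperature outside plausible range [-30, 60] degC")
  }
  d <- diff(as.numeric(series$timestamp))
  if (any(d <= 0)) {
    stop("timestamps must be strictly increasing with at most one reading per timestamp")
  }
  series
}

#' Reduce hourly temperature readings to daily extremes
#'
#' Groups readings by local calendar day (midnight boundary) and takes the
#' maximum and minimum per day. Days with fewer than `min_readings` readings
#' — logger dropouts — are flagged and gap-filled by linear interpolation of
#' Tmax and Tmin separately across days (nearest-day value is carried at the
#' series edges). Calendar days wholly absent between the first and last
#' reading are treated the same way.
#'
#' @param series Data frame with columns `timestamp` (POSIXct) and `temp_c`,
#'   e.g. from [read_temperature_csv()] or [simulate_soil_temperature()].
#' @param min_readings Minimum readings for a day to count as observed
#'   (default 18 of 24).
#' @return Data frame with columns `date`, `tmax`, `tmin`, `n_readings`,
#'   `interpolated`.
#' @export
daily_extremes <- function(series, min_readings = 18L) {
  series <- validate_temperature_series(series)
  day <- as.Date(series$timestamp, tz = "UTC")
  agg_max <- tapply(series$temp_c, day, max)
  agg_min <- tapply(series$temp_c, day, min)
  agg_n <- tapply(series$temp_c, day, length)
  all_days <- seq(min(day), max(day), by = "day")
  key <- as.character(all_days)
  n_day <- unname(agg_n[key])
  out <- data.frame(
    date = all_days,
    tmax = unname(as.numeric(agg_max[key])),
    tmin = unname(as.numeric(agg_min[key])),
    n_readings = as.integer(ifelse(is.na(n_day), 0L, n_day)),
    row.names = NULL
  )
  out$interpolated <- out$n_readings < min_readings
  if (all(out$interpolated)) {
    stop("no day has at least ", min_readings, " readings")
  }
  if (any(out$interpolated)) {
    ok <- !out$interpolated
    idx <- seq_len(nrow(out))
    out$tmax[!ok] <- stats::approx(idx[ok], out$tmax[ok], idx[!ok], rule = 2)$y
    out$tmin[!ok] <- stats::approx(idx[ok], out$tmin[ok], idx[!ok], rule = 2)$y
  }
  stopifnot(all(out$tmax >= out$tmin))
  out
}

#' Crop configuration for thermal-time accumulation
#'
#' Bundles the crop-specific base temperature with the accumulation start
#' date. Base temperatures used in the field study this package was built
#' for: 0 degC for faba bean and grass pea, 1.5 degC for lentil; GDD
#' accumulation starts January 1st.
#'
#' @param crop Crop name (character scalar).
#' @param tbase Base temperature in degC; development is assumed to stop
#'   below it. Must be >= -10.
#' @param gdd_start Date from which GDD accumulates (default January 1st of
#'   `year`).
#' @param sowing_date Optional sowing date, recorded for reporting only.
#' @param year Calendar year used for the default `gdd_start`.
#' @return An object of class `crop_config`.
#' @export
crop_config <- function(crop, tbase, gdd_start = NULL, sowing_date = NULL,
                        year = NULL) {
  stopifnot(is.character(crop), length(crop) == 1L, is.numeric(tbase))
  if (tbase < -10) stop("tbase below -10 degC is not plausible")
  if (is.null(gdd_start)) {
    if (is.null(year)) stop("provide gdd_start or year")
    gdd_start <- as.Date(sprintf("%d-01-01", year))
  }
  structure(list(crop = crop, tbase = as.numeric(tbase),
                 gdd_start = as.Date(gdd_start),
                 sowing_date = if (is.null(sowing_date)) NULL
                               else as.Date(sowing_date)),
            class = "crop_config")
}

#' @export
print.crop_config <- function(x, ...) {
  cat(sprintf("Crop config: %s (Tbase = %g degC, GDD from %s)\n",
              x$crop, x$tbase, format(x$gdd_start)))
  invisible(x)
}

#' Accumulate growing degree days from daily extremes
#'
#' Daily increment is `(Tmax + Tmin)/2 - Tbase`, clamped at zero by default
#' (the standard convention when a source does not state the sub-base
#' variant), accumulated from `cfg$gdd_start`. The value reported for a date
#' is the day-end cumulative sum including that day's increment.
#'
#' @param days Daily extremes, as returned by [daily_extremes()]; must be
#'   sorted, gap-free and cover `cfg$gdd_start` onward.
#' @param cfg A [crop_config()].
#' @param clamp If `TRUE` (default) negative daily increments contribute 0;
#'   if `FALSE` they subtract.
#' @return An object of class `gdd_series`: a data frame with columns
#'   `date` and `gdd_cum`, carrying `tbase`, `crop` and `start` attributes.
#' @export
gdd_accumulate <- function(days, cfg, clamp = TRUE) {
  stopifnot(inherits(cfg, "crop_config"),
            all(c("date", "tmax", "tmin") %in% names(days)))
  days <- days[order(days$date), , drop = FALSE]
  if (any(diff(as.integer(days$date)) != 1L)) {
    stop("daily extremes contain unflagged gaps; run daily_extremes() first")
  }
  if (min(days$date) > cfg$gdd_start) {
    stop(sprintf("temperature record starts %s, after gdd_start %s",
                 format(min(days$date)), format(cfg$gdd_start)))
  }
  days <- days[days$date >= cfg$gdd_start, , drop = FALSE]
  inc <- (days$tmax + days$tmin) / 2 - cfg$tbase
  if (clamp) inc <- pmax(0, inc)
  out <- data.frame(date = days$date, gdd_cum = cumsum(inc))
  structure(out, class = c("gdd_series", "data.frame"),
            tbase = cfg$tbase, crop = cfg$crop, start = cfg$gdd_start)
}

#' @export
print.gdd_series <- function(x, ...) {
  cat(sprintf("GDD series: %s, Tbase %g degC, %s to %s, final %.1f GDD\n",
              attr(x, "crop") %||% "?", attr(x, "tbase"),
              format(min(x$date)), format(max(x$date)),
              x$gdd_cum[nrow(x)]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Look up cumulative GDD at given dates
#'
#' Returns the day-end cumulative GDD for each query date. Dates outside
#' the series span are an error.
#'
#' @param series A `gdd_series` from [gdd_accumulate()].
#' @param dates Date vector.
#' @return Numeric vector of cumulative GDD, same length as `dates`.
#' @export
gdd_at <- function(series, dates) {
  stopifnot(inherits(series, "gdd_series"))
  dates <- as.Date(dates)
  i <- match(dates, series$date)
  if (anyNA(i)) {
    stop("date(s) outside GDD series span: ",
         paste(format(dates[is.na(i)]), collapse = ", "))
  }
  series$gdd_cum[i]
}

#' Write a GDD series to CSV
#'
#' Columns `date`, `gdd_cum`.
#'
#' @param series A `gdd_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gdd_csv <- function(series, path) {
  utils::write.csv(data.frame(date = format(series$date),
                              gdd_cum = series$gdd_cum),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
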