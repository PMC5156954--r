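#' Configuration for a full analysis run
#'
#' @param temperature Named list (by season label) of either temperature
#'   CSV paths or in-memory temperature data frames.
#' @param sampling Named list (by season label) of sampling CSV paths or
#'   in-memory sampling record data frames.
#' @param crops Named list of [crop_config()] objects; every crop appearing
#'   in the sampling data must be present.
#' @param offset,convention Log-transform offset and back-transform
#'   convention (see [transform_counts()], [back_transform()]).
#' @param aggregation Point aggregation mode for [transform_counts()].
#' @param q_low,q_high,round_to Phase segmentation settings
#'   (see [segment_phases()]).
#' @param df_rule Degrees-of-freedom rule for [compare_all()].
#' @param min_points Minimum stage points required to attempt a fit.
#' @param seed Seed recorded in the report metadata (the analysis itself is
#'   deterministic).
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(temperature, sampling, crops,
                            offset = 1, convention = "direct",
                            aggregation = "per_plot_mean",
                            q_low = 0.05, q_high = 0.95, round_to = NULL,
                            df_rule = "pooled_resid", min_points = 5L,
                            seed = 1L) {
  stopifnot(is.list(temperature), is.list(sampling),
            identical(sort(names(temperature)), sort(names(sampling))),
            is.list(crops), length(crops) >= 1L)
  if (is.null(names(crops))) {
    names(crops) <- vapply(crops, function(cc) cc$crop, character(1))
  }
  for (src in c(temperature, sampling)) {
    if (is.character(src) && !file.exists(src)) {
      stop("input file does not exist: ", src)
    }
  }
  structure(list(temperature = temperature, sampling = sampling,
                 crops = crops, offset = offset, convention = convention,
                 aggregation = aggregation, q_low = q_low,
                 q_high = q_high, round_to = round_to, df_rule = df_rule,
                 min_points = as.integer(min_points), seed = seed),
            class = "analysis_config")
}

#' Run the full thermal-time parasitism analysis
#'
#' For each season: reduces the hourly temperature record to daily
#' extremes, accumulates GDD per crop (base temperatures differ), turns
#' stage counts into log-scale points, fits the three-parameter logistic
#' per stage x crop, segments each fitted curve into lag/log/maximum
#' phases, and finally compares fitted parameters between crops. Stages
#' whose fit fails or has too few points (typically T6/T7, rarely observed)
#' are reported as skipped rather than aborting the run. The whole
#' procedure is deterministic given the inputs.
#'
#' @param config An [analysis_config()].
#' @param verbose Log each fit's outcome with [message()].
#' @return Object of class `report_bundle`: list with `coefficients`
#'   (one row per successful fit, the machine twin of a published
#'   coefficient table), `comparisons` (from [compare_all()]), `phases`,
#'   `curves` (fitted-curve samples: `stage, crop, season, gdd, y_fit`),
#'   `skipped`, `fits` (the underlying `logistic_fit` objects) and `meta`.
#' @export
run_analysis <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  fits <- list()
  coef_rows <- list(); phase_rows <- list(); curve_rows <- list()
  skipped <- list()
  for (season in names(config$sampling)) {
    temp <- config$temperature[[season]]
    if (is.character(temp)) temp <- read_temperature_csv(temp)
    days <- daily_extremes(temp)
    samp <- config$sampling[[season]]
    if (is.character(samp)) samp <- load_sampling_csv(samp)
    samp <- validate_sampling(samp)
    crops_here <- unique(samp$crop)
    missing_cfg <- setdiff(crops_here, names(config$crops))
    if (length(missing_cfg)) {
      stop("no crop_config for: ", paste(missing_cfg, collapse = ", "))
    }
    for (crop in crops_here) {
      gdd <- gdd_accumulate(days, config$crops[[crop]])
      recs <- samp[samp$crop == crop, , drop = FALSE]
      for (stage in STAGES) {
        cell <- sprintf("%s/%s/%s", stage, crop, season)
        pts <- tryCatch(
          transform_counts(recs, stage, gdd,
                           aggregation = config$aggregation,
                           offset = config$offset),
          error = function(e) NULL)
        if (is.null(pts) || nrow(pts) < config$min_points ||
            diff(range(pts$Y)) < 0.1) {
          skipped[[length(skipped) + 1L]] <- data.frame(
            stage = stage, crop = crop, season = season,
            reason = "insufficient or uninformative data")
          if (verbose) message("skip ", cell, ": insufficient data")
          next
        }
        fit <- tryCatch(fit_logistic(pts), error = function(e) e)
        if (inherits(fit, "error")) {
          skipped[[length(skipped) + 1L]] <- data.frame(
            stage = stage, crop = crop, season = season,
            reason = paste("fit failed:", conditionMessage(fit)))
          if (verbose) message("skip ", cell, ": ", conditionMessage(fit))
          next
        }
        if (verbose) {
          message(sprintf("fit %s: x0=%.1f rmse=%.4f (%d/%d starts)",
                          cell, fit$params[["x0"]], fit$rmse,
                          fit$n_starts_converged, 9L))
        }
        fits[[fit_key(crop, stage, season)]] <- fit
        coef_rows[[length(coef_rows) + 1L]] <- data.frame(
          season = season, crop = crop, stage = stage,
          a = fit$params[["a"]], se_a = fit$se[["a"]],
          b = fit$params[["b"]], se_b = fit$se[["b"]],
          x0 = fit$params[["x0"]], se_x0 = fit$se[["x0"]],
          rmse = fit$rmse, p_regression = fit$p_regression,
          n_points = fit$n_points, df_resid = fit$df_resid,
          max_per_plant = back_transform(fit$params[["a"]],
                                         config$convention,
                                         config$offset))
        seg <- segment_phases(fit, config$q_low, config$q_high,
                              config$round_to)
        phase_rows[[length(phase_rows) + 1L]] <- data.frame(
          season = season, crop = crop, stage = stage,
          lag_end = seg$lag_end, log_end = seg$log_end,
          q_low = seg$q_low, q_high = seg$q_high)
        xs <- seq(min(pts$x), max(pts$x), length.out = 100)
        curve_rows[[length(curve_rows) + 1L]] <- data.frame(
          stage = stage, crop = crop, season = season, gdd = xs,
          y_fit = logistic_eval(fit$params, xs))
      }
    }
  }
  comparisons <- if (length(fits) >= 2L &&
                     length(unique(sub("\\|.*", "", names(fits)))) >= 2L) {
    compare_all(fits, df_rule = config$df_rule)
  } else {
    NULL
  }
  structure(list(
    coefficients = do.call(rbind, coef_rows),
    comparisons = comparisons,
    phases = do.call(rbind, phase_rows),
    curves = do.call(rbind, curve_rows),
    skipped = if (length(skipped)) do.call(rbind, skipped) else NULL,
    fits = fits,
    meta = list(seed = config$seed, df_rule = config$df_rule,
                offset = config$offset, aggregation = config$aggregation,
                package_version =
                  as.character(utils::packageVersion("broomrape")))
  ), class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("Analysis report: %d fits, %d comparisons, %d skipped cells\n",
              length(x$fits),
              if (is.null(x$comparisons)) 0L else nrow(x$comparisons),
              if (is.null(x$skipped)) 0L else nrow(x$skipped)))
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits `coefficients.csv`, `comparisons.csv`, `phases.csv`, `curves.csv`
#' and a machine-readable `report.json` (coefficients, comparisons, phases
#' and metadata) into `dir`. Files are written via temporary names and
#' renamed, so a crash never leaves a half-written table.
#'
#' @param bundle A `report_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  atomically <- function(write_fun, path) {
    tmp <- paste0(path, ".tmp")
    write_fun(tmp)
    file.rename(tmp, path)
  }
  tables <- list(coefficients = bundle$coefficients,
                 comparisons = bundle$comparisons,
                 phases = bundle$phases, curves = bundle$curves,
                 skipped = bundle$skipped)
  for (nm in names(tables)) {
    if (is.null(tables[[nm]])) next
    atomically(function(p) utils::write.csv(tables[[nm]], p,
                                            row.names = FALSE),
               file.path(dir, paste0(nm, ".csv")))
  }
  json <- list(coefficients = bundle$coefficients,
               comparisons = bundle$comparisons,
               phases = bundle$phases, meta = bundle$meta)
  atomically(function(p) jsonlite::write_json(json, p, dataframe = "rows",
                                              auto_unbox = TRUE,
                                              digits = NA, null = "null"),
             file.path(dir, "report.json"))
  invisible(dir)
}

#' Export one fit as JSON
#'
#' The machine twin of one coefficient-table row: parameters, SEs, RMSE,
#' regression p, point count and residual df.
#'
#' @param fit A `logistic_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(list(
    params = as.list(fit$params), se = as.list(fit$se),
    rmse = fit$rmse, p_regression = fit$p_regression,
    n_points = fit$n_points, df_resid = fit$df_resid),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
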