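#' Load a field sampling CSV
#'
#' Two dialects are accepted. Long form has columns
#' `date,crop,plot,plant,stage,count` where `stage` is one of T1..T7 and
#' `count` is the number of attachments at *exactly* that stage; counts are
#' cumulated internally so that the stored T_k column means "reached at
#' least stage k". Wide form (`wide = TRUE`) has columns
#' `date,crop,plot,plant,T1,...,T7`; with `cumulative = TRUE` the columns
#' are taken as already cumulated (and checked for nonincreasing order),
#' otherwise they are per-stage exact counts and are cumulated.
#'
#' @param path CSV path.
#' @param wide Is the file in wide form?
#' @param cumulative For wide form, are counts already cumulative?
#' @return A validated data frame with columns `date`, `crop`, `plot`,
#'   `plant`, `T1`..`T7` (cumulative counts).
#' @export
load_sampling_csv <- function(path, wide = FALSE, cumulative = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!wide) {
    need <- c("date", "crop", "plot", "plant", "stage", "count")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("sampling CSV lacks columns: ",
                           paste(miss, collapse = ", "))
    bad <- which(!df$stage %in% STAGES)
    if (length(bad)) {
      stop("unknown stage label '", df$stage[bad[1]], "' at data row ",
           bad[1])
    }
    bad <- which(!is.finite(df$count) | df$count < 0 |
                   df$count != round(df$count))
    if (length(bad)) {
      stop("invalid count '", df$count[bad[1]], "' at data row ", bad[1])
    }
    wide_df <- stats::reshape(
      df, idvar = c("date", "crop", "plot", "plant"),
      timevar = "stage", direction = "wide")
    names(wide_df) <- sub("^count\\.", "", names(wide_df))
    for (s in STAGES) {
      if (!s %in% names(wide_df)) wide_df[[s]] <- 0L
      wide_df[[s]][is.na(wide_df[[s]])] <- 0L
    }
    df <- wide_df
    cumulative <- FALSE
  } else {
    miss <- setdiff(c("date", "crop", "plot", "plant", STAGES), names(df))
    if (length(miss)) stop("sampling CSV lacks columns: ",
                           paste(miss, collapse = ", "))
    for (s in STAGES) {
      bad <- which(!is.finite(df[[s]]) | df[[s]] < 0)
      if (length(bad)) {
        stop("invalid count '", df[[s]][bad[1]], "' in column ", s,
             " at data row ", bad[1])
      }
    }
  }
  m <- as.matrix(df[, STAGES])
  if (!cumulative) {
    # exact per-stage counts -> "reached at least stage k"
    m <- t(apply(m, 1L, function(r) rev(cumsum(rev(r)))))
  }
  out <- data.frame(date = as.Date(df$date), crop = df$crop,
                    plot = df$plot, plant = df$plant)
  out[STAGES] <- m
  validate_sampling(out)
}

validate_sampling <- function(records) {
  miss <- setdiff(c("date", "crop", "plot", "plant", STAGES),
                  names(records))
  if (length(miss)) stop("sampling records lack columns: ",
                         paste(miss, collapse = ", "))
  m <- as.matrix(records[, STAGES])
  if (any(m < 0)) stop("negative attachment counts")
  dec <- m[, -1L, drop = FALSE] <= m[, -ncol(m), drop = FALSE]
  if (!all(dec)) {
    stop("cumulative counts must be nonincreasing from T1 to T7 ",
         "(row ", which(!apply(dec, 1L, all))[1], ")")
  }
  records
}

#' Write sampling records to CSV (long form)
#'
#' Inverse of [load_sampling_csv()]: cumulative stage counts are converted
#' back to exact per-stage counts and written in the long dialect, so a
#' write/read round trip reproduces the records.
#'
#' @param records Sampling records (cumulative wide form).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sampling_csv <- function(records, path) {
  records <- validate_sampling(records)
  m <- as.matrix(records[, STAGES])
  exact <- cbind(m[, -ncol(m), drop = FALSE] - m[, -1L, drop = FALSE],
                 m[, ncol(m)])
  colnames(exact) <- STAGES
  long <- do.call(rbind, lapply(seq_along(STAGES), function(k) {
    data.frame(date = format(records$date), crop = records$crop,
               plot = records$plot, plant = records$plant,
               stage = STAGES[k], count = exact[, k])
  }))
  long <- long[order(long$date, long$crop, long$plot, long$plant,
                     long$stage), ]
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Transform stage counts to log-scale points on the thermal-time axis
#'
#' For the chosen stage, computes the mean number of attachments per plant
#' having reached at least that stage — per plot and date under
#' `"per_plot_mean"` (the default: with 5 plants per plot this yields 4
#' replicate points per sampling date), or per date across the whole crop
#' under `"per_crop_mean"` — then maps each date onto cumulative GDD and
#' log-transforms: `Y = log10(mean + offset)`.
#'
#' @param records Sampling records for a single crop (cumulative wide form).
#' @param stage Stage code, `"T1"`..`"T7"`.
#' @param gdd A `gdd_series` covering all sampling dates.
#' @param aggregation `"per_plot_mean"` or `"per_crop_mean"`.
#' @param offset Added before the log10 (default 1, so zero counts map to
#'   Y = 0). A smaller offset with all-zero counts is an error.
#' @return Data frame of stage points: columns `x` (GDD), `Y`, `plot`
#'   (`NA` under per-crop aggregation).
#' @export
transform_counts <- function(records, stage, gdd,
                             aggregation = c("per_plot_mean",
                                             "per_crop_mean"),
                             offset = 1) {
  aggregation <- match.arg(aggregation)
  records <- validate_sampling(records)
  if (!stage %in% STAGES) stop("unknown stage: ", stage)
  if (length(unique(records$crop)) > 1L) {
    stop("records span several crops; subset to one crop first")
  }
  cnt <- records[[stage]]
  if (aggregation == "per_plot_mean") {
    key <- interaction(records$date, records$plot, drop = TRUE)
    mean_cnt <- tapply(cnt, key, mean)
    first <- !duplicated(key)
    dates <- records$date[first][match(names(mean_cnt), key[first])]
    plots <- records$plot[first][match(names(mean_cnt), key[first])]
  } else {
    mean_cnt <- tapply(cnt, records$date, mean)
    dates <- as.Date(names(mean_cnt))
    plots <- rep(NA, length(mean_cnt))
  }
  if (any(mean_cnt + offset <= 0)) {
    stop("offset ", offset, " gives a nonpositive argument to log10; ",
         "use a positive offset with zero counts")
  }
  out <- data.frame(x = gdd_at(gdd, dates),
                    Y = log10(as.numeric(mean_cnt) + offset),
                    plot = plots)
  out[order(out$x, out$plot), , drop = FALSE]
}
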