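#' Classify a p-value into significance classes
#'
#' `***` for p <= 0.001, `**` for p <= 0.01, `*` for p <= 0.05, `ns`
#' otherwise.
#'
#' @param p Probability in (0, 1].
#' @return Character vector of classes.
#' @export
classify_significance <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    stop("p must lie within (0, 1]")
  }
  ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**",
                                   ifelse(p <= 0.05, "*", "ns")))
}

#' Compare one fitted parameter between two crops
#'
#' The t statistic is the difference of the two estimates divided by the
#' standard error of that difference, computed as the square root of the
#' sum of the squares of the two standard errors — a reasonable estimate
#' when the two curves were fitted to (nearly) equal numbers of points.
#' Degrees of freedom follow `df_rule`: `"pooled_resid"` (default) sums the
#' two residual dfs; `"welch"` uses the Satterthwaite approximation from
#' the SEs and per-fit dfs; `"normal"` uses the normal reference
#' (infinite df).
#'
#' @param fit1,fit2 `logistic_fit` objects (or lists with `params`, `se`,
#'   `df_resid`).
#' @param parameter One of `"a"`, `"b"`, `"x0"`.
#' @param df_rule Degrees-of-freedom rule.
#' @param labels Optional character pair naming the two crops.
#' @return Object of class `param_comparison`: parameter, estimates, SEs,
#'   difference, `se_diff`, `t`, `df`, two-sided `p`, significance `class`.
#' @export
param_ttest <- function(fit1, fit2, parameter = c("a", "b", "x0"),
                        df_rule = c("pooled_resid", "welch", "normal"),
                        labels = c("crop1", "crop2")) {
  parameter <- match.arg(parameter)
  df_rule <- match.arg(df_rule)
  e1 <- fit1$params[[parameter]]; s1 <- fit1$se[[parameter]]
  e2 <- fit2$params[[parameter]]; s2 <- fit2$se[[parameter]]
  if (!all(is.finite(c(s1, s2))) || s1 <= 0 || s2 <= 0) {
    stop("standard errors must be positive")
  }
  se_diff <- sqrt(s1^2 + s2^2)
  tt <- (e1 - e2) / se_diff
  df <- switch(df_rule,
    pooled_resid = fit1$df_resid + fit2$df_resid,
    welch = (s1^2 + s2^2)^2 /
      (s1^4 / fit1$df_resid + s2^4 / fit2$df_resid),
    normal = Inf)
  p <- 2 * stats::pt(-abs(tt), df)
  p <- min(max(p, .Machine$double.xmin), 1)
  structure(list(parameter = parameter, pair = labels,
                 estimate1 = e1, se1 = s1, estimate2 = e2, se2 = s2,
                 difference = e1 - e2, se_diff = se_diff,
                 t = tt, df = df, df_rule = df_rule, p = p,
                 class = classify_significance(p)),
            class = "param_comparison")
}

#' @export
print.param_comparison <- function(x, ...) {
  cat(sprintf(
    "%s: %s (%.4g +/- %.3g) vs %s (%.4g +/- %.3g)\n  t = %.3f, df = %s, p = %.4g %s [%s]\n",
    x$parameter, x$pair[1], x$estimate1, x$se1, x$pair[2], x$estimate2,
    x$se2, x$t, format(round(x$df, 1)), x$p, x$class, x$df_rule))
  invisible(x)
}

#' Compare all crop pairs across stages, seasons and parameters
#'
#' Runs [param_ttest()] for every crop pair sharing a (stage, season) cell,
#' for each of the three parameters. Pairs where one crop lacks a fit are
#' emitted as rows with `NA` statistics rather than dropped, so the output
#' mirrors a full comparison table with explicit gaps.
#'
#' @param fits Named list of `logistic_fit` objects; names of the form
#'   `"crop|stage|season"` (see [fit_key()]), or a list of lists with
#'   elements `crop`, `stage`, `season`, `fit`.
#' @param df_rule Passed to [param_ttest()].
#' @return Data frame with one row per pair x parameter x stage x season:
#'   columns `stage`, `season`, `pair`, `parameter`, `t`, `df`, `p`,
#'   `class`.
#' @export
compare_all <- function(fits, df_rule = "pooled_resid") {
  if (length(fits) == 0L) {
    return(data.frame(stage = character(), season = character(),
                      pair = character(), parameter = character(),
                      t = numeric(), df = numeric(), p = numeric(),
                      class = character()))
  }
  meta <- do.call(rbind, lapply(names(fits), function(k) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    data.frame(crop = parts[1], stage = parts[2], season = parts[3],
               key = k)
  }))
  crops <- sort(unique(meta$crop))
  if (length(crops) < 2L) {
    stop("need fits for at least two crops to compare")
  }
  pairs <- utils::combn(crops, 2L, simplify = FALSE)
  rows <- list()
  for (season in sort(unique(meta$season))) {
    for (stage in STAGES[STAGES %in% meta$stage]) {
      for (pr in pairs) {
        k1 <- fit_key(pr[1], stage, season)
        k2 <- fit_key(pr[2], stage, season)
        in_season <- any(meta$season == season & meta$stage == stage)
        if (!in_season) next
        for (par in c("a", "b", "x0")) {
          if (is.null(fits[[k1]]) || is.null(fits[[k2]])) {
            rows[[length(rows) + 1L]] <- data.frame(
              stage = stage, season = season,
              pair = paste(pr, collapse = "-"), parameter = par,
              t = NA_real_, df = NA_real_, p = NA_real_,
              class = NA_character_)
          } else {
            cmp <- param_ttest(fits[[k1]], fits[[k2]], par,
                               df_rule = df_rule, labels = pr)
            rows[[length(rows) + 1L]] <- data.frame(
              stage = stage, season = season,
              pair = paste(pr, collapse = "-"), parameter = par,
              t = cmp$t, df = cmp$df, p = cmp$p, class = cmp$class)
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Key for a fit in a (crop, stage, season) map
#'
#' @param crop,stage,season Character scalars.
#' @return `"crop|stage|season"`.
#' @export
fit_key <- function(crop, stage, season) {
  paste(crop, stage, season, sep = "|")
}

#' Two-way species-by-year ANOVA on log attachment counts
#'
#' Fits the fixed-effects model `log10(count + offset) ~ species * year`
#' per developmental stage on replicate-level (plot) aggregated counts and
#' returns the F statistic and p-value for the species, year and
#' interaction terms.
#'
#' @param data Data frame with columns `species`, `year`, `replicate`,
#'   `stage`, `count` (mean attachments per plant at >= stage for that
#'   replicate).
#' @param offset Offset in the log transform (default 1).
#' @return Data frame with columns `stage`, `term`, `df`, `F`, `p`.
#' @export
anova_species_year <- function(data, offset = 1) {
  need <- c("species", "year", "replicate", "stage", "count")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (length(unique(data$species)) < 2L || length(unique(data$year)) < 2L) {
    stop("need at least two levels of both species and year")
  }
  rows <- list()
  for (st in unique(data$stage)) {
    d <- data[data$stage == st, , drop = FALSE]
    d$y <- log10(d$count + offset)
    if (stats::var(d$y) < .Machine$double.eps) {
      rows[[length(rows) + 1L]] <- data.frame(
        stage = st, term = c("species", "year", "species:year"),
        df = NA_real_, F = NA_real_, p = NA_real_, degenerate = TRUE)
      next
    }
    fit <- stats::aov(y ~ factor(species) * factor(year), data = d)
    tab <- summary(fit)[[1]]
    terms <- trimws(rownames(tab))
    keep <- terms != "Residuals"
    rows[[length(rows) + 1L]] <- data.frame(
      stage = st,
      term = sub("factor\\(species\\)", "species",
                 sub("factor\\(year\\)", "year", terms[keep])),
      df = tab$Df[keep], F = tab$`F value`[keep],
      p = tab$`Pr(>F)`[keep], degenerate = FALSE)
  }
  do.call(rbind, rows)
}
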