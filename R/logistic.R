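#' Evaluate the three-parameter logistic curve
#'
#' The stage-progress model is `Y = a / (1 + (x/x0)^b)` with `a` the upper
#' asymptote (maximum log10 attachment number), `x0` the GDD at which Y is
#' half of `a`, and `b` the (negative, for increasing curves) shape
#' parameter controlling the slope at `x0`.
#'
#' @param params Named numeric vector or list with elements `a`, `b`, `x0`.
#' @param x Thermal time (GDD), strictly positive.
#' @return Numeric vector of Y values.
#' @export
logistic_eval <- function(params, x) {
  p <- check_params(params)
  if (any(x <= 0)) stop("x must be strictly positive GDD")
  p[["a"]] / (1 + (x / p[["x0"]])^p[["b"]])
}

check_params <- function(params) {
  p <- unlist(params)[c("a", "b", "x0")]
  if (anyNA(p)) stop("params must contain a, b and x0")
  if (p[["a"]] <= 0) stop("asymptote a must be positive")
  if (p[["x0"]] <= 0) stop("half-maximum x0 must be positive")
  p
}

#' Fit the three-parameter logistic by nonlinear least squares
#'
#' Fits `Y = a / (1 + (x/x0)^b)` to log-scale stage points by bounded
#' Levenberg-Marquardt least squares with deterministic multi-start:
#' starting values default to `a = max(Y)`, `x0` = x at the point closest to
#' half maximum, `b = -10`, augmented with a fixed grid of perturbed starts;
#' the converged fit with the lowest SSE wins, so the result is
#' deterministic given the data and `init`. Standard errors come from the
#' Jacobian-based covariance scaled by residual variance; `rmse` is
#' `sqrt(SSE / df_resid)`; the regression p-value is the F test of the
#' fitted model against the constant-mean model.
#'
#' @param points Data frame with columns `x` (GDD) and `Y` (log10 counts),
#'   e.g. from [transform_counts()], or a numeric vector of x (then supply
#'   `Y`).
#' @param Y Numeric response, if `points` is a numeric x vector.
#' @param init Optional named vector/list with starting `a`, `b`, `x0`.
#' @param bounds Optional list with `lower` and `upper` named vectors over
#'   `a`, `b`, `x0`. Defaults: a in (0, 3*max(Y)], b in \[-100, -0.1\],
#'   x0 in \[min(x)/2, 2*max(x)\].
#' @param n_starts Number of additional perturbed starts (default 8).
#' @return An object of class `logistic_fit` with components `params`, `se`,
#'   `rmse`, `p_regression`, `n_points`, `df_resid`, `sse`, `fitted`,
#'   `residuals`, `data`, `vcov`, `n_starts_converged`.
#' @examples
#' x <- seq(600, 1400, length.out = 20)
#' y <- logistic_eval(c(a = 0.7, b = -15, x0 = 900), x)
#' fit <- fit_logistic(data.frame(x = x, Y = y))
#' coef(fit)
#' @export
fit_logistic <- function(points, Y = NULL, init = NULL, bounds = NULL,
                         n_starts = 8L) {
  if (is.data.frame(points)) {
    stopifnot(all(c("x", "Y") %in% names(points)))
    x <- as.numeric(points$x); y <- as.numeric(points$Y)
  } else {
    x <- as.numeric(points); y <- as.numeric(Y)
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 5L) stop("need at least 5 points to fit 3 parameters")
  if (any(x <= 0)) stop("x must be strictly positive GDD")
  if (diff(range(y)) < .Machine$double.eps^0.5) {
    stop("degenerate data: all Y equal; logistic fit undefined")
  }

  if (is.null(bounds)) {
    bounds <- list(
      lower = c(a = 1e-8, b = -100, x0 = min(x) / 2),
      upper = c(a = 3 * max(y), b = -0.1, x0 = 2 * max(x))
    )
  }
  lo <- bounds$lower[c("a", "b", "x0")]
  hi <- bounds$upper[c("a", "b", "x0")]

  if (is.null(init)) {
    half <- max(y) / 2
    init <- c(a = max(y), b = -10,
              x0 = x[which.min(abs(y - half))])
  }
  init <- pmin(pmax(unlist(init)[c("a", "b", "x0")], lo), hi)

  starts <- list(init)
  # fixed perturbation grid: deterministic multi-start, no RNG involved
  mults <- expand.grid(a = c(1, 0.7), b = c(0.3, 1, 3), x0 = c(0.85, 1.15))
  for (k in seq_len(min(n_starts, nrow(mults)))) {
    s <- c(a = init[["a"]] * mults$a[k], b = init[["b"]] * mults$b[k],
           x0 = init[["x0"]] * mults$x0[k])
    starts[[length(starts) + 1L]] <- pmin(pmax(s, lo), hi)
  }

  best <- NULL
  n_conv <- 0L
  dat <- data.frame(x = x, y = y)
  for (s in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        y ~ a / (1 + (x / x0)^b), data = dat,
        start = as.list(s), lower = lo, upper = hi,
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    n_conv <- n_conv + 1L
    if (is.null(best) || stats::deviance(fit) < stats::deviance(best)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    stop("logistic fit failed to converge from any of ", length(starts),
         " starts")
  }

  n <- length(y)
  df_resid <- n - 3L
  sse <- stats::deviance(best)
  sm <- summary(best)
  est <- stats::coef(best)[c("a", "b", "x0")]
  se <- sm$coefficients[c("a", "b", "x0"), "Std. Error"]
  rmse <- sqrt(sse / df_resid)
  sst <- sum((y - mean(y))^2)
  f_stat <- ((sst - sse) / 2) / (sse / df_resid)
  p_reg <- stats::pf(f_stat, 2, df_resid, lower.tail = FALSE)

  structure(list(
    params = est, se = se, rmse = rmse, sse = sse,
    f_statistic = f_stat, p_regression = p_reg,
    n_points = n, df_resid = df_resid,
    fitted = as.numeric(stats::fitted(best)),
    residuals = as.numeric(stats::residuals(best)),
    data = dat, vcov = stats::vcov(best),
    bounds = list(lower = lo, upper = hi),
    n_starts_converged = n_conv
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, digits = 4, ...) {
  cat("Three-parameter logistic fit: Y = a / (1 + (x/x0)^b)\n")
  tab <- cbind(Estimate = x$params, `Std. Error` = x$se)
  print(round(tab, digits))
  cat(sprintf("RMSE %.4f on %d residual df; regression P %s\n",
              x$rmse, x$df_resid, format.pval(x$p_regression, digits = 3)))
  invisible(x)
}

#' @export
summary.logistic_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$params, `Std. Error` = object$se,
               `t value` = object$params / object$se)
  tab <- cbind(tab, `Pr(>|t|)` = 2 * stats::pt(-abs(tab[, "t value"]),
                                               object$df_resid))
  out <- list(coefficients = tab, rmse = object$rmse,
              sse = object$sse, f_statistic = object$f_statistic,
              p_regression = object$p_regression,
              n_points = object$n_points, df_resid = object$df_resid)
  class(out) <- "summary.logistic_fit"
  out
}

#' @export
print.summary.logistic_fit <- function(x, ...) {
  cat("Three-parameter logistic fit\n\nCoefficients:\n")
  stats::printCoefmat(x$coefficients)
  cat(sprintf("\nRMSE: %.4f (SSE %.5f, %d points, %d residual df)\n",
              x$rmse, x$sse, x$n_points, x$df_resid))
  cat(sprintf("F = %.2f vs constant mean, P %s\n",
              x$f_statistic, format.pval(x$p_regression, digits = 3)))
  invisible(x)
}

#' @export
coef.logistic_fit <- function(object, ...) object$params

#' @export
vcov.logistic_fit <- function(object, ...) object$vcov

#' @export
residuals.logistic_fit <- function(object, ...) object$residuals

#' @export
fitted.logistic_fit <- function(object, ...) object$fitted

#' Predict from a logistic fit
#'
#' @param object A `logistic_fit`.
#' @param newdata Optional data frame with column `x`, or numeric x vector;
#'   defaults to the fitting data.
#' @param ... Unused.
#' @return Predicted Y (log10 scale).
#' @export
predict.logistic_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  x <- if (is.data.frame(newdata)) newdata$x else as.numeric(newdata)
  logistic_eval(object$params, x)
}

#' Simulate responses from a logistic fit
#'
#' Draws Gaussian noise with sd equal to the fit RMSE around the fitted
#' curve at the original x values.
#'
#' @param object A `logistic_fit`.
#' @param nsim Number of replicate response vectors.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return Data frame with `nsim` columns, one simulated Y vector each.
#' @export
simulate.logistic_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- logistic_eval(object$params, object$data$x)
  out <- as.data.frame(replicate(
    nsim, mu + stats::rnorm(length(mu), 0, object$rmse)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a logistic fit
#'
#' Observed points with the fitted curve overlaid on a fine GDD grid.
#'
#' @param x A `logistic_fit`.
#' @param n_grid Number of curve evaluation points.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.logistic_fit <- function(x, n_grid = 200, ...) {
  graphics::plot(x$data$x, x$data$y, xlab = "GDD (degC day)",
                 ylab = "log10(broomrapes per plant + offset)", ...)
  xs <- seq(min(x$data$x), max(x$data$x), length.out = n_grid)
  graphics::lines(xs, logistic_eval(x$params, xs))
  invisible(x)
}

#' Thermal time at which the fitted curve reaches a fraction of its maximum
#'
#' Closed-form inversion of the logistic: the GDD where Y equals `q * a` is
#' `x0 * ((1 - q)/q)^(1/b)`. At `q = 0.5` this is `x0` exactly.
#'
#' @param fit A `logistic_fit`, or a named params vector/list.
#' @param q Fraction of the asymptote, in (0, 1).
#' @return GDD value(s).
#' @export
invert_logistic <- function(fit, q) {
  p <- check_params(if (inherits(fit, "logistic_fit")) fit$params else fit)
  if (any(q <= 0 | q >= 1)) stop("q must lie strictly within (0, 1)")
  p[["x0"]] * ((1 - q) / q)^(1 / p[["b"]])
}

#' Segment a fitted curve into lag, log and maximum phases
#'
#' The lag phase ends where the curve reaches fraction `q_low` of the
#' asymptote and the log (exponential growth) phase ends at `q_high`;
#' beyond that the population is at its maximum. Both boundaries are the
#' closed-form inversions of the logistic and can optionally be rounded to
#' a reporting grid (e.g. 50 GDD).
#'
#' @param fit A `logistic_fit` or named params.
#' @param q_low,q_high Phase thresholds as fractions of `a`
#'   (defaults 0.05 and 0.95); must satisfy 0 < q_low < q_high < 1.
#' @param round_to Optional GDD grid to round the boundaries to.
#' @return List of class `phase_segmentation` with `lag_end`, `log_end`,
#'   `q_low`, `q_high`, `round_to`.
#' @export
segment_phases <- function(fit, q_low = 0.05, q_high = 0.95,
                           round_to = NULL) {
  if (!(q_low > 0 && q_high < 1 && q_low < q_high)) {
    stop("need 0 < q_low < q_high < 1")
  }
  lag_end <- invert_logistic(fit, q_low)
  log_end <- invert_logistic(fit, q_high)
  if (!is.null(round_to)) {
    lag_end <- round(lag_end / round_to) * round_to
    log_end <- round(log_end / round_to) * round_to
  }
  structure(list(lag_end = lag_end, log_end = log_end,
                 q_low = q_low, q_high = q_high, round_to = round_to),
            class = "phase_segmentation")
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat(sprintf(
    "Phases: lag until %.1f GDD (q=%.2f), log until %.1f GDD (q=%.2f), then maximum\n",
    x$lag_end, x$q_low, x$log_end, x$q_high))
  invisible(x)
}

#' Back-transform a log10 response to broomrapes per plant
#'
#' The reporting convention (`"direct"`) is plain `10^y`, matching how
#' asymptotes on the log scale are usually quoted as plants per host (e.g.
#' a = 0.8 is 6.3 broomrapes per plant). The `"offset_consistent"`
#' convention undoes the `log10(count + offset)` transform exactly,
#' returning `10^y - offset`, so a Y of 0 under offset 1 maps back to zero
#' attachments.
#'
#' @param y Log10-scale value(s).
#' @param convention `"direct"` or `"offset_consistent"`.
#' @param offset Offset used in the forward transform (default 1).
#' @return Broomrapes per plant.
#' @export
back_transform <- function(y, convention = c("direct", "offset_consistent"),
                           offset = 1) {
  convention <- match.arg(convention)
  stopifnot(all(is.finite(y)))
  if (convention == "direct") 10^y else 10^y - offset
}
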