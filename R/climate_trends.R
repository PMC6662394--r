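# Trend battery for annual climate series: OLS trends with F tests, LOESS
# smoothing, Durbin-Watson and autocorrelation diagnostics, the
# opposite-tails Grubbs outlier test, and breakpoint period comparison.

#' Ordinary least-squares trend of a climate variable on time
#'
#' Fits `value ~ year` by OLS and reports the slope with its standard
#' error, the F test of the regression, and residual diagnostics
#' (Durbin-Watson d and the residual autocorrelation function).
#'
#' @param years integer years (distinct, length >= 3).
#' @param values variable values, same length.
#' @param max_lag maximum autocorrelation lag retained (default
#'   `min(20, n - 1)`).
#' @return a `trend_fit` list: `slope`, `slope_se`, `intercept`, `f_stat`,
#'   `df` (model, residual), `p_value`, `residuals`, `dw`, `acf`.
#' @export
fit_linear_trend <- function(years, values, max_lag = NULL) {
  if (length(years) != length(values)) {
    stop("years and values must have the same length", call. = FALSE)
  }
  if (length(years) < 3) stop("need at least 3 points", call. = FALSE)
  if (anyDuplicated(years)) stop("years must be distinct", call. = FALSE)
  fit <- stats::lm(values ~ years)
  sm <- suppressWarnings(summary(fit))
  res <- stats::residuals(fit)
  flat <- stats::var(values) == 0
  f_stat <- if (flat) 0 else unname(sm$fstatistic["value"])
  p_value <- if (flat) NA_real_ else {
    unname(stats::pf(sm$fstatistic["value"], sm$fstatistic["numdf"],
                     sm$fstatistic["dendf"], lower.tail = FALSE))
  }
  if (is.null(max_lag)) max_lag <- min(20, length(years) - 1)
  ac <- if (stats::var(res) == 0) NULL else {
    as.numeric(stats::acf(res, lag.max = max_lag, plot = FALSE,
                          demean = TRUE)$acf)
  }
  dw <- if (all(res == 0)) NA_real_ else durbin_watson(res)
  structure(list(
    slope = unname(stats::coef(fit)["years"]),
    slope_se = unname(sm$coefficients["years", "Std. Error"]),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    f_stat = f_stat,
    df = c(model = 1L, residual = length(years) - 2L),
    p_value = p_value,
    residuals = unname(res),
    dw = dw,
    acf = ac
  ), class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "Linear trend: slope = %.5g +/- %.3g per year (F = %.4g, df = %d,%d, p = %.3g)\n",
    x$slope, x$slope_se, x$f_stat, x$df[1], x$df[2], x$p_value))
  cat(sprintf("Durbin-Watson d = %.3f; lag-1 residual ACF = %.3f\n",
              x$dw, if (length(x$acf) > 1) x$acf[2] else NA))
  invisible(x)
}

#' Durbin-Watson statistic of a residual series
#'
#' d = sum_t (e_t - e_{t-1})^2 / sum_t e_t^2, bounded in [0, 4] and near 2
#' under serial independence.
#'
#' @param residuals numeric vector, length >= 2, not all zero.
#' @return the statistic d.
#' @export
durbin_watson <- function(residuals) {
  if (length(residuals) < 2) stop("need at least 2 residuals", call. = FALSE)
  ss <- sum(residuals^2)
  if (ss == 0) stop("all residuals are zero; Durbin-Watson undefined",
                    call. = FALSE)
  sum(diff(residuals)^2) / ss
}

#' Opposite-tails Grubbs test for simultaneous minimum/maximum outliers
#'
#' Tests whether the lowest and highest values of a sample are outliers on
#' opposite tails, using the studentised range G = (max - min) / s with s
#' the sample standard deviation. The p-value uses the classical
#' Bonferroni-type t-approximation for the two-sided range statistic under
#' normality and is therefore approximate (`p_approx = TRUE` in the
#' result).
#'
#' @param values numeric vector, length >= 4, positive variance.
#' @return list with `g_stat`, `p_value`, `min_index`, `max_index`,
#'   `p_approx`.
#' @export
grubbs_opposite_tails <- function(values) {
  n <- length(values)
  if (n < 4) stop("need at least 4 values", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) stop("zero variance; Grubbs statistic undefined",
                   call. = FALSE)
  g <- (max(values) - min(values)) / s
  # Invert the critical-value relation q = sqrt(2 (n-1) t^2 / (n-2+t^2)),
  # t = qt(p / (n (n-1)), n-2): given G, t^2 = G^2 (n-2) / (2(n-1) - G^2).
  denom <- 2 * (n - 1) - g^2
  p <- if (denom <= 0) 0 else {
    t2 <- g^2 * (n - 2) / denom
    min(1, n * (n - 1) * stats::pt(-sqrt(t2), n - 2))
  }
  list(g_stat = g, p_value = p,
       min_index = which.min(values), max_index = which.max(values),
       p_approx = TRUE)
}

#' LOESS smoother configuration
#'
#' @param alpha span: fraction of points in each local neighbourhood,
#'   in (0, 1].
#' @param degree local polynomial degree, 0 or 1.
#' @param robust_iters number of bisquare robustness reweighting passes
#'   after the initial fit (0 = plain local regression).
#' @return a `loess_config` list.
#' @export
loess_config <- function(alpha = 0.5, degree = 1, robust_iters = 2) {
  stopifnot(alpha > 0, alpha <= 1, degree %in% c(0, 1), robust_iters >= 0)
  structure(list(alpha = alpha, degree = as.integer(degree),
                 robust_iters = as.integer(robust_iters)),
            class = "loess_config")
}

#' Locally weighted regression smoothing of a series
#'
#' Fits a LOESS curve: at each point, a weighted local polynomial of the
#' configured degree over the `ceiling(alpha * n)` nearest neighbours with
#' tricube weights, optionally followed by bisquare robustness
#' reweighting passes that damp the influence of gross outliers.
#'
#' @param x ordering variable (e.g. year).
#' @param y values to smooth, same length.
#' @param config a [loess_config].
#' @return fitted values at each `x`, same length as the input.
#' @export
loess_smooth <- function(x, y, config = loess_config()) {
  if (length(x) != length(y)) {
    stop("x and y must have the same length", call. = FALSE)
  }
  n <- length(x)
  if (n < max(4, ceiling(config$alpha * n))) {
    stop("too few points for the requested span", call. = FALSE)
  }
  fam <- if (config$robust_iters > 0) "symmetric" else "gaussian"
  fit <- stats::loess(
    y ~ x, span = config$alpha, degree = config$degree, family = fam,
    surface = "direct",
    control = stats::loess.control(iterations = config$robust_iters + 1L))
  unname(stats::fitted(fit))
}

#' Mean comparison across a breakpoint year
#'
#' Splits an annual series at a breakpoint (the breakpoint year belongs to
#' the "after" period) and compares period means.
#'
#' @param climate climate data frame (see [read_climate]).
#' @param breakpoint_year first year of the "after" period.
#' @param field column of `climate` to compare.
#' @return list with `mean_before`, `mean_after`, `difference`
#'   (after - before) and `percent` (difference relative to the "before"
#'   mean, in percent).
#' @export
period_comparison <- function(climate, breakpoint_year, field) {
  if (!field %in% names(climate)) {
    stop(sprintf("unknown field '%s'", field), call. = FALSE)
  }
  before <- climate[[field]][climate$year < breakpoint_year]
  after <- climate[[field]][climate$year >= breakpoint_year]
  if (length(before) == 0 || length(after) == 0) {
    stop("both periods must be non-empty", call. = FALSE)
  }
  mb <- mean(before); ma <- mean(after)
  list(mean_before = mb, mean_after = ma, difference = ma - mb,
       percent = (ma - mb) / mb * 100)
}

#' First-decade versus last-decade comparison
#'
#' Compares the mean over the first `n_years` data years of a series with
#' the mean over the last `n_years`.
#'
#' @param years integer years (need not be consecutive; sorted internally).
#' @param values variable values, same length.
#' @param n_years window length (default 10).
#' @return list with `mean_first`, `mean_last`, `difference`
#'   (last - first).
#' @export
decade_comparison <- function(years, values, n_years = 10) {
  if (length(years) < 2 * n_years) {
    stop("series shorter than two windows", call. = FALSE)
  }
  o <- order(years)
  v <- values[o]
  mf <- mean(v[seq_len(n_years)])
  ml <- mean(v[seq.int(length(v) - n_years + 1, length(v))])
  list(mean_first = mf, mean_last = ml, difference = ml - mf)
}

#' Trend battery over the standard climate fields
#'
#' Runs [fit_linear_trend], [durbin_watson] (via the fit) and
#' [grubbs_opposite_tails] on each requested field of a climate series,
#' and [loess_smooth] on the same fields.
#'
#' @param climate climate data frame (see [read_climate]).
#' @param fields columns to analyse (default: all four standard fields).
#' @param loess a [loess_config] for the smoothed series.
#' @return list with `report` (one row per field: slope, slope_se, f_stat,
#'   p_value, dw, grubbs_g, grubbs_p) and `smoothed` (year plus one fitted
#'   column per field).
#' @export
climate_trend_report <- function(climate,
                                 fields = c("rainfall_mm",
                                            "tmin_annual_mean",
                                            "tmin_winter", "tmin_summer"),
                                 loess = loess_config()) {
  smoothed <- data.frame(year = climate$year)
  rows <- lapply(fields, function(f) {
    fit <- fit_linear_trend(climate$year, climate[[f]])
    gr <- grubbs_opposite_tails(climate[[f]])
    smoothed[[f]] <<- loess_smooth(climate$year, climate[[f]], loess)
    data.frame(field = f, slope = fit$slope, slope_se = fit$slope_se,
               f_stat = fit$f_stat, p_value = fit$p_value, dw = fit$dw,
               grubbs_g = gr$g_stat, grubbs_p = gr$p_value,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  list(report = report, smoothed = smoothed)
}
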