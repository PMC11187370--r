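days_in_month <- function(first_of_month) {
  nxt <- seq(first_of_month, by = "1 month", length.out = 2L)[2L]
  as.integer(nxt - first_of_month)
}

floor_month <- function(d) as.Date(format(as.Date(d), "%Y-%m-01"))

#' Aggregate event records into a monthly series
#'
#' One entry per calendar month between `start` and `end` (months with no
#' events get a zero). In `"casualties"` mode each record contributes its
#' `n_casualties`; in `"collisions"` mode each record counts once. A month
#' is flagged post-intervention when its first day falls on or after the
#' month containing `intervention_date` — so an event on the intervention
#' date itself belongs to the first post month.
#'
#' @param collisions collision tibble.
#' @param start,end dates bounding the series (coerced to whole months).
#' @param intervention_date date the intervention started.
#' @param mode `"casualties"` (default) or `"collisions"`.
#' @return tibble of class `monthly_series`: `year_month` (Date, first of
#'   month), `count`, `days_in_month`, `is_post`.
#' @export
aggregate_monthly <- function(collisions, start, end, intervention_date,
                              mode = c("casualties", "collisions")) {
  mode <- match.arg(mode)
  start <- floor_month(start); end <- floor_month(end)
  if (start > end) stop("empty date range", call. = FALSE)
  months <- seq(start, end, by = "1 month")
  w <- if (mode == "casualties") collisions$n_casualties else
    rep(1L, nrow(collisions))
  ym <- floor_month(collisions$date)
  keep <- ym >= start & ym <= end
  counts <- setNames(rep(0, length(months)), format(months, "%Y-%m"))
  if (any(keep)) {
    agg <- tapply(w[keep], format(ym[keep], "%Y-%m"), sum)
    counts[names(agg)] <- agg
  }
  out <- tibble::tibble(
    year_month = months,
    count = as.numeric(counts),
    days_in_month = vapply(months, days_in_month, integer(1)),
    is_post = months >= floor_month(intervention_date)
  )
  class(out) <- c("monthly_series", class(out))
  out
}

#' Model specification for the monthly-count GAM
#'
#' The trend is a penalized thin-plate spline of the month index;
#' seasonality is a cyclic cubic spline of month-of-year; the log of the
#' number of days per month enters as an offset. Smoothing parameters are
#' selected by REML.
#'
#' @param trend_basis_dim basis dimension for the trend smooth (default
#'   20; must be >= 3).
#' @param seasonal_basis_dim basis dimension for the cyclic seasonal
#'   smooth (default 12; must be >= 3).
#' @param family `"poisson"` (default), `"quasipoisson"` or
#'   `"negative_binomial"`.
#' @param include_intervention_smooth add a smooth of time since
#'   intervention when fitting the full series (plotting only; the
#'   counterfactual always comes from the pre-period sub-model).
#' @return list of class `its_model_spec`.
#' @export
its_model_spec <- function(trend_basis_dim = 20, seasonal_basis_dim = 12,
                           family = c("poisson", "quasipoisson",
                                      "negative_binomial"),
                           include_intervention_smooth = FALSE) {
  family <- match.arg(family)
  stopifnot(trend_basis_dim >= 3, seasonal_basis_dim >= 3)
  structure(list(trend_basis_dim = trend_basis_dim,
                 seasonal_basis_dim = seasonal_basis_dim,
                 family = family,
                 include_intervention_smooth = include_intervention_smooth),
            class = "its_model_spec")
}

its_family <- function(spec) {
  switch(spec$family,
         poisson = stats::poisson(),
         quasipoisson = stats::quasipoisson(),
         negative_binomial = mgcv::nb())
}

series_frame <- function(series) {
  data.frame(
    count = series$count,
    t = seq_len(nrow(series)),
    month_of_year = as.integer(format(series$year_month, "%m")),
    days = series$days_in_month
  )
}

#' Fit the pre-intervention sub-model
#'
#' Log-link count regression on the pre-intervention months only:
#' `count ~ s(t) + s(month_of_year, bs = "cc") + offset(log(days))`,
#' fitted with `mgcv::gam` and REML smoothness selection. The fit retains
#' the coefficient covariance needed for counterfactual intervals. A
#' dispersion statistic (Pearson chi-square over residual df) is reported
#' so overdispersion can be judged; refit with `family = "quasipoisson"`
#' when it is material.
#'
#' @param series `monthly_series` from [aggregate_monthly()].
#' @param spec [its_model_spec()].
#' @return object of class `its_fit` wrapping the `gam` fit, with elements
#'   `gam`, `spec`, `series` (pre months), `n_pre`, `dispersion`,
#'   `smoothing_criterion`.
#' @export
fit_pre_model <- function(series, spec = its_model_spec()) {
  pre <- series[!series$is_post, , drop = FALSE]
  if (nrow(pre) < 36L) {
    stop("need at least 36 pre-intervention months, got ", nrow(pre),
         call. = FALSE)
  }
  df <- series_frame(pre)
  k_t <- min(spec$trend_basis_dim, nrow(df) - 1L)
  fit <- mgcv::gam(
    count ~ s(t, bs = "tp", k = k_t) +
      s(month_of_year, bs = "cc", k = spec$seasonal_basis_dim) +
      offset(log(days)),
    family = its_family(spec), data = df, method = "REML",
    knots = list(month_of_year = c(0.5, 12.5))
  )
  if (!fit$converged) {
    stop("pre-period model did not converge (deviance ",
         format(fit$deviance), ")", call. = FALSE)
  }
  disp <- sum(stats::residuals(fit, type = "pearson")^2) / fit$df.residual
  structure(list(gam = fit, spec = spec, series = pre, n_pre = nrow(pre),
                 dispersion = disp, smoothing_criterion = "REML"),
            class = "its_fit")
}

#' @export
print.its_fit <- function(x, ...) {
  cat("Pre-period monthly count model (", x$spec$family,
      ", smoothing by ", x$smoothing_criterion, ")\n", sep = "")
  cat("  pre months: ", x$n_pre, "; dispersion (Pearson/df): ",
      format(x$dispersion, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Predict the counterfactual for post-intervention months
#'
#' Extends the pre-period sub-model over the requested months: mean
#' predictions with pointwise 95% intervals from the coefficient
#' covariance (normal on the linear predictor, exponentiated). The
#' thin-plate trend smooth extrapolates linearly beyond the training
#' range, the natural boundary behaviour of a 1-D penalized thin-plate
#' spline. The prediction never touches post-period counts. Extrapolating
#' more than 36 months past the training range draws a warning.
#'
#' @param fit `its_fit` from [fit_pre_model()].
#' @param post_series `monthly_series` rows to predict (typically the
#'   post months); must be contiguous with the training range.
#' @param level interval level (default 0.95).
#' @return tibble `year_month, predicted, lo, hi, days_in_month`.
#' @export
predict_counterfactual <- function(fit, post_series, level = 0.95) {
  stopifnot(inherits(fit, "its_fit"))
  first_train <- fit$series$year_month[1]
  off <- months_between(first_train, post_series$year_month)
  if (any(diff(off) != 1L)) {
    stop("post months must be consecutive", call. = FALSE)
  }
  horizon <- max(off) + 1L - fit$n_pre
  if (horizon > 36L) {
    warning("extrapolating ", horizon, " months beyond the training range")
  }
  newd <- data.frame(
    t = off + 1L,
    month_of_year = as.integer(format(post_series$year_month, "%m")),
    days = post_series$days_in_month
  )
  pr <- predict(fit$gam, newdata = newd, type = "link", se.fit = TRUE)
  z <- z_crit(level)
  eta <- as.numeric(pr$fit)
  se <- as.numeric(pr$se.fit)
  tibble::tibble(
    year_month = post_series$year_month,
    predicted = exp(eta),
    lo = exp(eta - z * se),
    hi = exp(eta + z * se),
    days_in_month = post_series$days_in_month
  )
}

months_between <- function(a, b) {
  ay <- as.integer(format(a, "%Y")); am <- as.integer(format(a, "%m"))
  by <- as.integer(format(b, "%Y")); bm <- as.integer(format(b, "%m"))
  (by - ay) * 12L + (bm - am)
}

#' Compare annualized predicted and observed post-period rates
#'
#' Totals the counterfactual predictions and the observed counts over the
#' post period and annualizes both. Rate CIs use the normal approximation
#' on totals (`total +/- z * sqrt(total)`, scaled by `1/years`); the
#' difference CI combines the two variances; the percent difference
#' `100 * (pred - obs)/pred` gets a delta-method CI on the ratio of
#' totals. One rule is used for every row, including the pre-period-style
#' rates.
#'
#' @param predicted tibble from [predict_counterfactual()].
#' @param observed `monthly_series` for the same months.
#' @param post_years exposure in years for annualization.
#' @param level confidence level.
#' @return list of class `counterfactual_comparison` with elements
#'   `predicted`, `observed`, `difference`, `percent` — each a list
#'   `(value, lo, hi)`; difference is predicted minus observed.
#' @export
compare_annualized <- function(predicted, observed, post_years,
                               level = 0.95) {
  if (!identical(format(predicted$year_month, "%Y-%m"),
                 format(observed$year_month, "%Y-%m"))) {
    stop("predicted and observed series must cover the same months",
         call. = FALSE)
  }
  z <- z_crit(level)
  tp <- sum(predicted$predicted)
  to <- sum(observed$count)
  ann <- function(tot) {
    list(value = tot / post_years,
         lo = (tot - z * sqrt(tot)) / post_years,
         hi = (tot + z * sqrt(tot)) / post_years)
  }
  d <- (tp - to) / post_years
  d_se <- sqrt(tp + to) / post_years
  # delta method on the ratio of totals: Var(obs/pred)/(obs/pred)^2
  # = 1/obs + 1/pred to first order
  ratio <- to / tp
  pct <- 100 * (1 - ratio)
  pct_se <- 100 * ratio * sqrt(1 / to + 1 / tp)
  structure(list(
    predicted = ann(tp),
    observed = ann(to),
    difference = list(value = d, lo = d - z * d_se, hi = d + z * d_se),
    percent = list(value = pct, lo = pct - z * pct_se, hi = pct + z * pct_se),
    totals = list(predicted = tp, observed = to, years = post_years)
  ), class = "counterfactual_comparison")
}

#' @export
print.counterfactual_comparison <- function(x, ...) {
  f <- function(v) sprintf("%.0f (%.0f to %.0f)", v$value, v$lo, v$hi)
  cat("Annualized post-period comparison (", x$totals$years, " years)\n",
      "  predicted: ", f(x$predicted), "\n",
      "  observed:  ", f(x$observed), "\n",
      "  difference (predicted - observed): ", f(x$difference), "\n",
      "  percent difference: ", sprintf("%.0f (%.0f to %.0f)",
                                        x$percent$value, x$percent$lo,
                                        x$percent$hi), "\n", sep = "")
  invisible(x)
}

#' Fit the full-series model including an intervention smooth
#'
#' For visual inspection only: adds a thin-plate smooth of time since
#' intervention (zero before it) to the trend and seasonal terms. The
#' headline counterfactual comparison always uses the pre-period
#' sub-model; this fit never feeds [compare_annualized()].
#'
#' @param series full `monthly_series`.
#' @param spec [its_model_spec()] with `include_intervention_smooth = TRUE`.
#' @return `its_fit` over the full series.
#' @export
fit_full_model <- function(series, spec = its_model_spec(
                             include_intervention_smooth = TRUE)) {
  df <- series_frame(series)
  df$since <- cumsum(series$is_post)
  k_t <- min(spec$trend_basis_dim, nrow(df) - 1L)
  k_i <- max(3L, min(10L, sum(series$is_post) - 1L))
  form <- if (spec$include_intervention_smooth && sum(series$is_post) > 4L) {
    count ~ s(t, bs = "tp", k = k_t) +
      s(month_of_year, bs = "cc", k = spec$seasonal_basis_dim) +
      s(since, bs = "tp", k = k_i) + offset(log(days))
  } else {
    count ~ s(t, bs = "tp", k = k_t) +
      s(month_of_year, bs = "cc", k = spec$seasonal_basis_dim) +
      offset(log(days))
  }
  fit <- mgcv::gam(form, family = its_family(spec), data = df,
                   method = "REML",
                   knots = list(month_of_year = c(0.5, 12.5)))
  disp <- sum(stats::residuals(fit, type = "pearson")^2) / fit$df.residual
  structure(list(gam = fit, spec = spec, series = series,
                 n_pre = sum(!series$is_post), dispersion = disp,
                 smoothing_criterion = "REML"),
            class = "its_fit")
}

#' Plot observed counts against the counterfactual
#'
#' Base-graphics view of the monthly series with the counterfactual mean
#' and its pointwise interval over the post period.
#'
#' @param series full `monthly_series`.
#' @param counterfactual tibble from [predict_counterfactual()].
#' @param ... passed to `plot()`.
#' @return invisibly, `NULL`.
#' @export
plot_counterfactual <- function(series, counterfactual, ...) {
  plot(series$year_month, series$count, type = "l", col = "steelblue",
       xlab = "month", ylab = "events/month", ...)
  lines(counterfactual$year_month, counterfactual$predicted, col = "firebrick")
  lines(counterfactual$year_month, counterfactual$lo, col = "grey60", lty = 2)
  lines(counterfactual$year_month, counterfactual$hi, col = "grey60", lty = 2)
  invisible(NULL)
}

#' @importFrom graphics lines plot
NULL

#' Replicated recovery study for the counterfactual pipeline
#'
#' Simulates monthly Poisson series with a log-linear secular trend,
#' sinusoidal seasonality, a day-count exposure and a step rate-ratio on
#' the post months; fits the pre-period sub-model, predicts the post
#' period and annualizes the comparison. Returns the percent difference
#' (predicted vs observed) and its CI for every replicate, so both effect
#' recovery and null coverage can be measured.
#'
#' @param n_reps number of replicate series.
#' @param effect rate ratio applied to post months (1 = null).
#' @param n_pre,n_post months before/after the step.
#' @param baseline_monthly expected events in a 30-day month at t = 0.
#' @param trend multiplicative change per year.
#' @param seasonal_amplitude log-scale sine amplitude.
#' @param spec [its_model_spec()].
#' @param seed RNG seed.
#' @return tibble with one row per replicate: `rep`, `pct`, `lo`, `hi`.
#' @export
its_simulation_study <- function(n_reps = 500, effect = 0.83,
                                 n_pre = 243, n_post = 30,
                                 baseline_monthly = 120, trend = 0.97,
                                 seasonal_amplitude = 0.1,
                                 spec = its_model_spec(), seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  out <- matrix(NA_real_, n_reps, 3)
  for (r in seq_len(n_reps)) {
    s <- simulate_monthly_series(n_pre, n_post, baseline_monthly, trend,
                                 seasonal_amplitude, effect)
    fit <- fit_pre_model(s, spec)
    post <- s[s$is_post, , drop = FALSE]
    cf <- predict_counterfactual(fit, post)
    cmp <- compare_annualized(cf, post, sum(post$days_in_month) / 365.25)
    out[r, ] <- c(cmp$percent$value, cmp$percent$lo, cmp$percent$hi)
  }
  tibble::tibble(rep = seq_len(n_reps), pct = out[, 1],
                 lo = out[, 2], hi = out[, 3])
}
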