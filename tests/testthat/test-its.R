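test_that("monthly aggregation conserves totals and flags post months", {
  col <- as_collisions(tibble::tibble(
    id = sprintf("c%02d", 1:4),
    date = as.Date(c("2016-01-10", "2016-01-20", "2016-02-05", "2016-07-31")),
    easting = 0, northing = 0, severity = "slight",
    n_casualties = c(2L, 1L, 3L, 1L)
  ))
  s <- aggregate_monthly(col, "2016-01-01", "2016-08-31", "2016-07-31")
  expect_equal(nrow(s), 8L)
  expect_equal(s$count[1:2], c(3, 3))
  expect_equal(s$days_in_month[1:2], c(31, 29))  # 2016 is a leap year
  expect_equal(sum(s$count), sum(col$n_casualties))  # conservation
  # the month containing the intervention date is the first post month
  expect_equal(s$is_post, c(rep(FALSE, 6), TRUE, TRUE))
  expect_equal(s$count[7], 1)
  # collision mode counts records, not casualties
  s2 <- aggregate_monthly(col, "2016-01-01", "2016-08-31", "2016-07-31",
                          mode = "collisions")
  expect_equal(sum(s2$count), 4)
  expect_error(aggregate_monthly(col, "2016-09-01", "2016-01-01", "2016-07-31"),
               "empty date range")
})

test_that("a constant daily rate yields a flat fitted trend", {
  set.seed(2)
  s <- simulate_monthly_series(120, 10, baseline_monthly = 400, trend = 1,
                               seasonal_amplitude = 0, effect = 1)
  fit <- fit_pre_model(s)
  # the trend term on the link scale varies by < 2% across the range
  terms <- predict(fit$gam, type = "terms")
  trend <- terms[, grep("s\\(t\\)", colnames(terms))]
  expect_lt(max(trend) - min(trend), 0.02)
})

test_that("a log-linear trend slope is recovered within 10%", {
  set.seed(3)
  # rate doubles over the pre period on the log scale
  n_pre <- 72
  slope <- log(2) / (n_pre / 12)  # per year
  s <- simulate_monthly_series(n_pre, 6, baseline_monthly = 250,
                               trend = exp(slope), seasonal_amplitude = 0.05)
  fit <- fit_pre_model(s)
  daily <- log(fitted(fit$gam) / fit$series$days_in_month)
  est_slope <- unname(coef(lm(daily ~ I(seq_len(n_pre) / 12)))[2])
  expect_lt(abs(est_slope - slope) / slope, 0.10)
})

test_that("the day-count offset acts exactly multiplicatively", {
  set.seed(4)
  s <- simulate_monthly_series(48, 6, baseline_monthly = 200)
  fit <- fit_pre_model(s)
  post <- s[s$is_post, , drop = FALSE]
  p1 <- predict_counterfactual(fit, post)
  post2 <- post
  post2$days_in_month <- post2$days_in_month * 2L
  p2 <- predict_counterfactual(fit, post2)
  expect_equal(p2$predicted, 2 * p1$predicted, tolerance = 1e-12)
})

test_that("the counterfactual never sees post-period data", {
  set.seed(5)
  s <- simulate_monthly_series(48, 12, baseline_monthly = 150)
  fit1 <- fit_pre_model(s)
  s2 <- s
  s2$count[s2$is_post] <- 0  # wreck the post counts
  fit2 <- fit_pre_model(s2)
  post <- s[s$is_post, , drop = FALSE]
  expect_equal(predict_counterfactual(fit1, post),
               predict_counterfactual(fit2, post))
})

test_that("prediction at a training month equals the fitted value", {
  set.seed(6)
  s <- simulate_monthly_series(48, 6, baseline_monthly = 150)
  fit <- fit_pre_model(s)
  pre <- s[!s$is_post, , drop = FALSE]
  p <- predict_counterfactual(fit, pre[10:12, ])
  expect_equal(p$predicted, unname(fitted(fit$gam)[10:12]), tolerance = 1e-8)
})

test_that("an injected post-period drop pushes observations below the band", {
  set.seed(7)
  s <- simulate_monthly_series(120, 24, baseline_monthly = 400, trend = 0.97,
                               seasonal_amplitude = 0.1, effect = 0.83)
  fit <- fit_pre_model(s)
  post <- s[s$is_post, , drop = FALSE]
  cf <- predict_counterfactual(fit, post)
  expect_gt(mean(post$count < cf$lo), 0.5)
})

test_that("annualized comparison follows the normal-on-totals rule", {
  # identical series: all differences exactly zero
  set.seed(8)
  s <- simulate_monthly_series(48, 12, baseline_monthly = 100)
  post <- s[s$is_post, , drop = FALSE]
  self <- tibble::tibble(year_month = post$year_month,
                         predicted = as.numeric(post$count),
                         lo = NA_real_, hi = NA_real_,
                         days_in_month = post$days_in_month)
  cmp0 <- compare_annualized(self, post, 1)
  expect_equal(cmp0$difference$value, 0)
  expect_equal(cmp0$percent$value, 0)
  # closed form: observed total 2611 over 2.42 years
  obs <- post[1, ]
  obs$count <- 2611
  pred1 <- self[1, ]; pred1$predicted <- 3160.52
  cmp <- compare_annualized(pred1, obs, 2.42)
  z <- qnorm(0.975)
  expect_equal(cmp$observed$value, 2611 / 2.42)
  expect_equal(cmp$observed$lo, (2611 - z * sqrt(2611)) / 2.42)
  expect_equal(round_half_away(cmp$observed$value), 1079)
  # endpoints consistent with an annual CI of roughly (1037, 1120)
  expect_lt(abs(cmp$observed$lo - 1037), 1)
  expect_lt(abs(cmp$observed$hi - 1120), 1)
  expect_error(compare_annualized(self, s[1:nrow(post), ], 1), "same months")
})

test_that("mismatched or gappy post months are rejected", {
  set.seed(9)
  s <- simulate_monthly_series(48, 6, baseline_monthly = 150)
  fit <- fit_pre_model(s)
  post <- s[s$is_post, , drop = FALSE]
  expect_error(predict_counterfactual(fit, post[c(1, 3), ]), "consecutive")
  expect_error(fit_pre_model(s[1:30, ]), "at least 36")
})
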