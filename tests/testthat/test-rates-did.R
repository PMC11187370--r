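test_that("annualized rates and Garwood intervals match the exact oracle", {
  expect_equal(annual_rate(354, 3), 118)
  expect_equal(annual_rate(0, 2.5), 0)
  expect_equal(round_half_away(annual_rate(321, 1.83)), 175)
  expect_error(annual_rate(10, 0), "positive")

  # chi-square form against independent CDF-inversion for integer counts
  for (n in c(1:20, seq(25, 200, by = 25))) {
    got <- poisson_exact_ci(n)
    want <- poisson_ci_oracle(n)
    expect_lt(abs(got$lo - want[["lo"]]), 0.01)
    expect_lt(abs(got$hi - want[["hi"]]), 0.01)
  }
  expect_equal(poisson_exact_ci(0)$lo, 0)
  expect_error(poisson_exact_ci(-1), "non-negative")
})

test_that("rate difference uses count-based variance and covers ~95%", {
  d <- rate_difference(354, 3, 121, 1.83)
  expect_equal(d$diff, 121 / 1.83 - 354 / 3)
  # identical periods: zero difference, symmetric CI
  d0 <- rate_difference(100, 2, 100, 2)
  expect_equal(d0$diff, 0)
  expect_equal(d0$hi, -d0$lo)
  # Monte-Carlo coverage at lambda*T >= 100
  set.seed(1)
  reps <- 1e4
  n1 <- rpois(reps, 150); n2 <- rpois(reps, 120)
  true_d <- 120 / 2 - 150 / 3
  z <- qnorm(0.975)
  se <- sqrt(n1 / 9 + n2 / 4)
  est <- n2 / 2 - n1 / 3
  cover <- mean(est - z * se <= true_d & true_d <= est + z * se)
  expect_gt(cover, 0.94)
  expect_lt(cover, 0.96)
})

test_that("percent change matches the numeric-gradient delta oracle", {
  pd <- percent_diff(354, 3, 121, 1.83)
  expect_equal(pd$value, 100 * ((121 / 1.83) / (354 / 3) - 1))
  expect_equal(round_half_away(pd$value), -44)

  # generic delta method by numerical differentiation of g(N1, N2)
  g <- function(n1, n2) 100 * ((n2 / 1.83) / (n1 / 3) - 1)
  h <- 1e-4
  g1 <- (g(354 + h, 121) - g(354 - h, 121)) / (2 * h)
  g2 <- (g(354, 121 + h) - g(354, 121 - h)) / (2 * h)
  sd_num <- sqrt(g1^2 * 354 + g2^2 * 121)  # Var(N) = N for Poisson
  expect_equal(pd$sd, sd_num, tolerance = 1e-10)

  # equal rates give exactly zero
  expect_equal(percent_diff(100, 2, 100, 2)$value, 0)
  # sd scales as 1/sqrt(N): doubling both counts at fixed rates
  a <- percent_diff(200, 2, 160, 2)
  b <- percent_diff(400, 4, 320, 4)
  expect_equal(a$sd / b$sd, sqrt(2), tolerance = 1e-9)
  # degenerate cases
  expect_error(percent_diff(0, 1, 5, 1), "zero pre-period")
  z0 <- percent_diff(10, 1, 0, 1)
  expect_equal(z0$value, -100)
  expect_true(z0$degenerate)
})

test_that("percent change from printed rates is a pure point value", {
  expect_equal(round_half_away(percent_diff_from_rates(1014, 680)), -33)
  expect_equal(round_half_away(percent_diff_from_rates(587, 519)), -12)
  expect_equal(percent_diff_from_rates(42, 42), 0)
  expect_error(percent_diff_from_rates(0, 10), "positive")
})

test_that("difference-in-differences combines variances in quadrature", {
  a <- percent_diff(1568, 3, 550, 1.83)
  b <- percent_diff(802, 3, 321, 1.83)
  dd <- did(a, b)
  expect_equal(dd$value, a$value - b$value)
  # identical arms: exactly zero with a symmetric CI
  same <- did(a, a)
  expect_equal(same$value, 0)
  expect_equal(same$hi, -same$lo)
  # antisymmetric point value
  expect_equal(did(b, a)$value, -dd$value)
  expect_error(did(a, list(value = 1, sd = NA_real_)), "finite")
})

test_that("DiD point estimate covers the true effect across replicates", {
  # shared secular change, a 0.9 rate ratio on the treated arm only:
  # the true difference-in-differences is -10 percent points
  set.seed(1)
  reps <- 500
  covered <- logical(reps)
  for (r in seq_len(reps)) {
    n1t <- rpois(1, 1000); n2t <- rpois(1, 1000 * 0.9)
    n1r <- rpois(1, 1000); n2r <- rpois(1, 1000)
    dd <- did(percent_diff(n1t, 1, n2t, 1), percent_diff(n1r, 1, n2r, 1))
    covered[r] <- dd$lo <= -10 && -10 <= dd$hi
  }
  expect_gte(mean(covered), 0.93)
})

test_that("rate_table reproduces its inputs and is order-invariant", {
  counts <- data.frame(
    group = c("existing20", "changed20", "stay30"),
    measure = "collisions",
    n_pre = c(354, 1568, 802), n_post = c(121, 550, 321)
  )
  t1 <- rate_table(counts, 3, 1.83, ref_group = "stay30")
  t2 <- rate_table(counts[c(3, 1, 2), ], 3, 1.83, ref_group = "stay30")
  expect_identical(t1, t2)
  row <- t1[t1$group == "existing20", ]
  expect_equal(row$rate_pre, 118)
  expect_true(is.na(t1$did[t1$group == "stay30"]))
  # empty group: flagged, table still emitted
  counts0 <- rbind(counts, data.frame(group = "other", measure = "collisions",
                                      n_pre = 0, n_post = 0))
  t0 <- rate_table(counts0, 3, 1.83)
  expect_true(t0$flagged[t0$group == "other"])
  expect_equal(t0$rate_pre[t0$group == "other"], 0)
})

test_that("segment_table sums match ground truth and ignore the gap", {
  net <- tiny_network()  # segA changed20_local, segB stay30, segC existing20
  mk <- function(id, date, east, north, ncas) {
    tibble::tibble(id = id, date = as.Date(date), easting = east,
                   northing = north, severity = "slight",
                   n_casualties = as.integer(ncas))
  }
  col <- as_collisions(rbind(
    mk("a1", "2014-01-01", 50, 1, 2),   # segA pre
    mk("a2", "2017-01-01", 50, 1, 1),   # segA post
    mk("b1", "2014-06-01", 50, 99, 3),  # segB pre
    mk("b2", "2017-06-01", 50, 101, 1), # segB post
    mk("x1", "2016-07-15", 50, 1, 1),   # in the gap: excluded
    mk("u1", "2014-01-01", 50, 55, 1)   # unmatched: excluded
  ))
  w <- study_window("2013-08-01", "2016-06-30", "2016-08-01", "2018-05-31",
                    pre_years = 3, post_years = 1.83)
  m <- snap_collisions(col, net)
  tab <- segment_table(col, m, net, w)
  cas <- tab[tab$measure == "casualties", ]
  expect_equal(cas$n_pre[cas$group == "changed20_local"], 2)
  expect_equal(cas$n_post[cas$group == "changed20_local"], 1)
  expect_equal(cas$n_pre[cas$group == "stay30"], 3)
  colr <- tab[tab$measure == "collisions", ]
  expect_equal(colr$n_pre[colr$group == "changed20_local"], 1)
  expect_equal(sum(colr$n_pre), 2)  # gap and unmatched rows dropped
})

test_that("zone_table totals equal the sum of pair counts", {
  cfg <- sim_config(seed = 5, baseline_monthly_rate = 2, months_pre = 18,
                    months_post = 12, n_zone_pairs = 3,
                    start_date = "2015-02-01", intervention_date = "2016-08-01")
  nz <- make_network(cfg)
  sim <- simulate_collisions(cfg, nz$network, nz$zones)
  m <- snap_collisions(sim$collisions, nz$network, zones = nz$zones)
  w <- study_window("2015-02-01", "2016-07-31", "2016-08-01", "2017-07-31")
  zw <- setNames(rep(list(w), 3), paste0("pair", 1:3))
  tab <- zone_table(sim$collisions, m, nz$zones, zw)
  tot <- tab[tab$pair_id == "Total" & tab$measure == "collisions", ]
  pairs <- tab[tab$pair_id != "Total" & tab$measure == "collisions", ]
  expect_equal(tot$n_pre_impl, sum(pairs$n_pre_impl))
  expect_equal(tot$n_post_ctrl, sum(pairs$n_post_ctrl))
  # missing window is a configuration error
  expect_error(zone_table(sim$collisions, m, nz$zones, zw[1:2]),
               "pair3")
  # identical streams in both zones give a DiD of exactly zero
  pdx <- percent_diff(120, 2, 100, 1)
  expect_equal(did(pdx, pdx)$value, 0)
})
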