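test_that("the generator is deterministic for a fixed seed", {
  cfg <- sim_config(seed = 1, baseline_monthly_rate = 1, months_pre = 12,
                    months_post = 6, n_zone_pairs = 2)
  nz1 <- make_network(cfg); nz2 <- make_network(cfg)
  p1 <- tempfile(); p2 <- tempfile()
  write_network(nz1$network, p1); write_network(nz2$network, p2)
  expect_identical(readLines(p1), readLines(p2))  # byte-identical GeoJSON
  s1 <- simulate_collisions(cfg, nz1$network, nz1$zones)
  s2 <- simulate_collisions(cfg, nz2$network, nz2$zones)
  expect_identical(s1$collisions, s2$collisions)
  expect_identical(s1$truth, s2$truth)
})

test_that("the network layout keeps categories apart and pairs matched", {
  cfg <- sim_config(seed = 1, n_zone_pairs = 7)
  nz <- make_network(cfg)
  expect_equal(nrow(nz$zones), 14L)
  expect_equal(length(unique(nz$zones$pair_id)), 7L)
  # matched pairs cover identical areas
  areas <- vapply(nz$zones$rings, calmstreets:::zone_area, numeric(1))
  by_pair <- split(areas, nz$zones$pair_id)
  for (a in by_pair) expect_equal(a[1], a[2])
  # exhaustive pairwise check: different-category segments >= 30 m apart
  net <- nz$network
  n <- nrow(net)
  min_d <- Inf
  for (i in seq_len(n - 1)) {
    vi <- net$vertices[[i]]
    for (j in seq(i + 1, n)) {
      if (net$category[i] == net$category[j]) next
      vj <- net$vertices[[j]]
      d <- min(point_polyline_distance(vi[1, ], vj),
               point_polyline_distance(vi[2, ], vj),
               point_polyline_distance(vj[1, ], vi),
               point_polyline_distance(vj[2, ], vi))
      min_d <- min(min_d, d)
    }
  }
  expect_gte(min_d, 30)
})

test_that("simulated monthly means match the closed-form intensity", {
  # flat regime: no trend, no seasonality, no intervention
  cfg <- sim_config(seed = 2, baseline_monthly_rate = 8, trend = 1,
                    seasonal_amplitude = 0, intervention_effect = 1,
                    months_pre = 120, months_post = 120,
                    n_segments_per_category = 1, n_zone_pairs = 1,
                    position_jitter_sd = 0)
  nz <- make_network(cfg)
  sim <- simulate_collisions(cfg, nz$network, nz$zones)
  n_months <- cfg$months_pre + cfg$months_post
  n_seg <- nrow(nz$network)
  lam_total <- 8 * n_seg * n_months
  # z-test at alpha = 0.001 on the total count
  zstat <- (nrow(sim$collisions) - lam_total) / sqrt(lam_total)
  expect_lt(abs(zstat), qnorm(0.9995))
  # per-month mean within 3 * sqrt(lambda / n_months) of the baseline
  per_month <- nrow(sim$collisions) / n_months / n_seg
  expect_lt(abs(per_month - 8), 3 * sqrt(8 / n_months))
})

test_that("degenerate generator settings behave as documented", {
  cfg <- sim_config(seed = 3, baseline_monthly_rate = 1, months_pre = 12,
                    months_post = 0, n_zone_pairs = 1,
                    position_jitter_sd = 0,
                    severity_probs = c(slight = 1, serious = 0, fatal = 0),
                    casualty_excess_mean = 0)
  nz <- make_network(cfg)
  sim <- simulate_collisions(cfg, nz$network, nz$zones)
  expect_true(all(as.character(sim$collisions$severity) == "slight"))
  expect_true(all(sim$collisions$n_casualties == 1L))
  # zero jitter: every collision lies exactly on its source street
  seg_of <- setNames(nz$network$vertices, nz$network$id)
  d <- vapply(seq_len(nrow(sim$collisions)), function(i) {
    point_polyline_distance(c(sim$collisions$easting[i],
                              sim$collisions$northing[i]),
                            seg_of[[sim$truth$true_segment_id[i]]])
  }, numeric(1))
  expect_true(all(d < 1e-9))
})

test_that("the intervention multiplies treated post-period counts only", {
  base <- sim_config(seed = 6, baseline_monthly_rate = 6, trend = 1,
                     seasonal_amplitude = 0, months_pre = 60,
                     months_post = 60, n_zone_pairs = 2,
                     start_date = "2010-01-01",
                     intervention_date = "2015-01-01")
  null_cfg <- base; null_cfg$intervention_effect <- 1
  eff_cfg <- base; eff_cfg$intervention_effect <- 0.5
  nz <- make_network(base)
  post_treated <- function(cfg) {
    sim <- simulate_collisions(cfg, nz$network, nz$zones)
    m <- snap_collisions(sim$collisions, nz$network, zones = nz$zones)
    cat_of <- setNames(as.character(nz$network$category), nz$network$id)
    treated <- cat_of[m$segment_id] %in% c("changed20_local", "changed20_main")
    post <- sim$collisions$date >= as.Date("2015-01-01")
    c(sum(treated & post, na.rm = TRUE), sum(treated & !post, na.rm = TRUE))
  }
  n_null <- post_treated(null_cfg)
  n_eff <- post_treated(eff_cfg)
  # pre-period counts are unaffected by the intervention setting
  expect_lt(abs(n_eff[2] - n_null[2]) / n_null[2], 0.15)
  # post-period treated counts drop by about half
  ratio <- n_eff[1] / n_null[1]
  expect_lt(abs(ratio - 0.5), 0.1)
})

test_that("simulate_monthly_series matches its closed form on average", {
  set.seed(4)
  s <- simulate_monthly_series(200, 0, baseline_monthly = 100, trend = 1,
                               seasonal_amplitude = 0)
  lam <- 100 * s$days_in_month / 30
  zstat <- (sum(s$count) - sum(lam)) / sqrt(sum(lam))
  expect_lt(abs(zstat), qnorm(0.9995))
  expect_true(all(s$days_in_month %in% 28:31))
  expect_false(any(s$is_post))
})
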