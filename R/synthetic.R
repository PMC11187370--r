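#' Configuration for the synthetic study generator
#'
#' Defaults describe the emulated study conditions: a 3-year pre period
#' and a 1.83-year post period (36 + 22 months), seven matched
#' implementation/control zone pairs, a secular downward trend of 3% per
#' year, mild annual seasonality, a 17% step reduction on converted
#' streets from the intervention date, about 1.13 casualties per
#' collision, a severity mix dominated by slight injuries, and collision
#' coordinates jittered a few metres off their true street so the 12 m
#' snapping rule is genuinely exercised.
#'
#' @param seed integer RNG seed.
#' @param n_segments_per_category segments per category within each zone
#'   (default 1).
#' @param n_zone_pairs matched implementation/control pairs (default 7).
#' @param baseline_monthly_rate expected collisions per segment-month at
#'   the study start (default 10).
#' @param trend multiplicative rate change per year (default 0.97).
#' @param seasonal_amplitude log-scale sine amplitude (default 0.1).
#' @param intervention_effect rate ratio applied to converted streets from
#'   the intervention date (default 0.83).
#' @param casualty_excess_mean mean extra casualties beyond the first per
#'   collision (default 0.13).
#' @param severity_probs probabilities over `(slight, serious, fatal)` for
#'   each casualty; must sum to 1 (default `c(0.85, 0.145, 0.005)`).
#' @param position_jitter_sd isotropic Gaussian jitter SD in metres
#'   (default 3).
#' @param months_pre,months_post months before/after the intervention
#'   (defaults 36 and 22).
#' @param start_date first day of the study (default `"2013-08-01"`).
#' @param intervention_date date(s) the intervention starts: length 1 for
#'   a common date (the default, `"2016-08-01"`) or one per zone pair for
#'   a stepped-wedge rollout.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_segments_per_category = 1L,
                       n_zone_pairs = 7L,
                       baseline_monthly_rate = 10,
                       trend = 0.97,
                       seasonal_amplitude = 0.1,
                       intervention_effect = 0.83,
                       casualty_excess_mean = 0.13,
                       severity_probs = c(slight = 0.85, serious = 0.145,
                                          fatal = 0.005),
                       position_jitter_sd = 3,
                       months_pre = 36L,
                       months_post = 22L,
                       start_date = "2013-08-01",
                       intervention_date = "2016-08-01") {
  stopifnot(abs(sum(severity_probs) - 1) < 1e-12,
            all(severity_probs >= 0),
            baseline_monthly_rate >= 0, position_jitter_sd >= 0,
            casualty_excess_mean >= 0, intervention_effect > 0,
            months_pre >= 1, months_post >= 0,
            n_zone_pairs >= 1, n_segments_per_category >= 1)
  if (!length(intervention_date) %in% c(1L, n_zone_pairs)) {
    stop("intervention_date must have length 1 or n_zone_pairs",
         call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed),
    n_segments_per_category = as.integer(n_segments_per_category),
    n_zone_pairs = as.integer(n_zone_pairs),
    baseline_monthly_rate = baseline_monthly_rate,
    trend = trend,
    seasonal_amplitude = seasonal_amplitude,
    intervention_effect = intervention_effect,
    casualty_excess_mean = casualty_excess_mean,
    severity_probs = severity_probs,
    position_jitter_sd = position_jitter_sd,
    months_pre = as.integer(months_pre),
    months_post = as.integer(months_post),
    start_date = as.Date(start_date),
    intervention_date = as.Date(rep_len(as.character(intervention_date),
                                        n_zone_pairs))
  ), class = "sim_config")
}

# category blueprints used for the implementation-side streets
CATEGORY_BLUEPRINT <- data.frame(
  category = c("existing20", "changed20_local", "changed20_main",
               "stay30", "other"),
  limit_pre = c(20, 30, 30, 30, 40),
  limit_post = c(20, 20, 20, 30, 40),
  street_class = c("local", "local", "main", "main", "other"),
  stringsAsFactors = FALSE
)

#' Build a deterministic synthetic network and zone set
#'
#' Straight 200 m street segments laid out on parallel rows 40 m apart,
#' so streets of different categories are always at least 40 m from each
#' other and a 12 m snapping threshold is unambiguous. Each zone pair is
#' two disjoint rectangles of identical area: the implementation-side
#' rectangle holds one row per category (times
#' `n_segments_per_category`), the control-side rectangle (1000 m to the
#' east, standing in for a matched zone in another city) holds the same
#' number of rows, all of which are 30 mph throughout. Fully
#' deterministic: no randomness is used.
#'
#' @param cfg [sim_config()].
#' @return list with `network` and `zones` tibbles in the formats of
#'   [read_network()] and [read_zones()].
#' @export
make_network <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  spacing <- 40; seg_len <- 200; x_ctrl <- 1000; margin <- 15
  rows_per_zone <- nrow(CATEGORY_BLUEPRINT) * cfg$n_segments_per_category
  segs <- list(); zrows <- list()
  seg_i <- 0L
  row_i <- 0L
  for (p in seq_len(cfg$n_zone_pairs)) {
    y_first <- (row_i + 1L) * spacing
    for (k in seq_len(cfg$n_segments_per_category)) {
      for (b in seq_len(nrow(CATEGORY_BLUEPRINT))) {
        row_i <- row_i + 1L
        y <- row_i * spacing
        seg_i <- seg_i + 1L
        segs[[seg_i]] <- list(
          id = sprintf("seg%04d", seg_i),
          vertices = cbind(c(0, seg_len), c(y, y)),
          limit_pre = CATEGORY_BLUEPRINT$limit_pre[b],
          limit_post = CATEGORY_BLUEPRINT$limit_post[b],
          street_class = CATEGORY_BLUEPRINT$street_class[b]
        )
        # mirrored control-side street: 30 mph before and after
        seg_i <- seg_i + 1L
        segs[[seg_i]] <- list(
          id = sprintf("seg%04d", seg_i),
          vertices = cbind(c(x_ctrl, x_ctrl + seg_len), c(y, y)),
          limit_pre = 30, limit_post = 30, street_class = "main"
        )
      }
    }
    y_last <- row_i * spacing
    rect <- function(x0) {
      m <- rbind(c(x0 - margin, y_first - margin),
                 c(x0 + seg_len + margin, y_first - margin),
                 c(x0 + seg_len + margin, y_last + margin),
                 c(x0 - margin, y_last + margin),
                 c(x0 - margin, y_first - margin))
      list(m)
    }
    zrows[[length(zrows) + 1L]] <- list(
      id = sprintf("impl%d", p), rings = rect(0), role = "implementation",
      pair_id = sprintf("pair%d", p),
      intervention_date = cfg$intervention_date[p])
    zrows[[length(zrows) + 1L]] <- list(
      id = sprintf("ctrl%d", p), rings = rect(x_ctrl), role = "control",
      pair_id = sprintf("pair%d", p), intervention_date = as.Date(NA))
  }
  network <- tibble::tibble(
    id = vapply(segs, `[[`, character(1), "id"),
    vertices = lapply(segs, `[[`, "vertices"),
    limit_pre = vapply(segs, `[[`, numeric(1), "limit_pre"),
    limit_post = vapply(segs, `[[`, numeric(1), "limit_post"),
    street_class = vapply(segs, `[[`, character(1), "street_class")
  )
  zones <- tibble::tibble(
    id = vapply(zrows, `[[`, character(1), "id"),
    rings = lapply(zrows, `[[`, "rings"),
    role = vapply(zrows, `[[`, character(1), "role"),
    pair_id = vapply(zrows, `[[`, character(1), "pair_id"),
    intervention_date = as.Date(vapply(zrows, function(r)
      as.character(r$intervention_date), character(1)))
  )
  list(network = validate_network(network), zones = validate_zones(zones))
}

# closed-form monthly mean for one segment
segment_lambda <- function(cfg, month_of_year, t_years, treated_post) {
  cfg$baseline_monthly_rate * cfg$trend^t_years *
    exp(cfg$seasonal_amplitude * sin(2 * pi * month_of_year / 12)) *
    ifelse(treated_post, cfg$intervention_effect, 1)
}

#' Simulate a collision stream over a synthetic network
#'
#' Per segment-month counts are Poisson with log-mean
#' `log(baseline) + t * log(trend_per_year) + A * sin(2 pi month/12)`,
#' plus `log(intervention_effect)` on converted (30-to-20) streets inside
#' an implementation zone from that zone's intervention date. Each
#' collision is placed uniformly along its street, then displaced by
#' isotropic Gaussian jitter; casualties are `1 + Poisson(excess)`;
#' casualty severities are drawn from `severity_probs` and the collision
#' records the most severe. Ground-truth segment and zone labels are
#' returned separately so the spatial matcher can be validated without
#' the analysis path ever seeing them.
#'
#' @param cfg [sim_config()].
#' @param network,zones output of [make_network()].
#' @return list with `collisions` (analysis-facing tibble) and `truth`
#'   (tibble `collision_id, true_segment_id, true_zone_id`).
#' @export
simulate_collisions <- function(cfg, network, zones) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)

  n_months <- cfg$months_pre + cfg$months_post
  months <- seq(floor_month(cfg$start_date), by = "1 month",
                length.out = n_months)
  mdays <- vapply(months, days_in_month, integer(1))
  moy <- as.integer(format(months, "%m"))
  t_years <- (seq_len(n_months) - 0.5) / 12

  # segment midpoints -> containing zone (the ground-truth zone)
  mids <- t(vapply(network$vertices, function(v)
    c(mean(v[, 1]), mean(v[, 2])), numeric(2)))
  seg_zone <- assign_zone(mids, zones)
  zdate <- setNames(zones$intervention_date, zones$id)
  treated_cat <- network$category %in% c("changed20_local", "changed20_main")
  impl_zone <- seg_zone %in% zones$id[zones$role == "implementation"]

  sev_levels <- SEVERITY_LEVELS
  recs <- vector("list", nrow(network) * n_months)
  k <- 0L
  for (s in seq_len(nrow(network))) {
    v <- network$vertices[[s]]
    treated <- treated_cat[s] && impl_zone[s]
    post_m <- if (treated) months >= floor_month(zdate[[seg_zone[s]]]) else
      rep(FALSE, n_months)
    lam <- segment_lambda(cfg, moy, t_years, post_m)
    counts <- rpois(n_months, lam)
    for (m in which(counts > 0L)) {
      nc <- counts[m]
      u <- runif(nc)
      px <- v[1, 1] + u * (v[2, 1] - v[1, 1]) + rnorm(nc, 0, cfg$position_jitter_sd)
      py <- v[1, 2] + u * (v[2, 2] - v[1, 2]) + rnorm(nc, 0, cfg$position_jitter_sd)
      dates <- months[m] + sample.int(mdays[m], nc, replace = TRUE) - 1L
      ncas <- 1L + rpois(nc, cfg$casualty_excess_mean)
      sev <- vapply(ncas, function(nn)
        max(sample.int(3L, nn, replace = TRUE, prob = cfg$severity_probs)),
        integer(1))
      k <- k + 1L
      recs[[k]] <- tibble::tibble(
        date = dates, easting = px, northing = py,
        severity = sev_levels[sev], n_casualties = ncas,
        true_segment_id = network$id[s], true_zone_id = seg_zone[s]
      )
    }
  }
  all <- do.call(rbind, recs[seq_len(k)])
  all <- all[order(all$date, all$true_segment_id, all$easting), ]
  all$id <- sprintf("c%06d", seq_len(nrow(all)))
  collisions <- as_collisions(all[, c("id", "date", "easting", "northing",
                                      "severity", "n_casualties")])
  truth <- tibble::tibble(collision_id = all$id,
                          true_segment_id = all$true_segment_id,
                          true_zone_id = all$true_zone_id)
  list(collisions = collisions, truth = truth)
}

#' Simulate a monthly count series directly
#'
#' City-level analogue of [simulate_collisions()] for interrupted
#' time-series studies: Poisson monthly counts with a log-linear secular
#' trend, sinusoidal annual seasonality, a day-count exposure adjustment,
#' and a step rate-ratio applied to the post months.
#'
#' @param n_pre,n_post numbers of pre/post months.
#' @param baseline_monthly expected events in a 30-day pre month at t = 0.
#' @param trend multiplicative change per year.
#' @param seasonal_amplitude log-scale sine amplitude.
#' @param effect rate ratio applied to post months (1 = null).
#' @param start first month (Date or string).
#' @return `monthly_series` tibble (see [aggregate_monthly()]).
#' @export
simulate_monthly_series <- function(n_pre, n_post, baseline_monthly = 120,
                                    trend = 0.97, seasonal_amplitude = 0.1,
                                    effect = 1, start = "1996-01-01") {
  n <- n_pre + n_post
  months <- seq(floor_month(as.Date(start)), by = "1 month", length.out = n)
  mdays <- vapply(months, days_in_month, integer(1))
  moy <- as.integer(format(months, "%m"))
  t_years <- (seq_len(n) - 0.5) / 12
  is_post <- seq_len(n) > n_pre
  lam <- baseline_monthly * (mdays / 30) * trend^t_years *
    exp(seasonal_amplitude * sin(2 * pi * moy / 12)) *
    ifelse(is_post, effect, 1)
  out <- tibble::tibble(year_month = months, count = rpois(n, lam),
                        days_in_month = mdays, is_post = is_post)
  class(out) <- c("monthly_series", class(out))
  out
}
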