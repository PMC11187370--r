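# z for 95% two-sided intervals: the normal 97.5th percentile, kept at
# full precision rather than 1.96
z_crit <- function(level) qnorm(1 - (1 - level) / 2)

#' Annualized event rate
#'
#' @param count non-negative event count over the period.
#' @param exposure exposure time in years (> 0).
#' @return events per year, `count / exposure`.
#' @export
annual_rate <- function(count, exposure) {
  if (any(exposure <= 0)) stop("exposure must be positive", call. = FALSE)
  if (any(count < 0)) stop("count must be non-negative", call. = FALSE)
  count / exposure
}

#' Exact Poisson (Garwood) confidence interval for an annualized rate
#'
#' Chi-square form of the exact Poisson interval applied to the annualized
#' rate value treated as a Poisson count:
#' `lo = qchisq(alpha/2, 2r) / 2`, `hi = qchisq(1 - alpha/2, 2r + 2) / 2`.
#' Continuous `r` is permitted (annualization rarely yields an integer);
#' the lower bound is 0 at `r = 0`.
#'
#' @param rate_value annualized rate (events/year, >= 0); vectorized.
#' @param level confidence level (default 0.95).
#' @return tibble with columns `lo`, `hi` on the same scale as
#'   `rate_value`.
#' @export
poisson_exact_ci <- function(rate_value, level = 0.95) {
  if (any(rate_value < 0)) stop("rate must be non-negative", call. = FALSE)
  a <- 1 - level
  lo <- ifelse(rate_value == 0, 0, 0.5 * qchisq(a / 2, 2 * rate_value))
  hi <- 0.5 * qchisq(1 - a / 2, 2 * rate_value + 2)
  tibble::tibble(lo = lo, hi = hi)
}

#' Difference of two annualized rates with normal-approximation CI
#'
#' Point difference `N2/T2 - N1/T1`; variance from the Poisson count
#' variance scaled by exposure, `N1/T1^2 + N2/T2^2`.
#'
#' @param n_pre,t_pre pre-period count and exposure (years).
#' @param n_post,t_post post-period count and exposure (years).
#' @param level confidence level.
#' @return list with `diff`, `lo`, `hi` (events/year).
#' @export
rate_difference <- function(n_pre, t_pre, n_post, t_post, level = 0.95) {
  if (any(c(t_pre, t_post) <= 0)) stop("exposure must be positive", call. = FALSE)
  d <- n_post / t_post - n_pre / t_pre
  se <- sqrt(n_pre / t_pre^2 + n_post / t_post^2)
  z <- z_crit(level)
  list(diff = d, lo = d - z * se, hi = d + z * se)
}

#' Percent change in rates with delta-method SD
#'
#' `value = 100 * (R_post/R_pre - 1)`. Since `Var(R)/R^2 = 1/N` for a
#' Poisson count N, the first-order (delta-method) SD of the percent
#' change is `100 * (R_post/R_pre) * sqrt(1/N_pre + 1/N_post)`.
#'
#' @param n_pre,t_pre pre-period count (> 0) and exposure.
#' @param n_post,t_post post-period count and exposure.
#' @return list of class `percent_diff` with `value` and `sd` (both in
#'   percent). A zero post count gives `value = -100` with `sd = NA` and
#'   `degenerate = TRUE`.
#' @export
percent_diff <- function(n_pre, t_pre, n_post, t_post) {
  if (any(c(t_pre, t_post) <= 0)) stop("exposure must be positive", call. = FALSE)
  if (n_pre == 0) {
    stop("percent change is undefined for a zero pre-period count",
         call. = FALSE)
  }
  ratio <- (n_post / t_post) / (n_pre / t_pre)
  value <- 100 * (ratio - 1)
  if (n_post == 0) {
    return(structure(list(value = -100, sd = NA_real_, degenerate = TRUE),
                     class = "percent_diff"))
  }
  sd <- 100 * ratio * sqrt(1 / n_pre + 1 / n_post)
  structure(list(value = value, sd = sd, degenerate = FALSE),
            class = "percent_diff")
}

#' Percent change from two already-annualized rates
#'
#' Point value only — for inputs where the underlying counts are not
#' available (e.g. rates transcribed from a published table).
#'
#' @param r_pre,r_post annualized rates (events/year), `r_pre > 0`.
#' @return percent change `100 * (r_post/r_pre - 1)`.
#' @export
percent_diff_from_rates <- function(r_pre, r_post) {
  if (any(r_pre <= 0)) stop("pre-period rate must be positive", call. = FALSE)
  100 * (r_post / r_pre - 1)
}

#' Difference-in-differences of two percent changes
#'
#' `value = treated - reference` (percent points); the CI combines the two
#' delta-method SDs in quadrature, assuming independent count streams.
#'
#' @param treated,reference `percent_diff` objects (or lists with `value`
#'   and `sd`).
#' @param level confidence level.
#' @return list with `value`, `lo`, `hi` (percent points).
#' @export
did <- function(treated, reference, level = 0.95) {
  if (!is.finite(treated$sd) || !is.finite(reference$sd)) {
    stop("difference-in-differences requires finite SDs on both arms",
         call. = FALSE)
  }
  v <- treated$value - reference$value
  se <- sqrt(treated$sd^2 + reference$sd^2)
  z <- z_crit(level)
  list(value = v, lo = v - z * se, hi = v + z * se)
}

#' Round half away from zero
#'
#' Display rounding used in the published-style tables (base `round()`
#' rounds half to even). Internal computation is always unrounded.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Rate comparison table from pre/post counts
#'
#' The workhorse behind [segment_table()] and the printed-table
#' reproduction path: given per-group pre/post counts and exposures it
#' computes annualized rates with Garwood CIs, the rate difference with a
#' normal CI, the percent change with delta-method SD and CI, and the
#' difference-in-differences of each group against a reference group.
#'
#' @param counts data frame with columns `group`, `measure`, `n_pre`,
#'   `n_post` (one row per group x measure).
#' @param pre_years,post_years exposures in years.
#' @param ref_group group label used as the DiD reference (its own DiD
#'   cells are `NA`).
#' @param level confidence level.
#' @return tibble with one row per group x measure and columns
#'   `group, measure, n_pre, n_post, rate_pre, rate_pre_lo, rate_pre_hi,
#'   rate_post, rate_post_lo, rate_post_hi, diff, diff_lo, diff_hi,
#'   pct_diff, pct_diff_sd, pct_diff_lo, pct_diff_hi, did, did_lo, did_hi`.
#'   All values unrounded; empty groups (zero pre count) get `NA`
#'   percent-change cells and a `flagged` marker.
#' @export
rate_table <- function(counts, pre_years, post_years, ref_group = "stay30",
                       level = 0.95) {
  stopifnot(all(c("group", "measure", "n_pre", "n_post") %in% names(counts)))
  counts <- counts[order(counts$measure, counts$group), , drop = FALSE]
  z <- z_crit(level)
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    n1 <- counts$n_pre[i]; n2 <- counts$n_post[i]
    r1 <- annual_rate(n1, pre_years); r2 <- annual_rate(n2, post_years)
    ci1 <- poisson_exact_ci(r1, level); ci2 <- poisson_exact_ci(r2, level)
    d <- rate_difference(n1, pre_years, n2, post_years, level)
    if (n1 > 0 && n2 > 0) {
      pd <- percent_diff(n1, pre_years, n2, post_years)
      pct <- pd$value; pct_sd <- pd$sd
      pct_lo <- pct - z * pct_sd; pct_hi <- pct + z * pct_sd
      flagged <- FALSE
    } else {
      pct <- if (n1 > 0) -100 else NA_real_
      pct_sd <- NA_real_; pct_lo <- NA_real_; pct_hi <- NA_real_
      flagged <- TRUE
    }
    tibble::tibble(
      group = as.character(counts$group[i]),
      measure = as.character(counts$measure[i]),
      n_pre = n1, n_post = n2,
      rate_pre = r1, rate_pre_lo = ci1$lo, rate_pre_hi = ci1$hi,
      rate_post = r2, rate_post_lo = ci2$lo, rate_post_hi = ci2$hi,
      diff = d$diff, diff_lo = d$lo, diff_hi = d$hi,
      pct_diff = pct, pct_diff_sd = pct_sd,
      pct_diff_lo = pct_lo, pct_diff_hi = pct_hi, flagged = flagged
    )
  })
  tab <- do.call(rbind, rows)
  # DiD of every group against the reference, within measure
  tab$did <- NA_real_; tab$did_lo <- NA_real_; tab$did_hi <- NA_real_
  for (m in unique(tab$measure)) {
    ref <- tab[tab$measure == m & tab$group == ref_group, ]
    if (nrow(ref) != 1L || ref$flagged) next
    refpd <- list(value = ref$pct_diff, sd = ref$pct_diff_sd)
    for (i in which(tab$measure == m & tab$group != ref_group)) {
      if (tab$flagged[i]) next
      dd <- did(list(value = tab$pct_diff[i], sd = tab$pct_diff_sd[i]),
                refpd, level)
      tab$did[i] <- dd$value; tab$did_lo[i] <- dd$lo; tab$did_hi[i] <- dd$hi
    }
  }
  tab
}

#' Segment-category rate table from matched collisions
#'
#' Aggregates matched collisions into per-category pre/post counts of
#' collisions (records) and casualties (sum of `n_casualties`), then runs
#' [rate_table()] with the streets staying at 30 mph as the DiD
#' reference. Collisions falling outside the pre and post windows, or
#' unmatched to any segment, are excluded.
#'
#' @param collisions collision tibble.
#' @param matches tibble from [snap_collisions()].
#' @param network network tibble (supplies the segment categories).
#' @param window [study_window()] (its `pre_years`/`post_years` are the
#'   exposures used).
#' @param ref_group DiD reference category (default `"stay30"`).
#' @param level confidence level.
#' @return the [rate_table()] tibble, one row per category x
#'   {collisions, casualties}.
#' @export
segment_table <- function(collisions, matches, network, window,
                          ref_group = "stay30", level = 0.95) {
  stopifnot(inherits(window, "study_window"))
  cat_of <- setNames(as.character(network$category), network$id)
  m <- merge(as.data.frame(matches), as.data.frame(collisions),
             by.x = "collision_id", by.y = "id")
  m <- m[!is.na(m$segment_id), , drop = FALSE]
  m$category <- cat_of[m$segment_id]
  pre <- m$date >= window$pre_start & m$date <= window$pre_end
  post <- m$date >= window$post_start & m$date <= window$post_end
  cats <- levels(network$category)
  count_by <- function(keep, weights) {
    out <- setNames(rep(0, length(cats)), cats)
    if (any(keep)) {
      agg <- tapply(weights[keep], m$category[keep], sum)
      out[names(agg)] <- agg
    }
    out
  }
  ones <- rep(1, nrow(m))
  counts <- rbind(
    data.frame(group = cats, measure = "collisions",
               n_pre = count_by(pre, ones), n_post = count_by(post, ones)),
    data.frame(group = cats, measure = "casualties",
               n_pre = count_by(pre, m$n_casualties),
               n_post = count_by(post, m$n_casualties))
  )
  rate_table(counts, window$pre_years, window$post_years,
             ref_group = ref_group, level = level)
}

#' Implementation-versus-control zone comparison table
#'
#' For each matched implementation/control pair, computes pre/post rates
#' and percent changes for collisions and casualties, and the
#' difference-in-differences (implementation minus control). A `Total` row
#' per measure pools counts across all pairs. Because the intervention was
#' phased, each pair uses its own pre/post windows.
#'
#' @param collisions collision tibble.
#' @param matches tibble from [snap_collisions()] (must carry `zone_id`).
#' @param zones zone tibble.
#' @param zone_windows named list mapping each implementation `pair_id` to
#'   a [study_window()]; a missing entry is a configuration error.
#' @param level confidence level.
#' @return tibble with one row per pair x measure plus `Total` rows;
#'   columns `pair_id, measure, n_pre_impl, n_post_impl, n_pre_ctrl,
#'   n_post_ctrl, rate_pre_impl, rate_post_impl, rate_pre_ctrl,
#'   rate_post_ctrl, pct_impl, pct_impl_sd, pct_ctrl, pct_ctrl_sd, did,
#'   did_lo, did_hi`.
#' @export
zone_table <- function(collisions, matches, zones, zone_windows,
                       level = 0.95) {
  pairs <- sort(unique(zones$pair_id))
  missing_w <- setdiff(pairs, names(zone_windows))
  if (length(missing_w)) {
    stop("no study window supplied for zone pair(s): ",
         paste(missing_w, collapse = ", "), call. = FALSE)
  }
  m <- merge(as.data.frame(matches), as.data.frame(collisions),
             by.x = "collision_id", by.y = "id")
  m <- m[!is.na(m$zone_id), , drop = FALSE]
  zrole <- setNames(zones$role, zones$id)
  zpair <- setNames(zones$pair_id, zones$id)
  m$role <- zrole[m$zone_id]
  m$pair_id <- zpair[m$zone_id]

  cell <- function(pair, role, w, weights) {
    sel <- m$pair_id == pair & m$role == role
    c(pre = sum(weights[sel & m$date >= w$pre_start & m$date <= w$pre_end]),
      post = sum(weights[sel & m$date >= w$post_start & m$date <= w$post_end]))
  }
  rows <- list()
  totals <- list()
  for (meas in c("collisions", "casualties")) {
    weights <- if (meas == "collisions") rep(1, nrow(m)) else m$n_casualties
    tot <- c(ipre = 0, ipost = 0, cpre = 0, cpost = 0,
             tpre = 0, tpost = 0)
    for (pair in pairs) {
      w <- zone_windows[[pair]]
      stopifnot(inherits(w, "study_window"))
      ci <- cell(pair, "implementation", w, weights)
      cc <- cell(pair, "control", w, weights)
      rows[[length(rows) + 1L]] <- zone_row(pair, meas, ci, cc, w, level)
      tot <- tot + c(ci["pre"], ci["post"], cc["pre"], cc["post"],
                     w$pre_years, w$post_years)
    }
    # pooled total: counts summed over pairs; exposure is the common
    # window when all pairs share one, else the pair-average
    npairs <- length(pairs)
    wtot <- list(pre_years = tot[["tpre"]] / npairs,
                 post_years = tot[["tpost"]] / npairs)
    totals[[meas]] <- zone_row("Total", meas,
                               c(pre = tot[["ipre"]], post = tot[["ipost"]]),
                               c(pre = tot[["cpre"]], post = tot[["cpost"]]),
                               wtot, level)
  }
  do.call(rbind, c(rows, totals))
}

zone_row <- function(pair, meas, impl, ctrl, w, level) {
  z <- z_crit(level)
  pd_safe <- function(n1, n2) {
    if (n1 > 0 && n2 > 0) {
      percent_diff(n1, w$pre_years, n2, w$post_years)
    } else {
      list(value = NA_real_, sd = NA_real_)
    }
  }
  pi <- pd_safe(impl[["pre"]], impl[["post"]])
  pc <- pd_safe(ctrl[["pre"]], ctrl[["post"]])
  dd <- if (is.finite(pi$sd) && is.finite(pc$sd)) {
    did(pi, pc, level)
  } else {
    list(value = NA_real_, lo = NA_real_, hi = NA_real_)
  }
  tibble::tibble(
    pair_id = pair, measure = meas,
    n_pre_impl = impl[["pre"]], n_post_impl = impl[["post"]],
    n_pre_ctrl = ctrl[["pre"]], n_post_ctrl = ctrl[["post"]],
    rate_pre_impl = impl[["pre"]] / w$pre_years,
    rate_post_impl = impl[["post"]] / w$post_years,
    rate_pre_ctrl = ctrl[["pre"]] / w$pre_years,
    rate_post_ctrl = ctrl[["post"]] / w$post_years,
    pct_impl = pi$value, pct_impl_sd = pi$sd,
    pct_ctrl = pc$value, pct_ctrl_sd = pc$sd,
    did = dd$value, did_lo = dd$lo, did_hi = dd$hi
  )
}
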