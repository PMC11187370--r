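MPH_PER_KMH <- 1 / 1.609344

#' Convert speeds between mph and km/h
#'
#' Exact conversion (1 mph = 1.609344 km/h). Identity when `from == to`.
#'
#' @param x speeds.
#' @param from,to `"mph"` or `"kmh"`.
#' @return converted speeds.
#' @export
convert_speed <- function(x, from, to) {
  from <- match.arg(from, c("mph", "kmh"))
  to <- match.arg(to, c("mph", "kmh"))
  if (from == to) return(x)
  if (from == "mph") x * 1.609344 else x * MPH_PER_KMH
}

#' Severity-specific exponents for the exponential speed-injury model
#'
#' Default values are the published 20-30 mph range estimates with their
#' 95% bounds: 0.034 (0.014 to 0.054) per km/h for all injuries, 0.069
#' (0.045 to 0.093) for serious and for fatal. The unit of the exponent
#' (per km/h by default, per the source calibration) is carried
#' explicitly and checked wherever the exponent meets a speed change;
#' it is never silently assumed.
#'
#' @param injury,serious,fatal length-3 numeric vectors
#'   `(estimate, lo, hi)`.
#' @param speed_unit unit the exponents are per: `"kmh"` (default) or
#'   `"mph"`.
#' @return tibble of class `elvik_params` with columns `severity`,
#'   `exponent`, `lo`, `hi`, `se` (from `(hi - lo) / (2z)`), `speed_unit`.
#' @export
elvik_params <- function(injury = c(0.034, 0.014, 0.054),
                         serious = c(0.069, 0.045, 0.093),
                         fatal = c(0.069, 0.045, 0.093),
                         speed_unit = c("kmh", "mph")) {
  speed_unit <- match.arg(speed_unit)
  m <- rbind(injury = injury, serious = serious, fatal = fatal)
  if (any(m[, 2] > m[, 1] | m[, 1] > m[, 3])) {
    stop("exponent bounds must satisfy lo <= estimate <= hi", call. = FALSE)
  }
  z <- z_crit(0.95)
  out <- tibble::tibble(
    severity = rownames(m),
    exponent = unname(m[, 1]), lo = unname(m[, 2]), hi = unname(m[, 3]),
    se = unname((m[, 3] - m[, 2]) / (2 * z)),
    speed_unit = speed_unit
  )
  class(out) <- c("elvik_params", class(out))
  out
}

#' Speed and volume change summary
#'
#' @param speed_before,speed_after mean speeds (> 0) in `speed_unit`.
#' @param volume_before,volume_after traffic volumes (vehicles/day);
#'   `volume_before` must be positive.
#' @param speed_unit `"mph"` or `"kmh"`.
#' @return list of class `speed_volume_change`.
#' @export
speed_volume_change <- function(speed_before, speed_after,
                                volume_before, volume_after,
                                speed_unit = c("mph", "kmh")) {
  speed_unit <- match.arg(speed_unit)
  if (speed_before <= 0 || speed_after <= 0) {
    stop("speeds must be positive", call. = FALSE)
  }
  if (volume_before <= 0) stop("volume_before must be positive", call. = FALSE)
  structure(list(speed_before = speed_before, speed_after = speed_after,
                 volume_before = volume_before, volume_after = volume_after,
                 speed_unit = speed_unit),
            class = "speed_volume_change")
}

#' Exponential speed effect on an injury rate
#'
#' `rate_before * exp((speed_after - speed_before) * exponent)`. The speed
#' change and the exponent must be expressed per the same unit; a
#' mismatch is a configuration error — convert explicitly with
#' [convert_speed()].
#'
#' @param rate_before annual rate before the change (>= 0).
#' @param change [speed_volume_change()].
#' @param exponent severity-specific exponent.
#' @param exponent_unit unit the exponent is per (`"kmh"` or `"mph"`).
#' @return predicted annual rate.
#' @export
predict_speed <- function(rate_before, change, exponent,
                          exponent_unit = c("kmh", "mph")) {
  exponent_unit <- match.arg(exponent_unit)
  stopifnot(inherits(change, "speed_volume_change"))
  if (any(rate_before < 0)) stop("rate must be non-negative", call. = FALSE)
  if (change$speed_unit != exponent_unit) {
    stop("speed change is in ", change$speed_unit, " but the exponent is per ",
         exponent_unit, "; convert explicitly with convert_speed()",
         call. = FALSE)
  }
  dv <- change$speed_after - change$speed_before
  rate_before * exp(dv * exponent)
}

#' Linear traffic-volume adjustment
#'
#' `rate * (1 + (volume_after - volume_before) / volume_before)`, i.e. the
#' rate scaled by the relative volume change. Multiplicative, so it
#' commutes with [predict_speed()].
#'
#' @param rate annual rate.
#' @param change [speed_volume_change()].
#' @return adjusted rate.
#' @export
apply_volume <- function(rate, change) {
  stopifnot(inherits(change, "speed_volume_change"))
  rate * (1 + (change$volume_after - change$volume_before) /
            change$volume_before)
}

# convert a change's speeds into the exponent's unit
align_units <- function(change, exponent_unit) {
  if (change$speed_unit == exponent_unit) return(change)
  speed_volume_change(
    convert_speed(change$speed_before, change$speed_unit, exponent_unit),
    convert_speed(change$speed_after, change$speed_unit, exponent_unit),
    change$volume_before, change$volume_after, exponent_unit
  )
}

#' Per-zone exponential predictions summed over zones
#'
#' For each implementation zone and severity class, applies the speed
#' effect and the volume adjustment to the zone's before-rate, then sums
#' the zone predictions per severity. Zone speeds are converted to the
#' exponent's unit explicitly before the exponential is applied. A zone
#' present in the rate table but missing from the traffic table (or vice
#' versa) is a configuration error.
#'
#' @param traffic zone traffic tibble (see [read_zone_traffic()]).
#' @param rates tibble with columns `zone_id`, `severity`, `rate_before`
#'   (annual rate in the zone before the change).
#' @param params [elvik_params()].
#' @return tibble with one row per severity: `severity`,
#'   `rate_before` (summed), `predicted` (summed), and the per-zone mean
#'   `speed_factor` and `volume_factor` components.
#' @export
predict_by_zone <- function(traffic, rates, params = elvik_params()) {
  stopifnot(inherits(params, "elvik_params"))
  missing_z <- setdiff(unique(rates$zone_id), traffic$zone_id)
  if (length(missing_z)) {
    stop("no speed/volume data for zone(s): ",
         paste(missing_z, collapse = ", "), call. = FALSE)
  }
  tr <- traffic[match(rates$zone_id, traffic$zone_id), ]
  ex <- params$exponent[match(rates$severity, params$severity)]
  if (anyNA(ex)) {
    stop("unknown severity class in rate table", call. = FALSE)
  }
  dv <- convert_speed(tr$mean_speed_post - tr$mean_speed_pre,
                      tr$speed_unit[1], params$speed_unit[1])
  speed_factor <- exp(dv * ex)
  volume_factor <- 1 + (tr$volume_post - tr$volume_pre) / tr$volume_pre
  pred <- rates$rate_before * speed_factor * volume_factor
  sev <- unique(rates$severity)
  by_sev <- function(x, f) {
    vapply(sev, function(s) f(x[rates$severity == s]), numeric(1),
           USE.NAMES = FALSE)
  }
  tibble::tibble(
    severity = sev,
    rate_before = by_sev(rates$rate_before, sum),
    predicted = by_sev(pred, sum),
    speed_factor = by_sev(speed_factor, mean),
    volume_factor = by_sev(volume_factor, mean)
  )
}

#' Delta-method interval for an exponential-model prediction
#'
#' Propagates (a) the exponent uncertainty, with SE taken from the
#' published 95% bounds as `(hi - lo) / (2z)`, and (b) the Poisson
#' variance of the before-rate (relative variance `1/N` on a count basis
#' of `N` events). On the log scale
#' `Var(log pred) = 1/N + (dv * se_b)^2`, reported as a 95% normal
#' interval on the prediction scale via first-order propagation.
#'
#' @param prediction point prediction (annual rate).
#' @param n_before event count underlying the before-rate.
#' @param delta_speed speed change in the exponent's unit.
#' @param exponent_se SE of the exponent.
#' @param level confidence level.
#' @return list `(lo, hi, se)` on the prediction scale.
#' @export
prediction_interval <- function(prediction, n_before, delta_speed,
                                exponent_se, level = 0.95) {
  rel_var <- 1 / n_before + (delta_speed * exponent_se)^2
  se <- prediction * sqrt(rel_var)
  z <- z_crit(level)
  list(lo = prediction - z * se, hi = prediction + z * se, se = se)
}
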