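#' @importFrom stats aggregate pnorm qchisq qnorm quantile rnorm rpois runif
#'   sd setNames ppois predict var
#' @importFrom utils read.csv write.csv head modifyList
NULL

SEVERITY_LEVELS <- c("slight", "serious", "fatal")

# alias table for severity normalization; keys are lower-case. Unknown
# values are hard errors, never silently coerced to "slight".
SEVERITY_ALIASES <- c(
  slight  = "slight",
  serious = "serious",
  fatal   = "fatal",
  killed  = "fatal",
  minor   = "slight"
)

STREET_CLASSES <- c("local", "main", "other")
SEGMENT_CATEGORIES <- c("existing20", "changed20_local", "changed20_main",
                        "stay30", "other")
ZONE_ROLES <- c("implementation", "control")

#' Normalize collision severity labels
#'
#' Case-insensitive lookup in a fixed alias table mapping raw labels to the
#' canonical levels `slight`, `serious`, `fatal`. Unrecognized labels are an
#' error naming the offending rows.
#'
#' @param x character vector of raw severity labels.
#' @return factor with levels `slight < serious < fatal` (ordered).
#' @export
normalize_severity <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- unname(SEVERITY_ALIASES[key])
  bad <- which(is.na(out))
  if (length(bad)) {
    stop("unrecognized severity value(s) ",
         paste0("'", unique(x[bad]), "'", collapse = ", "),
         " at row(s) ", paste(head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  factor(out, levels = SEVERITY_LEVELS, ordered = TRUE)
}

#' Read collision records from CSV
#'
#' Expects a header with columns `id, date, easting, northing, severity,
#' n_casualties`. Dates must be ISO-8601 (`YYYY-MM-DD`); coordinates are
#' planar metres (British National Grid convention). Each collision must
#' carry at least one casualty.
#'
#' @param path path to a CSV file.
#' @return tibble with one row per collision: `id` (character), `date`
#'   (Date), `easting`, `northing` (numeric metres), `severity` (ordered
#'   factor), `n_casualties` (integer).
#' @export
read_collisions <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  req <- c("id", "date", "easting", "northing", "severity", "n_casualties")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols)) {
    stop("collision file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  as_collisions(tibble::tibble(
    id = raw$id,
    date = as.Date(raw$date, format = "%Y-%m-%d"),
    easting = as.numeric(raw$easting),
    northing = as.numeric(raw$northing),
    severity = raw$severity,
    n_casualties = suppressWarnings(as.integer(raw$n_casualties))
  ))
}

#' Validate a collision table
#'
#' Enforces the record invariants: parseable ISO dates, finite coordinates,
#' recognized severity, and `n_casualties >= 1`. Violations are errors
#' naming the offending row.
#'
#' @param x data frame with the collision columns (see [read_collisions()]).
#' @return validated tibble with normalized severity.
#' @export
as_collisions <- function(x) {
  x <- tibble::as_tibble(x)
  x$id <- as.character(x$id)
  if (!inherits(x$date, "Date")) x$date <- as.Date(x$date)
  fail <- function(rows, what) {
    stop("invalid collision record at row(s) ",
         paste(head(rows, 5L), collapse = ", "), ": ", what, call. = FALSE)
  }
  if (anyNA(x$date)) fail(which(is.na(x$date)), "unparseable date")
  coords_ok <- is.finite(x$easting) & is.finite(x$northing)
  if (!all(coords_ok)) fail(which(!coords_ok), "non-finite coordinates")
  x$severity <- normalize_severity(x$severity)
  nc <- x$n_casualties
  nc_ok <- !is.na(nc) & nc >= 1L & nc == as.integer(nc)
  if (!all(nc_ok)) fail(which(!nc_ok), "n_casualties must be an integer >= 1")
  x$n_casualties <- as.integer(nc)
  x
}

#' Write collision records to CSV
#'
#' Inverse of [read_collisions()]: a write-then-read round trip reproduces
#' every field, with coordinates preserved to full double precision.
#'
#' @param x collision tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_collisions <- function(x, path) {
  out <- data.frame(
    id = x$id,
    date = format(x$date, "%Y-%m-%d"),
    easting = format(x$easting, digits = 17, trim = TRUE, scientific = FALSE),
    northing = format(x$northing, digits = 17, trim = TRUE, scientific = FALSE),
    severity = as.character(x$severity),
    n_casualties = x$n_casualties
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Classify a road segment by its speed-limit history
#'
#' Deterministic, total mapping from (limit before, limit after, street
#' class) to the analysis categories: streets already at 20 mph before the
#' intervention (`existing20`), 30 mph streets converted to 20 mph split by
#' street class (`changed20_local`, `changed20_main`), streets at 30 mph
#' throughout (`stay30`), and everything else (`other`).
#'
#' @param limit_pre,limit_post speed limits in mph, each in `{20, 30, 40}`.
#' @param street_class `"local"`, `"main"` or `"other"`; only consulted for
#'   30-to-20 conversions.
#' @return factor with levels
#'   `existing20, changed20_local, changed20_main, stay30, other`.
#' @examples
#' derive_segment_category(20, 20, "local")  # existing20
#' derive_segment_category(30, 20, "main")   # changed20_main
#' @export
derive_segment_category <- function(limit_pre, limit_post, street_class) {
  n <- max(length(limit_pre), length(limit_post), length(street_class))
  limit_pre <- rep_len(limit_pre, n)
  limit_post <- rep_len(limit_post, n)
  street_class <- rep_len(as.character(street_class), n)
  out <- rep("other", n)
  out[limit_pre == 20 & limit_post == 20] <- "existing20"
  out[limit_pre == 30 & limit_post == 30] <- "stay30"
  conv <- limit_pre == 30 & limit_post == 20
  out[conv & street_class == "local"] <- "changed20_local"
  out[conv & street_class == "main"] <- "changed20_main"
  out[conv & !street_class %in% c("local", "main")] <- "other"
  factor(out, levels = SEGMENT_CATEGORIES)
}

validate_network <- function(net) {
  stopifnot(is.data.frame(net),
            all(c("id", "vertices", "limit_pre", "limit_post",
                  "street_class") %in% names(net)))
  for (i in seq_len(nrow(net))) {
    v <- net$vertices[[i]]
    if (!is.matrix(v) || ncol(v) != 2L || nrow(v) < 2L) {
      stop("segment '", net$id[i], "': vertices must be an n x 2 matrix, n >= 2",
           call. = FALSE)
    }
    if (all(v[, 1] == v[1, 1]) && all(v[, 2] == v[1, 2])) {
      stop("segment '", net$id[i], "': all vertices identical", call. = FALSE)
    }
  }
  ok_lim <- net$limit_pre %in% c(20, 30, 40) & net$limit_post %in% c(20, 30, 40)
  if (!all(ok_lim)) {
    stop("segment '", net$id[which(!ok_lim)[1]],
         "': speed limits must be in {20, 30, 40}", call. = FALSE)
  }
  if (!all(net$street_class %in% STREET_CLASSES)) {
    stop("street_class must be one of ", paste(STREET_CLASSES, collapse = "/"),
         call. = FALSE)
  }
  net$category <- derive_segment_category(net$limit_pre, net$limit_post,
                                          net$street_class)
  net
}

#' Read a road network from GeoJSON
#'
#' Expects a FeatureCollection of LineString features with properties
#' `id`, `limit_pre`, `limit_post`, `street_class`. Coordinates are kept
#' exactly as stored (planar metres). A `category` column is derived via
#' [derive_segment_category()].
#'
#' @param path path to a GeoJSON file.
#' @return tibble with columns `id`, `vertices` (list of n x 2 matrices),
#'   `limit_pre`, `limit_post`, `street_class`, `category`.
#' @export
read_network <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  rows <- lapply(feats, function(f) {
    if (!identical(f$geometry$type, "LineString")) {
      stop("feature '", f$properties$id %||% "<no id>",
           "': expected LineString geometry, got ", f$geometry$type,
           call. = FALSE)
    }
    coords <- do.call(rbind, lapply(f$geometry$coordinates, function(p) {
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))
    }))
    p <- f$properties
    list(id = as.character(p$id), vertices = coords,
         limit_pre = as.numeric(p$limit_pre),
         limit_post = as.numeric(p$limit_post),
         street_class = as.character(p$street_class))
  })
  net <- tibble::tibble(
    id = vapply(rows, `[[`, character(1), "id"),
    vertices = lapply(rows, `[[`, "vertices"),
    limit_pre = vapply(rows, `[[`, numeric(1), "limit_pre"),
    limit_post = vapply(rows, `[[`, numeric(1), "limit_post"),
    street_class = vapply(rows, `[[`, character(1), "street_class")
  )
  validate_network(net)
}

#' Write a road network to GeoJSON
#' @param net network tibble (see [read_network()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  feats <- lapply(seq_len(nrow(net)), function(i) {
    v <- net$vertices[[i]]
    list(
      type = "Feature",
      properties = list(id = net$id[i],
                        limit_pre = net$limit_pre[i],
                        limit_post = net$limit_post[i],
                        street_class = net$street_class[i]),
      geometry = list(type = "LineString",
                      coordinates = lapply(seq_len(nrow(v)),
                                           function(j) as.list(v[j, ])))
    )
  })
  write_geojson(feats, path)
}

close_ring <- function(m) {
  # convention: rings are stored explicitly closed (first vertex repeated
  # as last); unclosed input rings are auto-closed.
  if (!all(m[1, ] == m[nrow(m), ])) m <- rbind(m, m[1, ])
  m
}

validate_zones <- function(zones) {
  stopifnot(all(c("id", "rings", "role", "pair_id",
                  "intervention_date") %in% names(zones)))
  if (!all(zones$role %in% ZONE_ROLES)) {
    stop("zone role must be one of ", paste(ZONE_ROLES, collapse = "/"),
         call. = FALSE)
  }
  impl <- zones$role == "implementation"
  if (anyNA(zones$intervention_date[impl])) {
    stop("implementation zone '", zones$id[impl & is.na(zones$intervention_date)][1],
         "' is missing its intervention_date", call. = FALSE)
  }
  if (any(!is.na(zones$intervention_date[!impl]))) {
    stop("control zone '",
         zones$id[!impl & !is.na(zones$intervention_date)][1],
         "' must not carry an intervention_date", call. = FALSE)
  }
  zones$rings <- lapply(zones$rings, function(rr) lapply(rr, close_ring))
  zones
}

#' Read implementation/control zones from GeoJSON
#'
#' Expects a FeatureCollection of Polygon features with properties `id`,
#' `role` (`implementation` or `control`), `pair_id`, and (implementation
#' zones only) `intervention_date`. Unclosed rings are auto-closed; a
#' control zone carrying an intervention date is a validation error.
#'
#' @param path path to a GeoJSON file.
#' @return tibble with columns `id`, `rings` (list; each element a list of
#'   closed n x 2 ring matrices, outer ring first), `role`, `pair_id`,
#'   `intervention_date` (Date, `NA` for control zones).
#' @export
read_zones <- function(path) {
  gj <- jsonlite::read_json(path)
  rows <- lapply(gj$features, function(f) {
    if (!identical(f$geometry$type, "Polygon")) {
      stop("feature '", f$properties$id %||% "<no id>",
           "': expected Polygon geometry, got ", f$geometry$type,
           call. = FALSE)
    }
    rings <- lapply(f$geometry$coordinates, function(ring) {
      do.call(rbind, lapply(ring, function(p) {
        c(as.numeric(p[[1]]), as.numeric(p[[2]]))
      }))
    })
    p <- f$properties
    list(id = as.character(p$id), rings = rings,
         role = as.character(p$role), pair_id = as.character(p$pair_id),
         intervention_date = if (is.null(p$intervention_date)) as.Date(NA)
                             else as.Date(p$intervention_date))
  })
  zones <- tibble::tibble(
    id = vapply(rows, `[[`, character(1), "id"),
    rings = lapply(rows, `[[`, "rings"),
    role = vapply(rows, `[[`, character(1), "role"),
    pair_id = vapply(rows, `[[`, character(1), "pair_id"),
    intervention_date = as.Date(vapply(rows, function(r)
      as.character(r$intervention_date), character(1)))
  )
  validate_zones(zones)
}

#' Write zones to GeoJSON
#' @param zones zone tibble (see [read_zones()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_zones <- function(zones, path) {
  feats <- lapply(seq_len(nrow(zones)), function(i) {
    props <- list(id = zones$id[i], role = zones$role[i],
                  pair_id = zones$pair_id[i])
    if (!is.na(zones$intervention_date[i])) {
      props$intervention_date <- format(zones$intervention_date[i], "%Y-%m-%d")
    }
    list(
      type = "Feature",
      properties = props,
      geometry = list(type = "Polygon",
                      coordinates = lapply(zones$rings[[i]], function(m)
                        lapply(seq_len(nrow(m)), function(j) as.list(m[j, ]))))
    )
  })
  write_geojson(feats, path)
}

write_geojson <- function(features, path) {
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' Read per-zone speed and volume summaries
#'
#' CSV with columns `zone_id, speed_unit, mean_speed_pre, mean_speed_post,
#' volume_pre, volume_post`. `speed_unit` must be `mph` or `kmh`, constant
#' across rows, and declared explicitly — it is never guessed.
#'
#' @param path path to a CSV file.
#' @return tibble of per-zone traffic summaries with a `speed_unit` column.
#' @export
read_zone_traffic <- function(path) {
  x <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  req <- c("zone_id", "speed_unit", "mean_speed_pre", "mean_speed_post",
           "volume_pre", "volume_post")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols)) {
    stop("zone traffic file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(x$speed_unit %in% c("mph", "kmh"))) {
    stop("speed_unit must be 'mph' or 'kmh'", call. = FALSE)
  }
  if (length(unique(x$speed_unit)) > 1L) {
    stop("speed_unit must be constant across rows", call. = FALSE)
  }
  if (any(x$mean_speed_pre <= 0 | x$mean_speed_post <= 0)) {
    stop("speeds must be positive", call. = FALSE)
  }
  if (any(x$volume_pre < 0 | x$volume_post < 0)) {
    stop("volumes must be non-negative", call. = FALSE)
  }
  x$zone_id <- as.character(x$zone_id)
  x
}

#' Write per-zone traffic summaries to CSV
#' @param x zone traffic tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_zone_traffic <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Define a pre/post study window
#'
#' Exposure in years is the exact day count divided by 365.25 (both
#' endpoints inclusive), with optional explicit overrides so that nominal
#' exposures such as 3.0 and 1.83 years can be forced when reproducing a
#' published table.
#'
#' @param pre_start,pre_end,post_start,post_end calendar dates
#'   (coerced via `as.Date`); `pre_end` must not be after `post_start`.
#' @param pre_years,post_years optional explicit exposures (years)
#'   overriding the day-count computation.
#' @return object of class `study_window` with elements `pre_start`,
#'   `pre_end`, `post_start`, `post_end`, `pre_years`, `post_years`.
#' @export
study_window <- function(pre_start, pre_end, post_start, post_end,
                         pre_years = NULL, post_years = NULL) {
  pre_start <- as.Date(pre_start); pre_end <- as.Date(pre_end)
  post_start <- as.Date(post_start); post_end <- as.Date(post_end)
  stopifnot(pre_start <= pre_end, post_start <= post_end)
  if (pre_end > post_start) {
    stop("pre period must end on or before the post period starts",
         call. = FALSE)
  }
  days_years <- function(a, b) as.numeric(b - a + 1L) / 365.25
  w <- list(pre_start = pre_start, pre_end = pre_end,
            post_start = post_start, post_end = post_end,
            pre_years = if (is.null(pre_years)) days_years(pre_start, pre_end)
                        else pre_years,
            post_years = if (is.null(post_years)) days_years(post_start, post_end)
                         else post_years)
  structure(w, class = "study_window")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
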