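#' Assemble a pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: either a [sim_config()] (the
#' inputs are then generated) or paths to collision/network/zone files,
#' the study window for the segment analysis, per-pair zone windows
#' (derived from each zone's intervention date when omitted), the
#' time-series model spec, the exponential-model parameters, and the
#' snapping threshold.
#'
#' @param sim optional [sim_config()]; when supplied the input files are
#'   generated into the output directory.
#' @param collisions,network,zones input file paths (ignored when `sim`
#'   is given).
#' @param window [study_window()] for the segment analysis; defaults to
#'   the simulated study period when `sim` is given.
#' @param zone_windows named list of [study_window()] per pair id, or
#'   `NULL` to derive each pair's windows from its implementation zone's
#'   intervention date.
#' @param its_spec [its_model_spec()].
#' @param elvik [elvik_params()].
#' @param traffic optional zone traffic tibble (see
#'   [read_zone_traffic()]); when `NULL` under simulation, a default table
#'   with a 1.3 mph mean-speed drop and a 2% volume drop is fabricated
#'   for the implementation zones.
#' @param max_dist snapping threshold in metres.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, collisions = NULL, network = NULL,
                            zones = NULL, window = NULL, zone_windows = NULL,
                            its_spec = its_model_spec(),
                            elvik = elvik_params(), traffic = NULL,
                            max_dist = 12) {
  if (is.null(sim) && (is.null(collisions) || is.null(network) ||
                       is.null(zones))) {
    stop("either a sim config or all three input paths must be supplied",
         call. = FALSE)
  }
  structure(list(sim = sim, collisions = collisions, network = network,
                 zones = zones, window = window, zone_windows = zone_windows,
                 its_spec = its_spec, elvik = elvik, traffic = traffic,
                 max_dist = max_dist),
            class = "pipeline_config")
}

# FNV-1a over the config's JSON serialization: a plain content
# fingerprint for the run manifest, not a cryptographic hash
fnv1a <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor on the low byte only (b < 256), keeping h a plain double
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)
    # 32-bit modular multiply in two 16-bit halves to stay within 2^53
    h <- (((h %/% 65536) * p) %% 65536) * 65536 + (h %% 65536) * p
    h <- h %% 4294967296
  }
  sprintf("%08x", h)
}

default_zone_windows <- function(zones, start_date, end_date) {
  impl <- zones[zones$role == "implementation", ]
  w <- lapply(seq_len(nrow(impl)), function(i) {
    iv <- impl$intervention_date[i]
    study_window(start_date, iv - 1L, iv, end_date)
  })
  setNames(w, impl$pair_id)
}

default_traffic <- function(zones) {
  impl_ids <- zones$id[zones$role == "implementation"]
  tibble::tibble(zone_id = impl_ids, speed_unit = "mph",
                 mean_speed_pre = 23.63, mean_speed_post = 22.29,
                 volume_pre = 3641, volume_post = 3555)
}

#' Run the full evaluation pipeline
#'
#' Stages: `simulate` (or load), `snap`, `segments`, `zones`, `its`,
#' `elvik`. Emits `matches.csv`, `table1.csv`/`.json`,
#' `table2.csv`/`.json`, `its.json`, `elvik.json` and a `manifest.json`
#' recording the package version, seed, stage list and a config
#' fingerprint. A stage failure is re-raised naming the stage, and any
#' files that stage had already written are renamed with a `.partial`
#' suffix.
#'
#' @param config [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(name) file.path(out_dir, name)
  stage_outputs <- character(0)
  run_stage <- function(name, outputs, expr) {
    stage_outputs <<- outfile(outputs)
    tryCatch(expr, error = function(e) {
      for (f in stage_outputs) {
        if (file.exists(f)) file.rename(f, paste0(f, ".partial"))
      }
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  res <- list()

  res$inputs <- run_stage("simulate", c("collisions.csv", "network.geojson",
                                        "zones.geojson", "truth.csv",
                                        "traffic.csv"), {
    if (!is.null(config$sim)) {
      nz <- make_network(config$sim)
      sim <- simulate_collisions(config$sim, nz$network, nz$zones)
      write_collisions(sim$collisions, outfile("collisions.csv"))
      write_network(nz$network, outfile("network.geojson"))
      write_zones(nz$zones, outfile("zones.geojson"))
      write.csv(as.data.frame(sim$truth), outfile("truth.csv"),
                row.names = FALSE, quote = FALSE)
      traffic <- config$traffic %||% default_traffic(nz$zones)
      write_zone_traffic(traffic, outfile("traffic.csv"))
      list(collisions = sim$collisions, network = nz$network,
           zones = nz$zones, truth = sim$truth, traffic = traffic)
    } else {
      list(collisions = read_collisions(config$collisions),
           network = read_network(config$network),
           zones = read_zones(config$zones),
           truth = NULL,
           traffic = config$traffic)
    }
  })
  inputs <- res$inputs

  window <- config$window
  if (is.null(window) && !is.null(config$sim)) {
    s <- config$sim
    months <- seq(floor_month(s$start_date), by = "1 month",
                  length.out = s$months_pre + s$months_post + 1L)
    iv <- min(s$intervention_date)
    window <- study_window(s$start_date, iv - 1L, iv,
                           months[length(months)] - 1L)
  }
  if (is.null(window)) {
    stop("stage 'segments' failed: no study window configured",
         call. = FALSE)
  }

  res$matches <- run_stage("snap", "matches.csv", {
    m <- snap_collisions(inputs$collisions, inputs$network,
                         max_dist = config$max_dist, zones = inputs$zones)
    write_matches(m, outfile("matches.csv"))
    m
  })

  res$table1 <- run_stage("segments", c("table1.csv", "table1.json"), {
    t1 <- segment_table(inputs$collisions, res$matches, inputs$network,
                        window)
    write.csv(as.data.frame(t1), outfile("table1.csv"), row.names = FALSE)
    jsonlite::write_json(t1, outfile("table1.json"), auto_unbox = TRUE,
                         digits = NA, na = "null")
    t1
  })

  res$table2 <- run_stage("zones", c("table2.csv", "table2.json"), {
    zw <- config$zone_windows %||%
      default_zone_windows(inputs$zones, window$pre_start, window$post_end)
    t2 <- zone_table(inputs$collisions, res$matches, inputs$zones, zw)
    write.csv(as.data.frame(t2), outfile("table2.csv"), row.names = FALSE)
    jsonlite::write_json(t2, outfile("table2.json"), auto_unbox = TRUE,
                         digits = NA, na = "null")
    t2
  })

  res$its <- run_stage("its", "its.json", {
    iv <- window$post_start
    series <- aggregate_monthly(inputs$collisions, window$pre_start,
                                window$post_end, iv, mode = "casualties")
    fit <- fit_pre_model(series, config$its_spec)
    post <- series[series$is_post, , drop = FALSE]
    cf <- predict_counterfactual(fit, post)
    cmp <- compare_annualized(cf, post, window$post_years)
    out <- list(dispersion = fit$dispersion,
                smoothing_criterion = fit$smoothing_criterion,
                n_pre = fit$n_pre, n_post = nrow(post),
                predicted = cmp$predicted, observed = cmp$observed,
                difference = cmp$difference, percent = cmp$percent)
    jsonlite::write_json(out, outfile("its.json"), auto_unbox = TRUE,
                         digits = NA)
    list(series = series, fit = fit, counterfactual = cf, comparison = cmp)
  })

  res$elvik <- run_stage("elvik", "elvik.json", {
    traffic <- inputs$traffic
    if (is.null(traffic)) {
      stop("no zone traffic data configured", call. = FALSE)
    }
    # before-rates per implementation zone and severity, from matched
    # pre-period collisions (collision severity = worst casualty)
    m <- merge(as.data.frame(res$matches), as.data.frame(inputs$collisions),
               by.x = "collision_id", by.y = "id")
    impl_ids <- inputs$zones$id[inputs$zones$role == "implementation"]
    m <- m[!is.na(m$zone_id) & m$zone_id %in% impl_ids &
             m$date >= window$pre_start & m$date <= window$pre_end, ]
    sev_map <- c(slight = "injury", serious = "serious", fatal = "fatal")
    grid <- expand.grid(zone_id = impl_ids,
                        severity = c("injury", "serious", "fatal"),
                        stringsAsFactors = FALSE)
    grid$rate_before <- mapply(function(z, s) {
      sum(sev_map[as.character(m$severity)] == s & m$zone_id == z) /
        window$pre_years
    }, grid$zone_id, grid$severity)
    params <- config$elvik
    pred <- predict_by_zone(traffic, grid, params)
    jsonlite::write_json(pred, outfile("elvik.json"), auto_unbox = TRUE,
                         digits = NA)
    pred
  })

  manifest <- list(
    package = "calmstreets",
    version = as.character(utils::packageVersion("calmstreets")),
    seed = if (!is.null(config$sim)) config$sim$seed else NA,
    stages = c("simulate", "snap", "segments", "zones", "its", "elvik"),
    config_hash = fnv1a(as.character(jsonlite::serializeJSON(config)))
  )
  jsonlite::write_json(manifest, outfile("manifest.json"), auto_unbox = TRUE)
  invisible(res)
}
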