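#' Minimum distance from a point to a polyline
#'
#' Euclidean distance on the planar (metre) grid from point `p` to the
#' union of the closed line segments joining consecutive polyline vertices.
#' Exact for both the perpendicular-foot case and the endpoint case (foot
#' of the perpendicular falling outside the segment).
#'
#' @param p numeric length-2 vector `(easting, northing)`.
#' @param vertices n x 2 matrix of polyline vertices, `n >= 2`.
#' @return distance in metres (>= 0).
#' @export
point_polyline_distance <- function(p, vertices) {
  if (!is.matrix(vertices) || nrow(vertices) < 2L || ncol(vertices) != 2L) {
    stop("polyline must be an n x 2 matrix with n >= 2", call. = FALSE)
  }
  min(point_edges_distance(p[1], p[2],
                           vertices[-nrow(vertices), 1, drop = TRUE],
                           vertices[-nrow(vertices), 2, drop = TRUE],
                           vertices[-1, 1, drop = TRUE],
                           vertices[-1, 2, drop = TRUE]))
}

# vectorized distance from one point to many edges (x1,y1)-(x2,y2);
# degenerate zero-length edges fall back to point distance.
point_edges_distance <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  t <- ifelse(len2 > 0, ((px - x1) * dx + (py - y1) * dy) / len2, 0)
  t <- pmin(pmax(t, 0), 1)
  fx <- x1 + t * dx; fy <- y1 + t * dy
  sqrt((px - fx)^2 + (py - fy)^2)
}

# flatten a network's polylines into one edge table
network_edges <- function(network) {
  parts <- lapply(seq_len(nrow(network)), function(i) {
    v <- network$vertices[[i]]
    n <- nrow(v)
    cbind(x1 = v[-n, 1], y1 = v[-n, 2], x2 = v[-1, 1], y2 = v[-1, 2],
          seg = i)
  })
  do.call(rbind, parts)
}

#' Snap collisions to their nearest road segment
#'
#' Assigns each collision to the road segment minimizing the
#' point-to-polyline distance, provided that distance is at most
#' `max_dist` metres (inclusive comparison); otherwise the collision is
#' left unmatched. Ties within 1e-9 m are broken deterministically in
#' favour of the lexicographically smallest segment id. If `zones` is
#' supplied, each collision is also assigned to its containing zone via
#' [assign_zone()].
#'
#' @param collisions collision tibble (see [read_collisions()]).
#' @param network network tibble (see [read_network()]).
#' @param max_dist snapping threshold in metres (default 12).
#' @param zones optional zone tibble for zone assignment.
#' @param method `"grid"` (uniform-grid spatial index, the default) or
#'   `"brute"` (all-pairs scan). The two are guaranteed to produce
#'   identical assignments; the index only prunes edges that cannot be
#'   within `max_dist`.
#' @return tibble with columns `collision_id`, `segment_id` (NA when
#'   unmatched), `distance` (metres, NA when unmatched), `zone_id` (NA
#'   when outside all zones or when `zones` is not supplied).
#' @export
snap_collisions <- function(collisions, network, max_dist = 12,
                            zones = NULL, method = c("grid", "brute")) {
  method <- match.arg(method)
  if (nrow(network) == 0L) stop("network is empty", call. = FALSE)
  edges <- network_edges(network)
  n <- nrow(collisions)
  seg_id <- rep(NA_character_, n)
  dist_m <- rep(NA_real_, n)

  if (method == "grid") {
    cell <- max(4 * max_dist, 1)
    # each edge is registered in every cell its bounding box (expanded by
    # max_dist) overlaps, so a point can only match edges in its own cell
    ex_lo_x <- floor((pmin(edges[, "x1"], edges[, "x2"]) - max_dist) / cell)
    ex_hi_x <- floor((pmax(edges[, "x1"], edges[, "x2"]) + max_dist) / cell)
    ex_lo_y <- floor((pmin(edges[, "y1"], edges[, "y2"]) - max_dist) / cell)
    ex_hi_y <- floor((pmax(edges[, "y1"], edges[, "y2"]) + max_dist) / cell)
    index <- new.env(parent = emptyenv())
    for (e in seq_len(nrow(edges))) {
      for (cx in ex_lo_x[e]:ex_hi_x[e]) {
        for (cy in ex_lo_y[e]:ex_hi_y[e]) {
          key <- paste(cx, cy)
          index[[key]] <- c(index[[key]], e)
        }
      }
    }
    pcx <- floor(collisions$easting / cell)
    pcy <- floor(collisions$northing / cell)
    keys <- paste(pcx, pcy)
    for (i in seq_len(n)) {
      cand <- index[[keys[i]]]
      if (is.null(cand)) next
      res <- best_segment(collisions$easting[i], collisions$northing[i],
                          edges[cand, , drop = FALSE], network$id, max_dist)
      seg_id[i] <- res$id; dist_m[i] <- res$dist
    }
  } else {
    for (i in seq_len(n)) {
      res <- best_segment(collisions$easting[i], collisions$northing[i],
                          edges, network$id, max_dist)
      seg_id[i] <- res$id; dist_m[i] <- res$dist
    }
  }

  zone_id <- rep(NA_character_, n)
  if (!is.null(zones)) {
    zone_id <- assign_zone(cbind(collisions$easting, collisions$northing),
                           zones)
  }
  tibble::tibble(collision_id = collisions$id, segment_id = seg_id,
                 distance = dist_m, zone_id = zone_id)
}

best_segment <- function(px, py, edges, seg_ids, max_dist) {
  d <- point_edges_distance(px, py, edges[, "x1"], edges[, "y1"],
                            edges[, "x2"], edges[, "y2"])
  # per-segment minimum (a polyline contributes several edges)
  dmin <- tapply(d, edges[, "seg"], min)
  best <- min(dmin)
  if (best > max_dist) return(list(id = NA_character_, dist = NA_real_))
  tied <- as.integer(names(dmin)[dmin <= best + 1e-9])
  list(id = min(seg_ids[tied]), dist = best)
}

ring_area <- function(m) {
  n <- nrow(m)
  abs(sum(m[-n, 1] * m[-1, 2] - m[-1, 1] * m[-n, 2])) / 2
}

zone_area <- function(rings) {
  # outer ring minus holes (even-odd convention)
  a <- vapply(rings, ring_area, numeric(1))
  if (length(a) == 1L) a else a[1] - sum(a[-1])
}

# even-odd (ray casting) containment with boundary points counting inside
point_in_rings <- function(px, py, rings, eps = 1e-9) {
  inside <- FALSE
  for (m in rings) {
    # boundary test: distance to the ring polyline
    if (min(point_edges_distance(px, py,
                                 m[-nrow(m), 1], m[-nrow(m), 2],
                                 m[-1, 1], m[-1, 2])) <= eps) return(TRUE)
    n <- nrow(m) - 1L
    j <- n
    for (i in seq_len(n)) {
      yi <- m[i, 2]; yj <- m[j, 2]
      if ((yi > py) != (yj > py)) {
        xint <- m[i, 1] + (py - yi) / (yj - yi) * (m[j, 1] - m[i, 1])
        if (px < xint) inside <- !inside
      }
      j <- i
    }
  }
  inside
}

#' Assign points to containing zones
#'
#' Even-odd (ray-casting) point-in-polygon test; points exactly on a zone
#' boundary count as inside. When a point falls inside several overlapping
#' zones, the zone with the smallest area wins (a deterministic tie-break).
#'
#' @param points numeric length-2 vector or n x 2 matrix of
#'   `(easting, northing)` coordinates.
#' @param zones zone tibble (see [read_zones()]).
#' @return character vector of zone ids (`NA` where no zone contains the
#'   point).
#' @export
assign_zone <- function(points, zones) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  areas <- vapply(zones$rings, zone_area, numeric(1))
  ord <- order(areas, zones$id)  # smallest area first, id breaks exact ties
  # cheap bbox prefilter per zone
  bbox <- t(vapply(zones$rings, function(rr) {
    m <- rr[[1]]
    c(min(m[, 1]), max(m[, 1]), min(m[, 2]), max(m[, 2]))
  }, numeric(4)))
  out <- rep(NA_character_, nrow(points))
  eps <- 1e-9
  for (i in seq_len(nrow(points))) {
    px <- points[i, 1]; py <- points[i, 2]
    for (z in ord) {
      if (px < bbox[z, 1] - eps || px > bbox[z, 2] + eps ||
          py < bbox[z, 3] - eps || py > bbox[z, 4] + eps) next
      if (point_in_rings(px, py, zones$rings[[z]], eps)) {
        out[i] <- zones$id[z]
        break
      }
    }
  }
  out
}

#' Write snap results to CSV
#'
#' Columns `collision_id, segment_id, distance_m, zone_id`, with empty
#' fields for unmatched collisions.
#'
#' @param matches tibble from [snap_collisions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matches <- function(matches, path) {
  out <- data.frame(
    collision_id = matches$collision_id,
    segment_id = ifelse(is.na(matches$segment_id), "", matches$segment_id),
    distance_m = ifelse(is.na(matches$distance), "",
                        format(matches$distance, digits = 10, trim = TRUE)),
    zone_id = ifelse(is.na(matches$zone_id), "", matches$zone_id)
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
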