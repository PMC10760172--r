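# Spatial thinning: enforce a minimum pairwise distance between retained
# occurrence records, keeping as many as the greedy heuristic allows.

#' Spatial thinning configuration
#'
#' @param min_distance Minimum pairwise distance between retained points, km
#'   (> 0).  Default 0.5 km.
#' @param n_repeats Number of randomized greedy repeats; the largest retained
#'   set wins (>= 1).
#' @param seed Integer seed for the random tie-breaks.
#' @param metric `"auto"` (haversine for lon/lat tables, Euclidean for
#'   planar km tables), `"haversine"` or `"euclidean"`.
#' @param method `"distance"` (default; remove-max-conflict greedy) or
#'   `"grid"` (keep one random point per `min_distance` grid cell).
#' @return A `thin_config` object.
#' @export
thin_config <- function(min_distance = 0.5, n_repeats = 10, seed = 1,
                        metric = c("auto", "haversine", "euclidean"),
                        method = c("distance", "grid")) {
  if (min_distance <= 0) stop("`min_distance` must be > 0", call. = FALSE)
  assert_count(n_repeats, "n_repeats")
  structure(list(min_distance = min_distance,
                 n_repeats = as.integer(n_repeats), seed = seed,
                 metric = match.arg(metric), method = match.arg(method)),
            class = "thin_config")
}

# One randomized greedy pass: while any pair conflicts, drop a point with the
# maximal number of conflicting neighbours (random tie-break).
.thin_once <- function(conflicts) {
  keep <- rep(TRUE, nrow(conflicts))
  deg <- rowSums(conflicts)
  while (any(deg[keep] > 0)) {
    cand <- which(keep & deg == max(deg[keep]))
    drop <- if (length(cand) > 1L) cand[sample.int(length(cand), 1L)] else cand
    keep[drop] <- FALSE
    nb <- which(conflicts[drop, ] & keep)
    deg[nb] <- deg[nb] - 1L
    deg[drop] <- 0L
  }
  which(keep)
}

#' Thin occurrence records to a minimum pairwise distance
#'
#' Distance-based thinning: repeats a randomized greedy conflict-removal
#' `n_repeats` times and returns the largest retained set (first found on
#' ties).  Every retained pair is guaranteed to be at least `min_distance`
#' apart.  The `"grid"` method instead snaps points to a `min_distance` grid
#' and keeps one random point per occupied cell (faster, smaller sets, and
#' same-cell neighbours can still be closer than `min_distance` across cell
#' borders — provided for comparability with grid-based thinning tools).
#'
#' @param table An [occurrence_table()] (>= 1 row).
#' @param config A [thin_config()].
#' @return The thinned [occurrence_table()].
#' @export
thin_spatial <- function(table, config = thin_config()) {
  stopifnot(inherits(table, "occurrence_table"),
            inherits(config, "thin_config"))
  n <- nrow(table)
  if (n == 0) stop("cannot thin an empty table", call. = FALSE)
  if (n == 1) return(table)
  metric <- resolve_metric(config$metric, occ_coord_system(table))
  with_rng_seed(config$seed, {
    if (config$method == "grid") {
      if (metric == "euclidean") {
        gx <- floor(table$longitude / config$min_distance)
        gy <- floor(table$latitude / config$min_distance)
      } else {
        # degree-grid approximation at the table's mean latitude
        km_per_deg_lat <- pi * EARTH_RADIUS_KM / 180
        km_per_deg_lon <- km_per_deg_lat * cos(mean(table$latitude) * pi / 180)
        gx <- floor(table$longitude * km_per_deg_lon / config$min_distance)
        gy <- floor(table$latitude * km_per_deg_lat / config$min_distance)
      }
      keep <- vapply(split(seq_len(n), paste(gx, gy)),
                     function(i) if (length(i) == 1L) i
                                 else i[sample.int(length(i), 1L)],
                     integer(1))
      return(occ_rebuild(table[sort(unname(keep)), , drop = FALSE], table))
    }
    d <- pairwise_distances_km(table$longitude, table$latitude, metric)
    conflicts <- d < config$min_distance
    diag(conflicts) <- FALSE
    if (!any(conflicts)) return(table)
    best <- integer()
    for (r in seq_len(config$n_repeats)) {
      kept <- .thin_once(conflicts)
      if (length(kept) > length(best)) best <- kept
    }
    occ_rebuild(table[best, , drop = FALSE], table)
  })
}
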