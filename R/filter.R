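# Checklist-quality filtering of occurrence records.

#' Occurrence filter configuration
#'
#' Defaults follow standard eBird best-practice effort filters for breeding
#' season gull records: Stationary/Traveling protocols only, duration
#' strictly under 360 minutes, distance traveled strictly under 10 km, start
#' time within 06:00–21:00 (inclusive), at most 10 observers, complete
#' checklists only, June–July, 2010–2023, and the north-east Pacific study
#' extent 175°W–114°W, 31°N–62°N.
#'
#' @param allowed_protocols Character set of accepted protocols.
#' @param max_duration Exclusive upper bound on duration (minutes).
#' @param max_distance Exclusive upper bound on distance traveled (km).
#' @param time_window Inclusive `c(start, end)` clock times, \"HH:MM\".
#' @param max_observers Inclusive upper bound on observer count.
#' @param require_complete Keep only complete checklists?
#' @param months Accepted calendar months (subset of 1..12).
#' @param year_range Inclusive `c(first, last)` years.
#' @param bbox `c(lon_min, lon_max, lat_min, lat_max)` or `NULL` to skip.
#' @return A `filter_config` object.
#' @export
filter_config <- function(allowed_protocols = c("Stationary", "Traveling"),
                          max_duration = 360,
                          max_distance = 10,
                          time_window = c("06:00", "21:00"),
                          max_observers = 10,
                          require_complete = TRUE,
                          months = c(6, 7),
                          year_range = c(2010, 2023),
                          bbox = c(-175, -114, 31, 62)) {
  if (!all(months %in% 1:12)) stop("`months` must lie in 1..12", call. = FALSE)
  if (length(year_range) != 2L || year_range[1] > year_range[2])
    stop("`year_range` must be ordered c(first, last)", call. = FALSE)
  if (!is.null(bbox)) {
    if (length(bbox) != 4L || bbox[1] > bbox[2] || bbox[3] > bbox[4])
      stop("`bbox` must be c(lon_min, lon_max, lat_min, lat_max), ordered",
           call. = FALSE)
  }
  tw <- parse_clock_minutes(time_window)
  if (anyNA(tw) || tw[1] > tw[2])
    stop("`time_window` must be ordered \"HH:MM\" times", call. = FALSE)
  structure(list(allowed_protocols = allowed_protocols,
                 max_duration = max_duration, max_distance = max_distance,
                 time_window = time_window, max_observers = max_observers,
                 require_complete = require_complete, months = months,
                 year_range = year_range, bbox = bbox),
            class = "filter_config")
}

# Fixed criterion order for first-failure attribution (affects the rejection
# counts only, never the retained set).
FILTER_CRITERIA <- c("protocol", "duration", "distance", "time", "observers",
                     "complete", "month", "year", "bbox")

#' Filter occurrence records by checklist criteria
#'
#' Retains rows satisfying every criterion; each dropped row is attributed to
#' its first failed criterion in the fixed order protocol, duration,
#' distance, time, observers, completeness, month, year, bbox.
#'
#' Bounds follow the criteria as printed: duration and distance are strict
#' (`< 360`, `< 10`), observers inclusive (`<= 10`), the time window
#' inclusive on both ends.
#'
#' @param table An [occurrence_table()] carrying the metadata columns.
#' @param config A [filter_config()].
#' @return The retained [occurrence_table()]; attribute `rejections` is a
#'   named integer vector of first-failure counts per criterion.
#' @export
filter_records <- function(table, config = filter_config()) {
  stopifnot(inherits(table, "occurrence_table"),
            inherits(config, "filter_config"))
  needed <- c(OCC_META_COLS, "longitude", "latitude")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols))
    stop("missing metadata column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  tw <- parse_clock_minutes(config$time_window)
  tmin <- parse_clock_minutes(table$start_time)
  yr <- as.integer(substr(table$date, 1, 4))
  mo <- as.integer(substr(table$date, 6, 7))
  fails <- list(
    protocol = !(table$protocol %in% config$allowed_protocols),
    duration = !(table$duration_minutes < config$max_duration),
    distance = !(table$effort_distance_km < config$max_distance),
    time = is.na(tmin) | tmin < tw[1] | tmin > tw[2],
    observers = !(table$n_observers <= config$max_observers),
    complete = if (config$require_complete) !table$complete
               else rep(FALSE, nrow(table)),
    month = !(mo %in% config$months),
    year = is.na(yr) | yr < config$year_range[1] | yr > config$year_range[2],
    bbox = if (is.null(config$bbox)) rep(FALSE, nrow(table)) else {
      b <- config$bbox
      table$longitude < b[1] | table$longitude > b[2] |
        table$latitude < b[3] | table$latitude > b[4]
    })
  fail_mat <- do.call(cbind, fails[FILTER_CRITERIA])
  fail_mat[is.na(fail_mat)] <- TRUE
  any_fail <- rowSums(fail_mat) > 0
  first_fail <- apply(fail_mat[any_fail, , drop = FALSE], 1, which.max)
  rejections <- stats::setNames(
    vapply(seq_along(FILTER_CRITERIA),
           function(k) sum(first_fail == k), integer(1)),
    FILTER_CRITERIA)
  out <- occ_rebuild(table[!any_fail, , drop = FALSE], table)
  attr(out, "rejections") <- rejections
  out
}
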