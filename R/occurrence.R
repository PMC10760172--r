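# The occurrence table: point records with a group label and eBird-style
# checklist metadata; the unit flowing through filtering / thinning /
# balancing.

OCC_CORE_COLS <- c("id", "longitude", "latitude", "group")
OCC_META_COLS <- c("protocol", "duration_minutes", "effort_distance_km",
                   "start_time", "n_observers", "complete", "date")

#' Construct / validate an occurrence table
#'
#' @param df A data.frame with at least columns `id`, `longitude`,
#'   `latitude`, `group`; optionally the checklist metadata columns
#'   `protocol`, `duration_minutes`, `effort_distance_km`, `start_time`
#'   (\"HH:MM\"), `n_observers`, `complete`, `date` (\"YYYY-MM-DD\").
#' @param coord_system `"lonlat"` (WGS84 degrees) or `"planar"` (km units,
#'   used by synthetic planar grids).
#' @return The validated data.frame, classed `occurrence_table`, with the
#'   coordinate system stored in attribute `coord_system`.
#' @export
occurrence_table <- function(df, coord_system = c("lonlat", "planar")) {
  coord_system <- match.arg(coord_system)
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(OCC_CORE_COLS, names(df))
  if (length(missing_cols))
    stop("missing occurrence column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$id))
    stop("occurrence ids must be unique", call. = FALSE)
  if (coord_system == "lonlat") {
    if (any(df$longitude < -180 | df$longitude > 180, na.rm = TRUE) ||
        any(df$latitude < -90 | df$latitude > 90, na.rm = TRUE))
      stop("lon/lat outside [-180, 180] x [-90, 90]", call. = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, class = c("occurrence_table", "data.frame"),
            coord_system = coord_system)
}

occ_coord_system <- function(table) attr(table, "coord_system") %||% "lonlat"

# Reclass a plain data.frame slice as an occurrence table, keeping the
# coordinate-system tag of `template`.
occ_rebuild <- function(df, template) {
  rownames(df) <- NULL
  structure(as.data.frame(df), class = c("occurrence_table", "data.frame"),
            coord_system = occ_coord_system(template))
}

#' @export
print.occurrence_table <- function(x, ...) {
  cat(sprintf("<occurrence_table> %d record(s), %d group(s) [%s]\n",
              nrow(x), length(unique(x$group)), occ_coord_system(x)))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Write an occurrence table to CSV
#'
#' @param table An [occurrence_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read an occurrence table from CSV
#'
#' @param path CSV path with the [occurrence_table()] schema.
#' @param coord_system Coordinate system of the stored coordinates.
#' @return An [occurrence_table()].
#' @export
read_occurrences <- function(path, coord_system = "lonlat") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  occurrence_table(df, coord_system = coord_system)
}

# "HH:MM" -> minutes since midnight (NA for malformed values).
parse_clock_minutes <- function(x) {
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))
  vapply(m, function(p) {
    if (length(p) != 3L) return(NA_real_)
    as.numeric(p[2]) * 60 + as.numeric(p[3])
  }, numeric(1))
}
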