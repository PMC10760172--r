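# Sample-size balancing across groups and target-group background points.

#' Balance group sample sizes
#'
#' Samples exactly `n_per_group` rows per group, uniformly without
#' replacement and independently per group.
#'
#' @param table An [occurrence_table()] with a `group` column (or a named
#'   list of per-group tables, which is row-bound first).
#' @param n_per_group Rows to keep per group (default 1500).
#' @param seed Integer seed.
#' @return A balanced [occurrence_table()].
#' @export
balance_groups <- function(table, n_per_group = 1500, seed) {
  if (is.list(table) && !is.data.frame(table)) {
    cs <- occ_coord_system(table[[1]])
    table <- occurrence_table(do.call(rbind, lapply(table, as.data.frame)),
                              coord_system = cs)
  }
  stopifnot(inherits(table, "occurrence_table"))
  assert_count(n_per_group, "n_per_group")
  counts <- table(table$group)
  short <- counts < n_per_group
  if (any(short))
    stop(sprintf("group(s) with fewer than %d rows: %s", n_per_group,
                 paste(sprintf("%s (short by %d)", names(counts)[short],
                               n_per_group - counts[short]), collapse = ", ")),
         call. = FALSE)
  with_rng_seed(seed, {
    keep <- unlist(lapply(split(seq_len(nrow(table)), table$group),
                          function(i) sort(sample(i, n_per_group))),
                   use.names = FALSE)
    occ_rebuild(table[sort(keep), , drop = FALSE], table)
  })
}

#' Draw target-group background points
#'
#' Background points are sampled uniformly without replacement from the
#' all-species occurrence table (optionally restricted to a bounding box), so
#' they carry the survey process's spatial sampling-effort signature — the
#' target-group background device for presence-background models.
#'
#' @param all_species An [occurrence_table()] of all-species records.
#' @param n Number of background points (default 10000).
#' @param bbox Optional `c(lon_min, lon_max, lat_min, lat_max)` restriction.
#' @param seed Integer seed.
#' @return A data.frame with columns `longitude`, `latitude` only.
#' @export
target_group_background <- function(all_species, n = 10000, bbox = NULL, seed) {
  stopifnot(inherits(all_species, "occurrence_table"))
  assert_count(n, "n")
  df <- as.data.frame(all_species)
  if (!is.null(bbox)) {
    b <- bbox
    df <- df[df$longitude >= b[1] & df$longitude <= b[2] &
             df$latitude >= b[3] & df$latitude <= b[4], , drop = FALSE]
  }
  if (nrow(df) < n)
    stop(sprintf("only %d candidate background points for n = %d",
                 nrow(df), n), call. = FALSE)
  with_rng_seed(seed, {
    i <- sort(sample.int(nrow(df), n))
    out <- df[i, c("longitude", "latitude")]
    rownames(out) <- NULL
    out
  })
}
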