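# Gaussian niche-response scenarios, ground-truth suitability surfaces,
# multinomial occurrence sampling and eBird-style checklist metadata.

#' Define a Gaussian niche scenario
#'
#' For each group and continuous layer, the niche response is a Gaussian
#' curve with optimum `mu` and breadth `sigma`; for a categorical layer each
#' class carries a weight in \[0, 1\].  Suitability is the product of the
#' per-layer responses (independent responses, no interactions), which keeps
#' the ground truth analytically checkable.
#'
#' @param groups Character vector of group names.
#' @param optima Numeric matrix, groups x continuous layers (dimnames
#'   required), of niche optima in layer units.
#' @param breadths Matrix like `optima` of niche breadths (> 0).
#' @param class_weights Optional named list: per categorical layer, a matrix
#'   groups x classes of weights in \[0, 1\].
#' @return A `niche_scenario` object.
#' @export
niche_scenario <- function(groups, optima, breadths, class_weights = NULL) {
  optima <- as.matrix(optima); breadths <- as.matrix(breadths)
  stopifnot(nrow(optima) == length(groups),
            all(dim(optima) == dim(breadths)))
  if (is.null(colnames(optima)))
    stop("`optima` needs layer names as colnames", call. = FALSE)
  if (any(breadths <= 0)) stop("niche breadths must be > 0", call. = FALSE)
  rownames(optima) <- rownames(breadths) <- groups
  colnames(breadths) <- colnames(optima)
  if (!is.null(class_weights)) {
    for (nm in names(class_weights)) {
      w <- as.matrix(class_weights[[nm]])
      if (nrow(w) != length(groups) || any(w < 0) || any(w > 1))
        stop(sprintf("class weights for '%s' must be a groups x classes matrix in [0, 1]",
                     nm), call. = FALSE)
      rownames(w) <- groups
      class_weights[[nm]] <- w
    }
  }
  structure(list(groups = groups, optima = optima, breadths = breadths,
                 class_weights = class_weights),
            class = "niche_scenario")
}

#' @export
print.niche_scenario <- function(x, ...) {
  cat(sprintf("<niche_scenario> %d group(s): %s\n", length(x$groups),
              paste(x$groups, collapse = ", ")))
  cat("optima:\n"); print(x$optima)
  invisible(x)
}

#' Build a canned two- or three-group niche scenario
#'
#' `identical`: all groups share the same niche (the identity-test null).
#' `divergent`: two groups with optima `separation * sigma` apart on the
#' first layer.  `three_group`: two parental groups at `-separation/2` and
#' `+separation/2` on the first layer, and a hybrid whose optimum sits at the
#' parental midpoint on layer 1 but is offset by `separation/2` on the second
#' layer — a distinct niche, not merely an intermediate one.
#'
#' @param kind `"identical"`, `"divergent"` or `"three_group"`.
#' @param separation Niche separation in units of `sigma` (>= 0).
#' @param layer_names Continuous layers the scenario parameterizes (>= 2
#'   names for `three_group`).
#' @param sigma Common niche breadth in layer units.
#' @param groups Optional group names (2 or 3 depending on `kind`).
#' @param seed Unused; accepted for interface uniformity with the other
#'   generators (scenario construction is deterministic).
#' @return A [niche_scenario()].
#' @export
#' @examples
#' make_scenario("three_group", separation = 4)
make_scenario <- function(kind = c("identical", "divergent", "three_group"),
                          separation = 0,
                          layer_names = c("env1", "env2"),
                          sigma = 1, groups = NULL, seed = NULL) {
  kind <- match.arg(kind)
  if (separation < 0) stop("`separation` must be >= 0", call. = FALSE)
  k <- length(layer_names)
  if (kind == "three_group" && k < 2)
    stop("`three_group` needs at least two layers", call. = FALSE)
  if (is.null(groups))
    groups <- if (kind == "three_group") c("parental1", "parental2", "hybrid")
              else c("groupA", "groupB")
  n_groups <- if (kind == "three_group") 3L else 2L
  if (length(groups) != n_groups)
    stop(sprintf("`%s` scenarios take %d group names", kind, n_groups),
         call. = FALSE)
  mu <- matrix(0, n_groups, k, dimnames = list(groups, layer_names))
  if (kind == "divergent") {
    mu[1, 1] <- -separation * sigma / 2
    mu[2, 1] <- +separation * sigma / 2
  } else if (kind == "three_group") {
    mu[1, 1] <- -separation * sigma / 2
    mu[2, 1] <- +separation * sigma / 2
    mu[3, 2] <- separation * sigma / 2
  }
  sd <- matrix(sigma, n_groups, k, dimnames = dimnames(mu))
  niche_scenario(groups, mu, sd)
}

#' Ground-truth suitability of a group over a landscape
#'
#' Per cell: the product over continuous layers of
#' `exp(-0.5 * ((value - mu) / sigma)^2)`, times the group's class weight for
#' each categorical layer.  Layers present in the stack but not in the
#' scenario are an error (named in the message).
#'
#' @param scenario A [niche_scenario()].
#' @param group Group name.
#' @param stack A [raster_stack()].
#' @return A [suitability_grid()] with the stack's nodata mask.
#' @export
gaussian_niche_suitability <- function(scenario, group, stack) {
  stopifnot(inherits(scenario, "niche_scenario"), inherits(stack, "raster_stack"))
  if (!group %in% scenario$groups)
    stop(sprintf("unknown group '%s'", group), call. = FALSE)
  vals <- matrix(1, stack$grid$n_rows, stack$grid$n_cols)
  for (nm in names(stack$layers)) {
    m <- stack$layers[[nm]]
    if (stack$kind[[nm]] == "continuous") {
      if (!nm %in% colnames(scenario$optima))
        stop(sprintf("scenario lacks (mu, sigma) for layer '%s'", nm),
             call. = FALSE)
      mu <- scenario$optima[group, nm]
      sd <- scenario$breadths[group, nm]
      vals <- vals * exp(-0.5 * ((m - mu) / sd)^2)
    } else {
      w <- scenario$class_weights[[nm]]
      if (is.null(w))
        stop(sprintf("scenario lacks class weights for layer '%s'", nm),
             call. = FALSE)
      codes <- as.integer(m)
      if (any(codes < 1 | codes > ncol(w)))
        stop(sprintf("layer '%s' has class codes outside the weight table", nm),
             call. = FALSE)
      vals <- vals * matrix(w[group, codes],
                            stack$grid$n_rows, stack$grid$n_cols)
    }
  }
  suitability_grid(stack$grid, vals, mask = stack$mask)
}

#' Sample occurrence points from a suitability surface
#'
#' Draws `n` points from the multinomial over unmasked cells with
#' probabilities proportional to suitability (conditioned on `n`; not an
#' inhomogeneous Poisson process).  Coordinates are cell centers, optionally
#' jittered uniformly within the cell.
#'
#' @param suit A [suitability_grid()].
#' @param n Number of points.
#' @param group Group label attached to every record.
#' @param jitter `"uniform"` (within-cell) or `"none"`.
#' @param seed Integer seed.
#' @param id_prefix Prefix for record ids.
#' @return An [occurrence_table()] (planar or lonlat per the grid's crs).
#' @export
sample_occurrences <- function(suit, n, group = "A",
                               jitter = c("uniform", "none"), seed,
                               id_prefix = group) {
  stopifnot(inherits(suit, "suitability_grid"))
  jitter <- match.arg(jitter)
  assert_count(n, "n")
  valid <- which(!suit$mask)
  w <- suit$values[valid]
  if (!length(valid) || sum(w) <= 0)
    stop("no unmasked cell with positive suitability", call. = FALSE)
  grid <- suit$grid
  with_rng_seed(seed, {
    counts <- as.vector(stats::rmultinom(1, n, prob = w))
    cell <- rep(valid[counts > 0], counts[counts > 0])
    row <- (cell - 1L) %% grid$n_rows + 1L
    col <- (cell - 1L) %/% grid$n_rows + 1L
    x <- grid$origin_x + (col - 0.5) * grid$cell_size
    y <- grid$origin_y + (row - 0.5) * grid$cell_size
    if (jitter == "uniform") {
      x <- x + stats::runif(length(x), -0.5, 0.5) * grid$cell_size
      y <- y + stats::runif(length(y), -0.5, 0.5) * grid$cell_size
    }
    ord <- sample.int(length(x))  # decouple row order from cell index order
    occurrence_table(
      data.frame(id = sprintf("%s_%05d", id_prefix, seq_len(n)),
                 longitude = x[ord], latitude = y[ord],
                 group = group, stringsAsFactors = FALSE),
      coord_system = if (grid$crs == "lonlat") "lonlat" else "planar")
  })
}

#' Default checklist metadata distributions
#'
#' Clean records satisfy every occurrence filter of [filter_config()]:
#' Stationary/Traveling protocol, duration < 360 min, distance < 10 km,
#' start time within 06:00–21:00, <= 10 observers, complete checklists,
#' June–July of 2010–2023.  Violating records are drawn from the complement
#' of each criterion.
#'
#' @return A list of ranges/sets consumed by [attach_checklist_metadata()].
#' @export
checklist_config <- function() {
  list(protocols = c("Stationary", "Traveling"),
       bad_protocol = "Incidental",
       duration_range = c(10, 359), bad_duration_range = c(360, 600),
       distance_range = c(0, 9.9), bad_distance_range = c(10, 50),
       time_window = c("06:00", "21:00"),
       observers_range = c(1, 10), bad_observers_range = c(11, 25),
       months = c(6, 7), bad_months = c(1:5, 8:12),
       years = 2010:2023, bad_years = 2000:2009)
}

#' Attach synthetic checklist metadata, with a ledger of planted violations
#'
#' Each record gains protocol, duration, travel distance, start time,
#' observer count, completeness flag and date.  For each filter criterion a
#' fraction `fail_fraction[criterion]` of records (drawn independently per
#' criterion, so a record can violate several) is made to violate it; the ids
#' are recorded in the `fail_ledger` attribute, so downstream filter tests
#' know exactly which rows must fall.
#'
#' @param table An [occurrence_table()].
#' @param config Distributions from [checklist_config()].
#' @param fail_fraction Named numeric vector in \[0, 1\] over criteria
#'   `protocol`, `duration`, `distance`, `time`, `observers`, `complete`,
#'   `month`, `year`; unnamed scalar = same fraction everywhere.
#' @param seed Integer seed.
#' @return The table with metadata columns; attribute `fail_ledger` is a
#'   named list of violating ids per criterion.
#' @export
attach_checklist_metadata <- function(table, config = checklist_config(),
                                      fail_fraction = 0, seed) {
  stopifnot(inherits(table, "occurrence_table"))
  criteria <- c("protocol", "duration", "distance", "time", "observers",
                "complete", "month", "year")
  if (length(fail_fraction) == 1L && is.null(names(fail_fraction)))
    fail_fraction <- stats::setNames(rep(fail_fraction, length(criteria)),
                                     criteria)
  ff <- stats::setNames(rep(0, length(criteria)), criteria)
  ff[names(fail_fraction)] <- fail_fraction
  if (any(ff < 0 | ff > 1))
    stop("`fail_fraction` entries must lie in [0, 1]", call. = FALSE)
  n <- nrow(table)
  with_rng_seed(seed, {
    fmt_clock <- function(mins) sprintf("%02d:%02d", mins %/% 60L, mins %% 60L)
    win <- parse_clock_minutes(config$time_window)
    good_time <- function(k) fmt_clock(sample(seq(win[1], win[2]), k, TRUE))
    bad_time <- function(k) {
      pool <- setdiff(0:1439, seq(win[1], win[2]))
      fmt_clock(sample(pool, k, TRUE))
    }
    df <- as.data.frame(table)
    df$protocol <- sample(config$protocols, n, TRUE)
    df$duration_minutes <- round(stats::runif(n, config$duration_range[1],
                                              config$duration_range[2]))
    df$effort_distance_km <- round(stats::runif(n, config$distance_range[1],
                                                config$distance_range[2]), 2)
    df$start_time <- good_time(n)
    df$n_observers <- sample(seq(config$observers_range[1],
                                 config$observers_range[2]), n, TRUE)
    df$complete <- TRUE
    yr <- sample(config$years, n, TRUE)
    mo <- sample(config$months, n, TRUE)
    dy <- sample(1:28, n, TRUE)
    ledger <- list()
    pick <- function(frac) {
      k <- round(frac * n)
      if (k == 0) integer() else sample.int(n, k)
    }
    i <- pick(ff["protocol"])
    df$protocol[i] <- config$bad_protocol
    ledger$protocol <- df$id[i]
    i <- pick(ff["duration"])
    df$duration_minutes[i] <- round(stats::runif(length(i),
                                                 config$bad_duration_range[1],
                                                 config$bad_duration_range[2]))
    ledger$duration <- df$id[i]
    i <- pick(ff["distance"])
    df$effort_distance_km[i] <- round(stats::runif(length(i),
                                                   config$bad_distance_range[1],
                                                   config$bad_distance_range[2]), 2)
    ledger$distance <- df$id[i]
    i <- pick(ff["time"])
    df$start_time[i] <- bad_time(length(i))
    ledger$time <- df$id[i]
    i <- pick(ff["observers"])
    df$n_observers[i] <- sample(seq(config$bad_observers_range[1],
                                    config$bad_observers_range[2]),
                                length(i), TRUE)
    ledger$observers <- df$id[i]
    i <- pick(ff["complete"])
    df$complete[i] <- FALSE
    ledger$complete <- df$id[i]
    i <- pick(ff["month"])
    mo[i] <- sample(config$bad_months, length(i), TRUE)
    ledger$month <- df$id[i]
    i <- pick(ff["year"])
    yr[i] <- sample(config$bad_years, length(i), TRUE)
    ledger$year <- df$id[i]
    df$date <- sprintf("%04d-%02d-%02d", yr, mo, dy)
    out <- occ_rebuild(df, table)
    attr(out, "fail_ledger") <- ledger
    out
  })
}
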