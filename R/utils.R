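# Internal helpers: RNG scoping, seed derivation, distances.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed`, then restores the
#' previous RNG state, so generators are pure functions of their arguments.
#' With `seed = NULL` the expression runs against the ambient RNG stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_rng_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

#' Derive a per-stage seed from a master seed
#'
#' Deterministic polynomial hash of the stage name folded into the master
#' seed, modulo 2^31 - 1.  Adding a pipeline stage never perturbs the seeds
#' of existing stages because each stage's seed depends only on its own name.
#'
#' @param master_seed Integer master seed.
#' @param stage Character stage name.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "thin") != derive_seed(42, "balance")
derive_seed <- function(master_seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  m <- 2147483647
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% m
  as.integer((h + as.numeric(master_seed) %% m) %% m)
}

# Mean Earth radius (km) used for all great-circle computations.
EARTH_RADIUS_KM <- 6371.0088

# Pairwise distance matrix in km.  metric: "haversine" treats columns as
# lon/lat degrees; "euclidean" treats them as planar km coordinates.
pairwise_distances_km <- function(x, y, metric = c("haversine", "euclidean")) {
  metric <- match.arg(metric)
  if (metric == "euclidean") {
    as.matrix(stats::dist(cbind(x, y)))
  } else {
    geosphere::distm(cbind(x, y), fun = function(p1, p2)
      geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM * 1000)) / 1000
  }
}

# Distances (km) from one point to many.
dist_to_point_km <- function(x, y, x0, y0, metric = c("haversine", "euclidean")) {
  metric <- match.arg(metric)
  if (metric == "euclidean") {
    sqrt((x - x0)^2 + (y - y0)^2)
  } else {
    geosphere::distHaversine(c(x0, y0), cbind(x, y),
                             r = EARTH_RADIUS_KM * 1000) / 1000
  }
}

# Resolve a distance metric from an explicit choice or a coordinate-system tag.
resolve_metric <- function(metric, coord_system) {
  if (!is.null(metric) && metric != "auto") return(metric)
  if (identical(coord_system, "planar")) "euclidean" else "haversine"
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}
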