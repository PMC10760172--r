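# Point-wise environmental extraction and collinearity-based variable
# selection (VIF stepwise and pairwise-correlation procedures).

#' Extract environmental values at occurrence points
#'
#' Nearest-cell (no interpolation) extraction with the
#' `floor((coord - origin) / cell_size)` assignment convention, so a point on
#' a cell boundary deterministically belongs to the upper/right cell.
#' Points outside the raster extent or on nodata cells are dropped and
#' counted.
#'
#' @param stack A [raster_stack()].
#' @param points An [occurrence_table()] or any data.frame with `longitude`
#'   and `latitude` columns.
#' @return A data.frame (rows = surviving points, columns = layers) with
#'   attributes `kind` (per-column continuous/categorical), `point_id`,
#'   `cell_index` (linear index into the grid) and `n_dropped`
#'   (named: outside, nodata).
#' @export
extract_env <- function(stack, points) {
  stopifnot(inherits(stack, "raster_stack"))
  if (!all(c("longitude", "latitude") %in% names(points)))
    stop("`points` needs longitude/latitude columns", call. = FALSE)
  pc <- point_cell(stack$grid, points$longitude, points$latitude)
  outside <- !pc$inside
  cell <- rep(NA_integer_, nrow(pc))
  cell[!outside] <- (pc$col[!outside] - 1L) * stack$grid$n_rows +
    pc$row[!outside]
  nodata <- !outside
  nodata[!outside] <- stack$mask[cbind(pc$row[!outside], pc$col[!outside])]
  keep <- !outside & !nodata
  if (!any(keep))
    stop("every point fell outside the extent or on nodata", call. = FALSE)
  env <- as.data.frame(lapply(stack$layers, function(m) m[cell[keep]]))
  attr(env, "kind") <- stack$kind
  attr(env, "point_id") <- if ("id" %in% names(points))
    points$id[keep] else which(keep)
  attr(env, "cell_index") <- cell[keep]
  attr(env, "n_dropped") <- c(outside = sum(outside), nodata = sum(nodata))
  env
}

env_kinds <- function(env) {
  k <- attr(env, "kind")
  if (is.null(k)) stats::setNames(rep("continuous", ncol(env)), names(env))
  else k[names(env)]
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` with `R^2_j` from the least-squares regression
#' of variable `j` on all other listed variables plus an intercept.  Exact
#' collinearity is reported as `Inf`.  VIF is scale-invariant, so columns are
#' used unstandardized.
#'
#' @param env Environmental matrix/data.frame (see [extract_env()]).
#' @param variables Continuous variables to use; default = all continuous
#'   columns.
#' @return Named numeric vector of VIFs (>= 1, or `Inf`).
#' @export
compute_vif <- function(env, variables = NULL) {
  kinds <- env_kinds(env)
  if (is.null(variables))
    variables <- names(env)[kinds[names(env)] == "continuous"]
  if (length(variables) < 2)
    stop("VIF needs at least two continuous variables", call. = FALSE)
  x <- as.matrix(as.data.frame(env)[, variables, drop = FALSE])
  if (nrow(x) < length(variables) + 2)
    stop("too few rows for a VIF computation", call. = FALSE)
  const <- apply(x, 2, function(v) stats::sd(v) == 0)
  if (any(const))
    stop("constant column(s): ", paste(variables[const], collapse = ", "),
         call. = FALSE)
  vifs <- vapply(seq_along(variables), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((x[, j] - mean(x[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  stats::setNames(vifs, variables)
}

.vif_report <- function(env, retained, dropped, method, threshold) {
  x <- as.data.frame(env)[, retained, drop = FALSE]
  structure(list(method = method, threshold = threshold,
                 retained = retained, dropped = dropped,
                 vif = if (length(retained) >= 2) compute_vif(env, retained)
                       else stats::setNames(rep(1, length(retained)), retained),
                 cor_matrix = if (length(retained) >= 2)
                   stats::cor(as.matrix(x)) else NULL),
            class = "vif_report")
}

#' @export
print.vif_report <- function(x, ...) {
  cat(sprintf("<vif_report> method %s (threshold %g)\n", x$method, x$threshold))
  cat("retained:", paste(x$retained, collapse = ", "), "\n")
  if (length(x$dropped))
    cat("dropped (in order):", paste(x$dropped, collapse = ", "), "\n")
  print(round(x$vif, 3))
  invisible(x)
}

#' Stepwise VIF variable selection
#'
#' Iteratively drops the variable with the largest VIF while that VIF
#' exceeds `threshold` (alphabetical first on ties), recomputing after every
#' drop.
#'
#' @param env Environmental matrix (continuous columns are used).
#' @param threshold VIF threshold (default 10).
#' @param variables Optional explicit continuous subset.
#' @return A `vif_report`: retained set, drop order, final VIFs, correlation
#'   matrix.
#' @export
vifstep_select <- function(env, threshold = 10, variables = NULL) {
  kinds <- env_kinds(env)
  if (is.null(variables))
    variables <- names(env)[kinds[names(env)] == "continuous"]
  retained <- sort(variables)
  dropped <- character()
  while (length(retained) >= 2) {
    v <- compute_vif(env, retained)
    worst <- max(v)
    if (worst <= threshold) break
    # ties -> alphabetical first; retained is sorted so which.max suffices
    drop <- names(v)[which.max(v)]
    dropped <- c(dropped, drop)
    retained <- setdiff(retained, drop)
  }
  .vif_report(env, retained, dropped, "vifstep", threshold)
}

#' Pairwise-correlation VIF variable selection
#'
#' While the maximum absolute pairwise Pearson correlation exceeds
#' `r_threshold`, drops the member of that pair with the larger current VIF
#' (alphabetical first on ties), recomputing after every drop.
#'
#' @param env Environmental matrix (continuous columns are used).
#' @param r_threshold Correlation threshold (default 0.9).
#' @param variables Optional explicit continuous subset.
#' @return A `vif_report`.
#' @export
vifcor_select <- function(env, r_threshold = 0.9, variables = NULL) {
  kinds <- env_kinds(env)
  if (is.null(variables))
    variables <- names(env)[kinds[names(env)] == "continuous"]
  retained <- sort(variables)
  dropped <- character()
  while (length(retained) >= 2) {
    x <- as.matrix(as.data.frame(env)[, retained, drop = FALSE])
    cm <- abs(stats::cor(x))
    diag(cm) <- 0
    if (max(cm) <= r_threshold) break
    idx <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    pair <- sort(retained[idx])
    v <- compute_vif(env, retained)
    drop <- if (v[pair[1]] > v[pair[2]]) pair[1]
            else if (v[pair[2]] > v[pair[1]]) pair[2]
            else pair[1]  # tie -> alphabetical first
    dropped <- c(dropped, drop)
    retained <- setdiff(retained, drop)
  }
  .vif_report(env, retained, dropped, "vifcor", r_threshold)
}

#' Run both VIF procedures and intersect the retained sets
#'
#' Applies [vifstep_select()] and [vifcor_select()] and retains the
#' intersection of their retained sets; each method's pure result is also
#' reported.  Categorical variables are excluded from the VIF computations
#' (linear VIF is undefined for unordered codes) but always retained for
#' modelling.
#'
#' @param env Environmental matrix.
#' @param vif_threshold Threshold for [vifstep_select()].
#' @param r_threshold Threshold for [vifcor_select()].
#' @return A list with `retained` (continuous intersection plus categorical
#'   variables), `step` and `cor` reports.
#' @export
select_variables <- function(env, vif_threshold = 10, r_threshold = 0.9) {
  kinds <- env_kinds(env)
  categorical <- names(env)[kinds[names(env)] == "categorical"]
  continuous <- names(env)[kinds[names(env)] == "continuous"]
  if (length(continuous) < 2) {
    return(list(retained = c(continuous, categorical), step = NULL, cor = NULL))
  }
  step <- vifstep_select(env, vif_threshold)
  corr <- vifcor_select(env, r_threshold)
  keep <- intersect(step$retained, corr$retained)
  if (!length(keep))
    stop("the vifstep/vifcor intersection retained no continuous variables",
         call. = FALSE)
  list(retained = c(sort(keep), categorical), step = step, cor = corr)
}
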