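# Synthetic environmental landscapes: spatially autocorrelated Gaussian
# random fields with controllable inter-layer correlation, plus categorical
# layers derived by quantile-thresholding a latent field.

#' Describe one synthetic environmental layer
#'
#' @param name Layer identifier.
#' @param kind `"continuous"` or `"categorical"`.
#' @param autocorr_length Spatial autocorrelation length scale in cells
#'   (Gaussian smoothing kernel bandwidth; 0 = white noise).
#' @param n_classes Number of classes (categorical layers only, >= 2).
#' @return A `layer_spec` object.
#' @export
#' @examples
#' layer_spec("bio1", autocorr_length = 5)
#' layer_spec("landcover", kind = "categorical", n_classes = 19)
layer_spec <- function(name, kind = c("continuous", "categorical"),
                       autocorr_length = 5, n_classes = NULL) {
  kind <- match.arg(kind)
  if (autocorr_length < 0) stop("`autocorr_length` must be >= 0", call. = FALSE)
  if (kind == "categorical") {
    if (is.null(n_classes) || n_classes < 2)
      stop("categorical layers need `n_classes` >= 2", call. = FALSE)
    n_classes <- as.integer(n_classes)
  }
  structure(list(name = name, kind = kind,
                 autocorr_length = autocorr_length, n_classes = n_classes),
            class = "layer_spec")
}

# Gaussian random field: white noise convolved with a separable Gaussian
# kernel (circular boundary), standardized to mean 0 / sd 1.  The effective
# correlation length approximately equals the kernel bandwidth.
smooth_field <- function(n_rows, n_cols, length_scale) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  if (length_scale > 0) {
    kernel <- function(n) {
      # truncate at 3 bandwidths, capped so the kernel fits the grid
      half <- min(max(1L, ceiling(3 * length_scale)), (n - 1L) %/% 2L)
      k <- stats::dnorm(seq(-half, half), sd = length_scale)
      k / sum(k)
    }
    z <- apply(z, 2, function(col) stats::filter(col, kernel(n_rows),
                                                 circular = TRUE))
    z <- t(apply(z, 1, function(row) stats::filter(row, kernel(n_cols),
                                                   circular = TRUE)))
    z <- matrix(as.numeric(z), n_rows, n_cols)
  }
  (z - mean(z)) / stats::sd(z)
}

#' Generate a synthetic environmental landscape
#'
#' Continuous layers are smoothed Gaussian random fields; requested pairwise
#' correlations are induced by linearly mixing independent latent fields with
#' the Cholesky factor of the target correlation matrix (so achieved
#' correlations are approximate by design, converging with grid size).
#' Categorical layers are produced by quantile-thresholding their (mixed)
#' latent field into `n_classes` equal-area classes coded `1..n_classes`.
#'
#' @param grid A [grid_spec()].
#' @param layers List of [layer_spec()] objects.
#' @param correlation Optional target pairwise correlation matrix across all
#'   layers' latent fields (symmetric, unit diagonal, positive semi-definite).
#'   `NULL` means independent layers.
#' @param seed Integer seed; the generator is a pure function of
#'   (arguments, seed).
#' @return A [raster_stack()] with no masked cells.
#' @export
#' @examples
#' g <- grid_spec(50, 50)
#' ls <- list(layer_spec("a"), layer_spec("b"))
#' st <- generate_landscape(g, ls, correlation = matrix(c(1, .7, .7, 1), 2),
#'                          seed = 1)
generate_landscape <- function(grid, layers, correlation = NULL, seed) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!length(layers)) stop("at least one layer_spec is required", call. = FALSE)
  k <- length(layers)
  nm <- vapply(layers, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("layer names must be unique", call. = FALSE)
  if (is.null(correlation)) correlation <- diag(k)
  correlation <- as.matrix(correlation)
  if (!isTRUE(all.equal(correlation, t(correlation), tolerance = 1e-8)) ||
      any(abs(diag(correlation) - 1) > 1e-8))
    stop("`correlation` must be symmetric with unit diagonal", call. = FALSE)
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("`correlation` must be positive semi-definite", call. = FALSE)

  with_rng_seed(seed, {
    latents <- lapply(layers, function(ls)
      as.vector(smooth_field(grid$n_rows, grid$n_cols, ls$autocorr_length)))
    f <- do.call(cbind, latents)
    # PSD but possibly singular targets: mix through the eigendecomposition.
    es <- eigen(correlation, symmetric = TRUE)
    rt <- es$vectors %*% diag(sqrt(pmax(es$values, 0)), k) %*% t(es$vectors)
    mixed <- f %*% rt
    out <- list(); kinds <- character()
    for (j in seq_len(k)) {
      ls <- layers[[j]]
      m <- matrix(mixed[, j], grid$n_rows, grid$n_cols)
      if (ls$kind == "categorical") {
        qs <- stats::quantile(m, probs = seq_len(ls$n_classes - 1) / ls$n_classes)
        m <- matrix(findInterval(m, qs) + 1L, grid$n_rows, grid$n_cols)
      }
      out[[ls$name]] <- m
      kinds[ls$name] <- ls$kind
    }
    raster_stack(grid, out, kind = kinds)
  })
}
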