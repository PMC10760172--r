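# Niche-overlap statistics between two suitability surfaces: Schoener's D,
# Hellinger distance H and Warren's I, computed over a shared valid-cell set.

#' Normalize a suitability surface to a probability grid
#'
#' `p_i = suit_i / sum_j suit_j` over the shared valid cells, so the overlap
#' statistics operate on probability distributions as their definitions
#' assume.  Comparisons use the intersection of the two surfaces' valid
#' cells, renormalizing both.
#'
#' @param suit A [suitability_grid()] or a nonnegative numeric vector.
#' @param shared_mask Optional logical matrix (`TRUE` = exclude) applied on
#'   top of the surface's own mask.
#' @return A `probability_grid`: probabilities `p` and their `cell_index`.
#' @export
normalize_grid <- function(suit, shared_mask = NULL) {
  if (is.numeric(suit) && is.null(dim(suit))) {
    if (any(suit < 0)) stop("suitabilities must be >= 0", call. = FALSE)
    tot <- sum(suit)
    if (tot <= 0) stop("zero total suitability", call. = FALSE)
    return(structure(list(p = suit / tot, cell_index = seq_along(suit)),
                     class = "probability_grid"))
  }
  stopifnot(inherits(suit, "suitability_grid"))
  mask <- suit$mask
  if (!is.null(shared_mask)) mask <- mask | shared_mask
  idx <- which(!mask)
  v <- suit$values[idx]
  tot <- sum(v)
  if (tot <= 0) stop("zero total suitability over the shared cells",
                     call. = FALSE)
  structure(list(p = v / tot, cell_index = idx), class = "probability_grid")
}

#' @export
print.probability_grid <- function(x, ...) {
  cat(sprintf("<probability_grid> %d cell(s), sum %.6f\n",
              length(x$p), sum(x$p)))
  invisible(x)
}

.check_shared <- function(pX, pY) {
  stopifnot(inherits(pX, "probability_grid"), inherits(pY, "probability_grid"))
  if (length(pX$p) != length(pY$p) ||
      !identical(pX$cell_index, pY$cell_index))
    stop("probability grids do not share the same cell set", call. = FALSE)
}

#' Schoener's D niche overlap
#'
#' `D = 1 - 0.5 * sum_i |pX_i - pY_i|`; 0 = disjoint niches, 1 = identical.
#'
#' @param pX,pY [normalize_grid()] probability grids over the same cells.
#' @return D in \[0, 1\].
#' @export
#' @examples
#' schoener_d(normalize_grid(c(.5, .5)), normalize_grid(c(1, 0)))  # 0.5
schoener_d <- function(pX, pY) {
  .check_shared(pX, pY)
  1 - 0.5 * sum(abs(pX$p - pY$p))
}

#' Hellinger distance and Warren's I
#'
#' `H = sqrt(sum_i (sqrt(pX_i) - sqrt(pY_i))^2)` (range 0..sqrt(2)) and
#' `I = 1 - H^2 / 2`, which equals the Bhattacharyya coefficient
#' `sum_i sqrt(pX_i * pY_i)`; 0 = no overlap, 1 = identical niches.
#'
#' @param pX,pY [normalize_grid()] probability grids over the same cells.
#' @return List with `H` and `I`.
#' @export
warren_i <- function(pX, pY) {
  .check_shared(pX, pY)
  H2 <- sum((sqrt(pX$p) - sqrt(pY$p))^2)
  list(H = sqrt(H2), I = 1 - H2 / 2)
}

#' All overlap statistics for a pair of suitability surfaces
#'
#' Normalizes both surfaces over the intersection of their valid cells and
#' returns Schoener's D, Hellinger's H and Warren's I.
#'
#' @param suitX,suitY [suitability_grid()]s on the same grid (or nonnegative
#'   numeric vectors of equal length).
#' @return A list `(D, H, I)`.
#' @export
overlap_stats <- function(suitX, suitY) {
  if (inherits(suitX, "suitability_grid")) {
    shared <- suitX$mask | suitY$mask
    pX <- normalize_grid(suitX, shared)
    pY <- normalize_grid(suitY, shared)
  } else {
    pX <- normalize_grid(suitX)
    pY <- normalize_grid(suitY)
  }
  w <- warren_i(pX, pY)
  list(D = schoener_d(pX, pY), H = w$H, I = w$I)
}
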