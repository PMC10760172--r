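# Niche identity and blob range-breaking permutation tests: null
# distributions of D and I from refitted pseudo-group models, with
# one-tailed add-one-corrected p-values.

#' Permutation-test configuration
#'
#' @param n_iter Number of null replicates (default 100).
#' @param alpha Significance threshold (default 0.05), echoed in results.
#' @param statistics Statistics to test, subset of `c("D", "I")`.
#' @param seed Integer seed for the whole test (null draws and refits).
#' @param beta_multiplier,classes,max_iter,tolerance Maxent settings used for
#'   the observed and every null fit.
#' @param metric Distance metric for the blob splits: `"auto"`,
#'   `"haversine"` or `"euclidean"`.
#' @return A `test_config` object.
#' @export
test_config <- function(n_iter = 100, alpha = 0.05,
                        statistics = c("D", "I"), seed = 1,
                        beta_multiplier = 1,
                        classes = c("linear", "quadratic"),
                        max_iter = 500, tolerance = 1e-7,
                        metric = "auto") {
  assert_count(n_iter, "n_iter")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  statistics <- match.arg(statistics, several.ok = TRUE)
  structure(list(n_iter = as.integer(n_iter), alpha = alpha,
                 statistics = statistics, seed = seed,
                 beta_multiplier = beta_multiplier, classes = classes,
                 max_iter = max_iter, tolerance = tolerance, metric = metric),
            class = "test_config")
}

#' One-tailed permutation p-value with add-one correction
#'
#' Lower tail: `p = (1 + #(null <= observed)) / (n + 1)`; upper tail
#' analogous.  Ties count toward the tail, and the add-one correction keeps
#' `p >= 1 / (n + 1) > 0`.
#'
#' @param observed Observed statistic.
#' @param null Numeric vector of null statistics.
#' @param tail `"lower"` or `"upper"`.
#' @return The p-value.
#' @export
#' @examples
#' permutation_p(0.1, seq(0.2, 0.9, length.out = 100), "lower")  # 1/101
permutation_p <- function(observed, null, tail = c("lower", "upper")) {
  tail <- match.arg(tail)
  if (!length(null)) stop("`null` must be non-empty", call. = FALSE)
  k <- if (tail == "lower") sum(null <= observed) else sum(null >= observed)
  (1 + k) / (length(null) + 1)
}

# Shared engine for both permutation tests.  `split_fun(r)` returns the
# pooled-row indices assigned to pseudo-group A in null replicate r.
.pairwise_niche_test <- function(kind, occA, occB, stack, background, config,
                                 split_fun_factory) {
  stopifnot(inherits(stack, "raster_stack"), inherits(config, "test_config"))
  if (!nrow(occA) || !nrow(occB))
    stop("both groups must be non-empty", call. = FALSE)
  pooled <- occ_rebuild(rbind(as.data.frame(occA)[OCC_CORE_COLS],
                              as.data.frame(occB)[OCC_CORE_COLS]), occA)
  nA <- nrow(occA)
  env_pool <- extract_env(stack, pooled)
  if (nrow(env_pool) < nrow(pooled))
    stop("pooled occurrence points fell outside the stack extent or on ",
         "nodata; clip the inputs first", call. = FALSE)
  env_bg <- extract_env(stack, background)
  features <- build_features(env_pool, env_bg, classes = config$classes)
  # grid features once; null refits reuse them (feature scalings are fixed to
  # the pooled-data ranges, so replicates differ only in presence labels)
  env_grid <- stack_env_frame(stack)
  X_grid <- apply_features(features$defs, env_grid)

  overlap_from_models <- function(fitA, fitB) {
    pA <- exp_normalize(drop(X_grid %*% fitA$lambda))
    pB <- exp_normalize(drop(X_grid %*% fitB$lambda))
    H2 <- sum((sqrt(pA) - sqrt(pB))^2)
    c(D = 1 - 0.5 * sum(abs(pA - pB)), I = 1 - H2 / 2)
  }
  fit_pair <- function(rows_A, rows_B) {
    fitA <- fit_maxent(features, config$beta_multiplier, config$max_iter,
                       config$tolerance, presence_rows = rows_A)
    fitB <- fit_maxent(features, config$beta_multiplier, config$max_iter,
                       config$tolerance, presence_rows = rows_B)
    list(fitA = fitA, fitB = fitB,
         ok = fitA$converged && fitB$converged,
         stat = overlap_from_models(fitA, fitB))
  }

  n_pool <- nrow(pooled)
  with_rng_seed(config$seed, {
    obs <- fit_pair(seq_len(nA), (nA + 1):n_pool)
    split_fun <- split_fun_factory(pooled, nA)
    null_mat <- matrix(NA_real_, config$n_iter, 2,
                       dimnames = list(NULL, c("D", "I")))
    n_excluded <- 0L
    for (r in seq_len(config$n_iter)) {
      res <- NULL
      for (attempt in 1:2) {   # non-convergence: redraw once, then exclude
        idx_A <- split_fun()
        cand <- fit_pair(idx_A, setdiff(seq_len(n_pool), idx_A))
        if (cand$ok) { res <- cand; break }
      }
      if (is.null(res)) n_excluded <- n_excluded + 1L
      else null_mat[r, ] <- res$stat
    }
    null_mat <- null_mat[stats::complete.cases(null_mat), , drop = FALSE]
    p <- lapply(c(D = "D", I = "I"), function(s) c(
      lower = permutation_p(obs$stat[[s]], null_mat[, s], "lower"),
      upper = permutation_p(obs$stat[[s]], null_mat[, s], "upper")))
    structure(list(kind = kind,
                   observed = as.list(obs$stat),
                   null = as.data.frame(null_mat),
                   p = p, n_excluded = n_excluded,
                   groups = c(occA$group[1], occB$group[1]),
                   config = config),
              class = "permutation_test_result")
  })
}

exp_normalize <- function(eta) {
  w <- exp(eta - max(eta))
  w / sum(w)
}

#' @export
print.permutation_test_result <- function(x, ...) {
  cat(sprintf("<permutation_test_result> %s test: %s vs %s (%d null replicates%s)\n",
              x$kind, x$groups[1], x$groups[2], nrow(x$null),
              if (x$n_excluded) sprintf(", %d excluded", x$n_excluded) else ""))
  for (s in c("D", "I"))
    cat(sprintf("  %s = %.4f  (p_lower = %.4f, p_upper = %.4f)\n", s,
                x$observed[[s]], x$p[[s]]["lower"], x$p[[s]]["upper"]))
  invisible(x)
}

#' Niche identity test
#'
#' Fits maxent models to groups A and B against a shared background and
#' stack, computes Schoener's D and Warren's I between the normalized raw
#' prediction surfaces, and compares them with a null built by pooling
#' A and B, randomly repartitioning the pooled points into pseudo-groups of
#' the original sizes (without replacement) and refitting both models with
#' identical settings.  Niche divergence is the lower-tail comparison:
#' observed overlap below the randomized controls.
#'
#' @param occA,occB [occurrence_table()]s for the two groups.
#' @param stack A [raster_stack()] of environmental layers.
#' @param background Background points (data.frame with longitude/latitude),
#'   shared by the observed and every null fit.
#' @param config A [test_config()].
#' @return A `permutation_test_result`: observed D and I, null
#'   distributions, lower/upper p-values per statistic, and the count of
#'   replicates excluded for non-convergence.
#' @export
identity_test <- function(occA, occB, stack, background,
                          config = test_config()) {
  .pairwise_niche_test("identity", occA, occB, stack, background, config,
    split_fun_factory = function(pooled, nA) {
      n <- nrow(pooled)
      function() sample.int(n, nA)
    })
}

#' Blob range-breaking test
#'
#' Observed statistics as in [identity_test()], but each null replicate
#' splits the pooled points into spatially contiguous pseudo-ranges: one
#' pooled point is chosen uniformly as the origin and the `|A|` points
#' nearest to it (great-circle distance for lon/lat tables, ties broken by
#' point id) form pseudo-A, the rest pseudo-B.  The lower tail asks whether
#' the observed overlap is lower than expected under contiguous splits — a
#' distinct range boundary.
#'
#' @inheritParams identity_test
#' @return A `permutation_test_result`.
#' @export
blob_range_break_test <- function(occA, occB, stack, background,
                                  config = test_config()) {
  .pairwise_niche_test("blob", occA, occB, stack, background, config,
    split_fun_factory = function(pooled, nA) {
      n <- nrow(pooled)
      metric <- resolve_metric(config$metric, occ_coord_system(pooled))
      function() {
        origin <- sample.int(n, 1)
        d <- dist_to_point_km(pooled$longitude, pooled$latitude,
                              pooled$longitude[origin],
                              pooled$latitude[origin], metric)
        order(d, pooled$id)[seq_len(nA)]
      }
    })
}
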