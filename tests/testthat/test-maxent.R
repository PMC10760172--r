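# Maximum-entropy model: features, fitting (with brute-force oracle checks),
# prediction, AUC, validation, importance, response curves.

simple_features <- function(n_p = 60, n_b = 200, seed = 3, informative = TRUE) {
  set.seed(seed)
  env_b <- data.frame(e1 = runif(n_b, -2, 2), e2 = runif(n_b, -2, 2))
  env_p <- if (informative)
    data.frame(e1 = rnorm(n_p, 1, 0.3), e2 = runif(n_p, -2, 2))
  else
    env_b[sample.int(n_b, n_p, replace = TRUE), ]
  build_features(env_p, env_b, classes = c("linear", "quadratic"))
}

test_that("feature construction scales, squares and one-hots correctly", {
  env_p <- data.frame(v = c(0, 5, 10), lc = c(1L, 2L, 3L))
  env_b <- data.frame(v = c(0, 10), lc = c(1L, 2L))
  attr(env_p, "kind") <- c(v = "continuous", lc = "categorical")
  attr(env_b, "kind") <- c(v = "continuous", lc = "categorical")
  f <- build_features(env_p, env_b, classes = c("linear", "quadratic"))
  X <- f$X
  expect_equal(unname(X[, "v_lin"]), c(0, 0.5, 1, 0, 1))
  expect_equal(unname(X[, "v_quad"]), c(0, 0.25, 1, 0, 1))
  ind <- X[, grepl("^lc_is_", colnames(X))]
  expect_equal(unname(rowSums(ind)), rep(1, 5))  # one-hot
  expect_equal(ncol(ind), 3)
  # new data beyond the training range is clamped to [0, 1]
  Xn <- apply_features(f$defs, data.frame(v = c(-5, 15), lc = c(1L, 1L)))
  expect_equal(unname(Xn[, "v_lin"]), c(0, 1))
})

test_that("the single-binary-feature fit recovers the ln 4 closed form", {
  env_p <- data.frame(v = c(rep(1, 8), rep(0, 2)))
  env_b <- data.frame(v = c(rep(1, 5), rep(0, 5)))
  f <- build_features(env_p, env_b, classes = "linear")
  m <- fit_maxent(f, beta_multiplier = 0)
  expect_true(m$converged)
  expect_equal(unname(m$lambda), log(4), tolerance = 1e-6)
})

test_that("a large enough penalty zeroes the model and q is uniform", {
  f <- simple_features()
  m <- fit_maxent(f, beta_multiplier = 50)
  expect_true(all(m$lambda == 0))
  expect_equal(m$gain, 0)
  raw <- predict_scores(m, f$env[!f$presence, , drop = FALSE], "raw")
  expect_equal(raw, rep(1 / sum(!f$presence), sum(!f$presence)),
               tolerance = 1e-12)
})

test_that("the fitted gain matches a generic convex-solver oracle", {
  for (seed in 1:8) {
    set.seed(seed)
    n_b <- sample(20:50, 1)
    n_p <- sample(10:30, 1)
    k <- sample(2:3, 1)
    env_b <- as.data.frame(matrix(runif(n_b * k), n_b, k))
    env_p <- as.data.frame(matrix(runif(n_p * k)^1.5, n_p, k))
    names(env_b) <- names(env_p) <- paste0("v", seq_len(k))
    f <- build_features(env_p, env_b, classes = "linear")
    m <- fit_maxent(f, beta_multiplier = 1, tolerance = 1e-10,
                    max_iter = 2000)
    pres <- which(f$presence); bg <- which(!f$presence)
    gain_impl <- maxent_gain_r(f$X, pres, bg, m$lambda, m$beta_j)
    expect_equal(gain_impl, m$gain, tolerance = 1e-8)  # bookkeeping agrees
    starts <- rbind(rep(0, ncol(f$X)), m$lambda,
                    matrix(rnorm(3 * ncol(f$X)), 3))
    gain_oracle <- maxent_oracle_gain(f$X, pres, bg, m$beta_j, starts)
    expect_gte(gain_impl, gain_oracle - 1e-6)
  }
})

test_that("the penalized gain trace is non-decreasing", {
  f <- simple_features(seed = 11)
  m <- fit_maxent(f, beta_multiplier = 1)
  expect_true(all(diff(c(0, m$trace$gain)) >= -1e-12))
  expect_equal(sum(m$trace$delta_gain), m$gain, tolerance = 1e-9)
})

test_that("raw predictions normalize over the background; cloglog is monotone", {
  f <- simple_features(seed = 5)
  m <- fit_maxent(f)
  env_b <- f$env[!f$presence, , drop = FALSE]
  raw <- predict_scores(m, env_b, "raw")
  expect_equal(sum(raw), 1, tolerance = 1e-9)
  cll <- predict_scores(m, env_b, "cloglog")
  expect_true(all(cll >= 0 & cll <= 1))
  expect_equal(order(raw), order(cll))  # monotone transform, same ranking
  # lambda = 0 -> uniform raw over n background cells
  m0 <- fit_maxent(f, beta_multiplier = 50)
  expect_equal(predict_scores(m0, env_b, "raw"),
               rep(1 / nrow(env_b), nrow(env_b)), tolerance = 1e-12)
})

test_that("suitability maps demand every model layer and propagate masks", {
  st <- make_test_stack(n = 20, seed = 21)
  st$mask[1, 1] <- TRUE
  sc <- make_scenario("identical", layer_names = c("e1", "e2"))
  occ <- sample_occurrences(gaussian_niche_suitability(sc, "groupA", st),
                            80, seed = 2)
  bg <- make_uniform_background(st$grid, 150, seed = 3)
  f <- build_features(extract_env(st, occ), extract_env(st, bg))
  m <- fit_maxent(f)
  sg <- predict_suitability(m, st, "raw")
  expect_true(sg$mask[1, 1])
  expect_true(all(sg$values[!sg$mask] >= 0))
  one_layer <- raster_stack(st$grid, st$layers["e1"])
  expect_error(predict_suitability(m, one_layer), "e2")
})

test_that("AUC follows the Mann-Whitney mid-rank definition", {
  expect_equal(evaluate_auc(c(0.9, 0.8), c(0.2, 0.1)), 1)
  expect_equal(evaluate_auc(c(0.5, 0.5), c(0.5, 0.5)), 0.5)
  expect_equal(evaluate_auc(c(0.8, 0.3), c(0.5, 0.1)), 0.75)
  # invariance under a strictly monotone transform
  set.seed(1)
  p <- runif(40); b <- runif(60)
  expect_equal(evaluate_auc(p, b), evaluate_auc(exp(3 * p), exp(3 * b)))
  expect_error(evaluate_auc(numeric(), b), "non-empty")
})

test_that("replicated validation separates informative from null niches", {
  st <- make_test_stack(n = 40, seed = 31)
  bg <- make_uniform_background(st$grid, 250, seed = 32)
  env_bg <- extract_env(st, bg)
  # informative niche (4 sigma separation from background-typical values)
  sc <- make_scenario("divergent", separation = 4, layer_names = c("e1", "e2"))
  occ <- sample_occurrences(gaussian_niche_suitability(sc, "groupA", st),
                            150, seed = 33)
  f <- build_features(extract_env(st, occ), env_bg)
  ev <- crossvalidate(f, n_replicates = 10, test_fraction = 0.2, seed = 34)
  expect_length(ev$auc, 10)
  expect_true(all(ev$auc >= 0 & ev$auc <= 1))
  expect_gt(ev$mean, 0.7)
  # presences drawn from the background distribution -> AUC ~ 0.5
  occ0 <- sample_occurrences(
    suitability_grid(st$grid, matrix(1, 40, 40)), 150, seed = 35)
  f0 <- build_features(extract_env(st, occ0), env_bg)
  ev0 <- crossvalidate(f0, n_replicates = 10, seed = 36)
  expect_lt(abs(ev0$mean - 0.5), 0.1)
  # determinism under the seed
  ev_again <- crossvalidate(f, n_replicates = 10, test_fraction = 0.2,
                            seed = 34)
  expect_identical(ev$auc, ev_again$auc)
})

test_that("percent contribution sums to 100 and credits the generative variable", {
  f <- simple_features(seed = 41)   # presence informative in e1 only
  m <- fit_maxent(f)
  pc <- percent_contribution(m)
  expect_equal(sum(pc), 100, tolerance = 0.01)
  expect_gt(pc[["e1"]], pc[["e2"]])
  # single-variable model -> 100%
  env_p <- data.frame(v = rnorm(50, 1, 0.2))
  env_b <- data.frame(v = runif(200, -2, 2))
  m1 <- fit_maxent(build_features(env_p, env_b))
  expect_equal(unname(percent_contribution(m1)), 100, tolerance = 1e-9)
  # all-zero model warns and reports zeros
  mz <- fit_maxent(f, beta_multiplier = 50)
  expect_warning(pcz <- percent_contribution(mz), "zero")
  expect_true(all(pcz == 0))
})

test_that("permutation importance vanishes for absent variables and sums to 100", {
  f <- simple_features(seed = 51)
  m <- fit_maxent(f)
  # force e2's features out of the model
  jj <- m$defs$variable == "e2"
  m$lambda[jj] <- 0
  pi_ <- permutation_importance(m, f, seed = 52)
  expect_equal(unname(pi_[["e2"]]), 0)
  expect_equal(sum(pi_), 100, tolerance = 0.01)
  expect_identical(pi_, permutation_importance(m, f, seed = 52))
})

test_that("response curves honour grid size, monotonicity and class sets", {
  # single positive linear feature -> strictly increasing curve
  env_p <- data.frame(v = rnorm(60, 1, 0.2))
  env_b <- data.frame(v = runif(200, -2, 2))
  f <- build_features(env_p, env_b, classes = "linear")
  m <- fit_maxent(f)
  expect_gt(m$lambda[["v_lin"]], 0)
  rc <- response_curve(m, "v", n_grid = 100)
  expect_equal(nrow(rc), 100)
  expect_true(all(diff(rc$suitability) > 0))
  # categorical variable -> one value per class, no interpolation
  env_pc <- data.frame(v = rnorm(60, 1, 0.2), lc = sample(1:3, 60, TRUE))
  env_bc <- data.frame(v = runif(200, -2, 2), lc = sample(1:3, 200, TRUE))
  attr(env_pc, "kind") <- c(v = "continuous", lc = "categorical")
  attr(env_bc, "kind") <- c(v = "continuous", lc = "categorical")
  mc <- fit_maxent(build_features(env_pc, env_bc))
  rcc <- response_curve(mc, "lc")
  expect_equal(rcc$value, 1:3)
  expect_error(response_curve(mc, "nope"), "not in the model")
  # replicate band is ordered
  fc <- build_features(env_pc, env_bc)
  ev <- crossvalidate(fc, n_replicates = 5, seed = 6)
  rcb <- response_curve(mc, "v", n_grid = 20, replicates = ev$models)
  expect_true(all(rcb$lower <= rcb$upper))
})
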