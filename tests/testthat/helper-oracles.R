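# Shared fixtures and independent brute-force oracles.  Every oracle here is
# a direct transcription of the defining formula or an exhaustive search; none
# shares code with the implementation it checks.

# Small landscape with two mildly correlated continuous layers.
make_test_stack <- function(n = 40, seed = 11, autocorr = 4, r = 0) {
  generate_landscape(
    grid_spec(n, n, crs = "planar"),
    list(layer_spec("e1", autocorr_length = autocorr),
         layer_spec("e2", autocorr_length = autocorr)),
    correlation = matrix(c(1, r, r, 1), 2), seed = seed)
}

# Uniform background points over a grid (survey effort, not niche).
make_uniform_background <- function(grid, n, seed) {
  uni <- suitability_grid(grid, matrix(1, grid$n_rows, grid$n_cols))
  as.data.frame(sample_occurrences(uni, n, group = "bg", seed = seed,
                                   jitter = "uniform"))[,
    c("longitude", "latitude")]
}

# Exhaustive maximum independent set under a min-distance constraint
# (feasible for <= 15 points): the true thinning optimum.
brute_thin_optimum <- function(x, y, min_distance,
                               metric = c("euclidean", "haversine")) {
  metric <- match.arg(metric)
  n <- length(x)
  stopifnot(n <= 15)
  d <- if (metric == "euclidean") as.matrix(dist(cbind(x, y))) else
    geosphere::distm(cbind(x, y), fun = function(p1, p2)
      geosphere::distHaversine(p1, p2, r = 6371008.8)) / 1000
  best <- 0L
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(idx) <= best) next
    ok <- TRUE
    if (length(idx) > 1) {
      dd <- d[idx, idx]
      ok <- min(dd[upper.tri(dd)]) >= min_distance
    }
    if (ok) best <- length(idx)
  }
  best
}

# Penalized training gain computed straight from its definition.
maxent_gain_r <- function(X, presence_rows, background_rows, lambda, beta_j) {
  eta <- drop(X %*% lambda)
  mean(eta[presence_rows]) -
    log(mean(exp(eta[background_rows]))) -
    sum(beta_j * abs(lambda))
}

# Generic convex-solver oracle: multi-start Nelder-Mead on the penalized
# gain (Brent line search in one dimension; small dimension only).
maxent_oracle_gain <- function(X, presence_rows, background_rows, beta_j,
                               starts) {
  obj <- function(l) -maxent_gain_r(X, presence_rows, background_rows, l,
                                    beta_j)
  if (ncol(starts) == 1L) {
    o <- stats::optimize(function(l) obj(l), c(-100, 100), tol = 1e-12)
    return(-o$objective)
  }
  best <- -Inf
  for (s in seq_len(nrow(starts))) {
    o <- stats::optim(starts[s, ], obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 20000))
    o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 20000))
    if (-o$value > best) best <- -o$value
  }
  best
}

# Independent greedy replay of the stepwise VIF rule, using lm() R^2.
vif_r <- function(df, vars) {
  sapply(vars, function(v) {
    r2 <- summary(lm(stats::reformulate(setdiff(vars, v), v), data = df))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  })
}

vifstep_replay <- function(df, threshold = 10) {
  vars <- sort(names(df))
  repeat {
    if (length(vars) < 2) break
    v <- vif_r(df, vars)
    if (max(v) <= threshold) break
    vars <- setdiff(vars, names(v)[which.max(v)])
  }
  vars
}

vifcor_replay <- function(df, r_threshold = 0.9) {
  vars <- sort(names(df))
  repeat {
    if (length(vars) < 2) break
    cm <- abs(cor(df[vars])); diag(cm) <- 0
    if (max(cm) <= r_threshold) break
    ij <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    pair <- sort(vars[ij])
    v <- vif_r(df, vars)
    drop <- if (v[pair[2]] > v[pair[1]]) pair[2] else pair[1]
    vars <- setdiff(vars, drop)
  }
  vars
}
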