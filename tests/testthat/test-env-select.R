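# Environmental extraction and VIF-based variable selection.

test_that("extraction returns nearest-cell values with the floor convention", {
  g <- grid_spec(4, 4, origin_x = 10, origin_y = 20, cell_size = 2)
  lonlayer <- matrix(rep(10 + (1:4) * 2 - 1, each = 4), 4, 4)  # = cell center x
  st <- raster_stack(g, list(lon = lonlayer))
  pts <- data.frame(id = 1:3,
                    longitude = c(11, 14.0, 17.9),  # 14 on the 12|14 boundary
                    latitude = c(21, 23, 25))
  env <- extract_env(st, pts)
  expect_equal(env$lon, c(11, 15, 17))  # boundary point goes to the upper cell
  expect_true(all(abs(env$lon - pts$longitude) <= g$cell_size / 2))
  # out-of-extent and nodata points are dropped and counted
  mask <- matrix(FALSE, 4, 4); mask[1, 1] <- TRUE
  stm <- raster_stack(g, list(lon = lonlayer), mask = mask)
  pts2 <- data.frame(id = 1:4, longitude = c(11, 100, 11, 13),
                     latitude = c(21, 21, 100, 23))
  env2 <- extract_env(stm, pts2)   # (11,21) masked, two outside, one valid
  expect_equal(nrow(env2), 1)
  expect_equal(unname(attr(env2, "n_dropped")),
               c(2L, 1L))  # outside, nodata
})

test_that("extraction drops masked rows but keeps the rest aligned", {
  g <- grid_spec(4, 4, cell_size = 1)
  vals <- matrix(seq_len(16), 4, 4)
  mask <- matrix(FALSE, 4, 4); mask[2, 2] <- TRUE
  st <- raster_stack(g, list(v = vals), mask = mask)
  pts <- data.frame(id = c("a", "b", "c"),
                    longitude = c(0.5, 1.5, 2.5),
                    latitude = c(0.5, 1.5, 2.5))
  env <- extract_env(st, pts)
  expect_equal(attr(env, "point_id"), c("a", "c"))
  expect_equal(unname(attr(env, "n_dropped")["nodata"]), 1L)
  expect_equal(env$v, c(vals[1, 1], vals[3, 3]))
  # every row dropped -> error
  far <- data.frame(id = 1, longitude = 50, latitude = 50)
  expect_error(extract_env(st, far), "outside")
})

test_that("VIF matches the closed forms", {
  set.seed(42)
  n <- 4000
  # mutually orthogonal designed columns -> VIF 1
  x1 <- rep(c(-1, 1), n / 2)
  x2 <- rep(c(-1, -1, 1, 1), n / 4)
  x3 <- rep(c(-1, 1, 1, -1), n / 4)
  env <- data.frame(a = x1, b = x2, c = x3)
  expect_equal(unname(compute_vif(env)), rep(1, 3), tolerance = 1e-12)
  # exact bivariate construction with r = 0.9 -> VIF = 1/(1-0.81)
  z1 <- scale(rnorm(n))[, 1]
  z2 <- scale(residuals(lm(rnorm(n) ~ z1)))[, 1]
  r <- 0.9
  y <- r * z1 + sqrt(1 - r^2) * z2
  env2 <- data.frame(u = z1, v = y)
  expect_equal(unname(compute_vif(env2)), rep(1 / (1 - 0.81), 2),
               tolerance = 1e-9)
  # exact collinearity flagged infinite
  env3 <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  env3$x3 <- env3$x1 + env3$x2
  expect_true(all(is.infinite(compute_vif(env3))))
  # constant column rejected by name
  expect_error(compute_vif(data.frame(p = rnorm(10), q = rep(1, 10))), "q")
})

test_that("vifstep drops by largest VIF until all pass the threshold", {
  set.seed(7)
  n <- 500
  x1 <- rnorm(n); x2 <- rnorm(n); x4 <- rnorm(n)
  env <- data.frame(x1 = x1, x2 = x2, x3 = x1 + x2, x4 = x4)
  rep_ <- vifstep_select(env, threshold = 10)
  expect_length(rep_$dropped, 1)
  expect_true(rep_$dropped %in% c("x1", "x2", "x3"))
  expect_true(all(rep_$vif <= 10))
  expect_true("x4" %in% rep_$retained)
  # nothing to drop when all VIF <= threshold
  env_ok <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  expect_length(vifstep_select(env_ok, 10)$dropped, 0)
})

test_that("vifcor drops the higher-VIF member of the worst pair", {
  set.seed(8)
  n <- 2000
  x1 <- rnorm(n)
  x2 <- 0.96 * x1 + sqrt(1 - 0.96^2) * rnorm(n)   # r ~ 0.96 with x1
  x3 <- 0.5 * x1 + sqrt(1 - 0.25) * rnorm(n)      # x1 carries extra burden
  env <- data.frame(x1 = x1, x2 = x2, x3 = x3)
  v <- compute_vif(env)
  rep_ <- vifcor_select(env, r_threshold = 0.9)
  expect_equal(rep_$dropped, names(which.max(v[c("x1", "x2")])))
  cm <- abs(cor(as.data.frame(env)[rep_$retained]))
  diag(cm) <- 0
  expect_lte(max(cm), 0.9)
  # below-threshold correlation: nothing dropped
  y2 <- 0.85 * x1 + sqrt(1 - 0.85^2) * rnorm(n)
  expect_length(vifcor_select(data.frame(x1 = x1, y2 = y2), 0.9)$dropped, 0)
})

test_that("both procedures match an independent greedy replay on random matrices", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 300
    base <- matrix(rnorm(n * 3), n, 3)
    mix <- matrix(runif(15, -1, 1), 3, 5)
    df <- as.data.frame(base %*% mix + 0.3 * matrix(rnorm(n * 5), n, 5))
    names(df) <- paste0("v", 1:5)
    expect_identical(vifstep_select(df, 10)$retained, vifstep_replay(df, 10))
    expect_identical(vifcor_select(df, 0.9)$retained, vifcor_replay(df, 0.9))
    expect_true(all(compute_vif(df, vifstep_select(df, 10)$retained) <= 10))
  }
})

test_that("select_variables intersects methods and passes categoricals through", {
  set.seed(9)
  n <- 400
  x1 <- rnorm(n)
  env <- data.frame(x1 = x1, x2 = x1 + rnorm(n, sd = 0.1), x3 = rnorm(n),
                    lc = sample(1:4, n, TRUE))
  attr(env, "kind") <- c(x1 = "continuous", x2 = "continuous",
                         x3 = "continuous", lc = "categorical")
  sel <- select_variables(env)
  expect_true("lc" %in% sel$retained)
  expect_identical(sort(setdiff(sel$retained, "lc")),
                   sort(intersect(sel$step$retained, sel$cor$retained)))
})
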