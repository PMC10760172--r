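# Occurrence preparation: checklist filtering, spatial thinning, balancing,
# target-group background.

make_meta_table <- function(n = 400, seed = 1) {
  g <- grid_spec(30, 30)
  occ <- sample_occurrences(suitability_grid(g, matrix(1, 30, 30)), n,
                            seed = seed)
  attach_checklist_metadata(occ, fail_fraction = 0.1, seed = seed + 1)
}

test_that("filtering attributes rejections and honours the printed bounds", {
  tab <- make_meta_table()
  cfg <- filter_config(bbox = NULL)
  kept <- filter_records(tab, cfg)
  rej <- attr(kept, "rejections")
  expect_equal(nrow(kept) + sum(rej), nrow(tab))
  # retained rows satisfy every criterion
  expect_true(all(kept$protocol %in% c("Stationary", "Traveling")))
  expect_true(all(kept$duration_minutes < 360))
  expect_true(all(kept$effort_distance_km < 10))
  expect_true(all(kept$n_observers <= 10))
  expect_true(all(kept$complete))
  expect_true(all(as.integer(substr(kept$date, 6, 7)) %in% c(6, 7)))
  yr <- as.integer(substr(kept$date, 1, 4))
  expect_true(all(yr >= 2010 & yr <= 2023))
  # boundary: duration exactly 360 is rejected (strict <)
  clean <- as.data.frame(kept)[1:2, ]   # rows passing every other criterion
  clean$duration_minutes <- c(360, 359)
  edge <- occurrence_table(clean, coord_system = "planar")
  kept_edge <- filter_records(edge, cfg)
  expect_equal(nrow(kept_edge), 1)
  expect_equal(kept_edge$duration_minutes, 359)
  # observers boundary: exactly 10 is retained (inclusive <=)
  clean2 <- as.data.frame(kept)[1:2, ]
  clean2$n_observers <- c(10L, 11L)
  edge2 <- occurrence_table(clean2, coord_system = "planar")
  expect_equal(filter_records(edge2, cfg)$n_observers, 10L)
  # idempotence (same rows retained, zero further rejections)
  twice <- filter_records(kept, cfg)
  expect_equal(twice$id, kept$id)
  expect_true(all(attr(twice, "rejections") == 0))
  # missing column named in the error
  broken <- as.data.frame(tab)
  broken$duration_minutes <- NULL
  expect_error(filter_records(occurrence_table(broken, "planar"), cfg),
               "duration_minutes")
})

test_that("first-failure attribution follows the documented criterion order", {
  tab <- make_meta_table(50, seed = 3)
  # one row violating both protocol and duration counts toward protocol only
  df <- as.data.frame(tab)
  df$protocol[1] <- "Incidental"
  df$duration_minutes[1] <- 500
  df$duration_minutes[2] <- 500
  rest_ok <- filter_records(occurrence_table(df[1:2, ], "planar"),
                            filter_config(bbox = NULL))
  rej <- attr(rest_ok, "rejections")
  expect_equal(unname(rej["protocol"]), 1L)
  expect_equal(unname(rej["duration"]), 1L)
})

test_that("distance thinning guarantees the minimum distance and finds optima", {
  # three collinear planar points at 0, 0.4, 0.8 km; min 0.5 -> endpoints
  tab <- occurrence_table(
    data.frame(id = 1:3, longitude = c(0, 0.4, 0.8), latitude = 0,
               group = "A"), coord_system = "planar")
  th <- thin_spatial(tab, thin_config(min_distance = 0.5, seed = 1))
  expect_equal(sort(th$longitude), c(0, 0.8))
  expect_equal(nrow(th), brute_thin_optimum(tab$longitude, tab$latitude, 0.5))
  # already-thinned input is unchanged
  far <- occurrence_table(
    data.frame(id = 1:4, longitude = c(0, 2, 4, 6), latitude = 0,
               group = "A"), coord_system = "planar")
  expect_identical(thin_spatial(far, thin_config(min_distance = 0.5)), far)
  # random clusters: distance guarantee on every retained pair, and the
  # greedy never beats (and here matches) the brute-force optimum
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(8:13, 1)
    tabr <- occurrence_table(
      data.frame(id = seq_len(n), longitude = runif(n, 0, 2.5),
                 latitude = runif(n, 0, 2.5), group = "A"),
      coord_system = "planar")
    thr <- thin_spatial(tabr, thin_config(min_distance = 0.7, n_repeats = 30,
                                          seed = seed))
    if (nrow(thr) > 1) {
      d <- as.matrix(dist(cbind(thr$longitude, thr$latitude)))
      expect_gte(min(d[upper.tri(d)]), 0.7)
    }
    expect_equal(nrow(thr),
                 brute_thin_optimum(tabr$longitude, tabr$latitude, 0.7))
  }
})

test_that("haversine thinning works on lon/lat tables", {
  # 0.003 deg latitude ~ 0.334 km: neighbours conflict at 0.5 km, endpoints
  # (0.667 km apart) do not -> optimum keeps the two endpoints
  tab <- occurrence_table(
    data.frame(id = 1:3, longitude = -120,
               latitude = 45 + c(0, 0.003, 0.006), group = "A"))
  th <- thin_spatial(tab, thin_config(min_distance = 0.5, seed = 2))
  expect_equal(nrow(th),
               brute_thin_optimum(tab$longitude, tab$latitude, 0.5,
                                  metric = "haversine"))
  expect_equal(nrow(th), 2)
  d <- geosphere::distHaversine(c(th$longitude[1], th$latitude[1]),
                                c(th$longitude[2], th$latitude[2]),
                                r = 6371008.8) / 1000
  expect_gte(d, 0.5)
})

test_that("balancing samples exact group sizes without replacement", {
  g <- grid_spec(30, 30)
  suit <- suitability_grid(g, matrix(1, 30, 30))
  tabs <- list(
    A = sample_occurrences(suit, 200, group = "A", seed = 1),
    B = sample_occurrences(suit, 180, group = "B", seed = 2),
    C = sample_occurrences(suit, 160, group = "C", seed = 3))
  bal <- balance_groups(tabs, 150, seed = 9)
  expect_equal(unname(table(bal$group)), rep(150L, 3), ignore_attr = TRUE)
  expect_true(all(bal$id %in% c(tabs$A$id, tabs$B$id, tabs$C$id)))
  expect_false(anyDuplicated(bal$id) > 0)
  # group with exactly n rows is returned whole
  bal2 <- balance_groups(tabs, 160, seed = 9)
  expect_setequal(bal2$id[bal2$group == "C"], tabs$C$id)
  # determinism and shortfall reporting
  expect_identical(balance_groups(tabs, 150, seed = 9),
                   balance_groups(tabs, 150, seed = 9))
  expect_error(balance_groups(tabs, 190, seed = 1), "C.*short by 30")
})

test_that("target-group background is uniform when effort is uniform", {
  g <- grid_spec(40, 40)
  all_sp <- sample_occurrences(suitability_grid(g, matrix(1, 40, 40)), 4000,
                               group = "all", seed = 12)
  bg <- target_group_background(all_sp, 1000, seed = 13)
  expect_equal(nrow(bg), 1000)
  expect_named(bg, c("longitude", "latitude"))
  # quadrant chi-square: approximately uniform density
  qx <- bg$longitude > 20; qy <- bg$latitude > 20
  counts <- table(qx, qy)
  expect_gt(chisq.test(as.vector(counts))$p.value, 0.001)
  # determinism and shortfall
  expect_identical(bg, target_group_background(all_sp, 1000, seed = 13))
  expect_error(target_group_background(all_sp, 5000, seed = 1), "candidate")
})
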