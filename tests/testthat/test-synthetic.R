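# Synthetic-data module: landscapes, niche surfaces, occurrence sampling,
# checklist metadata.

test_that("landscape generation is deterministic and matches target correlations", {
  g <- grid_spec(200, 200)
  ls <- list(layer_spec("a", autocorr_length = 3),
             layer_spec("b", autocorr_length = 3))
  C <- matrix(c(1, 0.9, 0.9, 1), 2)
  st1 <- generate_landscape(g, ls, C, seed = 7)
  st2 <- generate_landscape(g, ls, C, seed = 7)
  expect_identical(st1, st2)
  r <- cor(as.vector(st1$layers$a), as.vector(st1$layers$b))
  expect_lt(abs(r - 0.9), 0.05)
  # independent layers stay near zero (wider band: autocorrelation shrinks
  # the effective sample size)
  st0 <- generate_landscape(g, ls, seed = 8)
  expect_lt(abs(cor(as.vector(st0$layers$a), as.vector(st0$layers$b))), 0.1)
})

test_that("categorical layers carry the requested classes in near-equal areas", {
  st <- generate_landscape(
    grid_spec(100, 100),
    list(layer_spec("lc", "categorical", autocorr_length = 4, n_classes = 19)),
    seed = 2)
  codes <- as.vector(st$layers$lc)
  expect_setequal(unique(codes), 1:19)
  areas <- table(codes)
  # quantile construction: each class covers ~ 1/19 of 10000 cells
  expect_lt(max(abs(areas - 10000 / 19)), 10000 / 19 * 0.05 + 1)
})

test_that("landscape generation rejects invalid correlation targets", {
  g <- grid_spec(10, 10)
  ls <- list(layer_spec("a"), layer_spec("b"))
  bad <- matrix(c(1, 2, 2, 1), 2)       # not PSD
  expect_error(generate_landscape(g, ls, bad, seed = 1), "semi-definite")
  asym <- matrix(c(1, 0.2, 0.6, 1), 2)  # not symmetric
  expect_error(generate_landscape(g, ls, asym, seed = 1), "symmetric")
})

test_that("gaussian niche suitability follows the product formula", {
  g <- grid_spec(3, 3)
  st <- raster_stack(g, list(e1 = matrix(5, 3, 3)))
  sc <- niche_scenario("A", matrix(5, 1, 1, dimnames = list("A", "e1")),
                       matrix(2, 1, 1, dimnames = list("A", "e1")))
  expect_equal(unname(gaussian_niche_suitability(sc, "A", st)$values),
               matrix(1, 3, 3))
  # one sigma from the optimum -> exp(-1/2)
  st2 <- raster_stack(g, list(e1 = matrix(7, 3, 3)))
  expect_equal(gaussian_niche_suitability(sc, "A", st2)$values[1, 1],
               exp(-0.5))
  # two-layer product with a categorical weight
  stc <- raster_stack(g, list(e1 = matrix(7, 3, 3), lc = matrix(2L, 3, 3)),
                      kind = c("continuous", "categorical"))
  scc <- niche_scenario("A", matrix(5, 1, 1, dimnames = list("A", "e1")),
                        matrix(2, 1, 1, dimnames = list("A", "e1")),
                        class_weights = list(lc = matrix(c(1, 0.25), 1)))
  expect_equal(gaussian_niche_suitability(scc, "A", stc)$values[2, 2],
               exp(-0.5) * 0.25)
  # identical parameters for two groups -> identical surfaces
  sc2 <- niche_scenario(c("A", "B"),
                        matrix(5, 2, 1, dimnames = list(c("A", "B"), "e1")),
                        matrix(2, 2, 1, dimnames = list(c("A", "B"), "e1")))
  expect_identical(gaussian_niche_suitability(sc2, "A", st2)$values,
                   gaussian_niche_suitability(sc2, "B", st2)$values)
  # missing parameters are rejected by layer name
  expect_error(gaussian_niche_suitability(sc, "A", stc), "lc")
})

test_that("occurrence sampling respects the multinomial cell probabilities", {
  g <- grid_spec(1, 2)
  suit <- suitability_grid(g, matrix(c(3, 1), 1, 2))
  occ <- sample_occurrences(suit, 4000, seed = 5, jitter = "none")
  n_first <- sum(occ$longitude < 1)
  expect_gt(chisq.test(c(n_first, 4000 - n_first), p = c(3, 1) / 4)$p.value,
            0.001)
  # zero-probability cells are never sampled
  g2 <- grid_spec(10, 10)
  v <- matrix(0, 10, 10); v[1:3, 1:3] <- 1
  occ2 <- sample_occurrences(suitability_grid(g2, v), 500, seed = 6)
  expect_true(all(occ2$longitude < 3 & occ2$latitude < 3))
  # determinism and failure on all-zero surfaces
  expect_identical(sample_occurrences(suit, 50, seed = 9),
                   sample_occurrences(suit, 50, seed = 9))
  expect_error(sample_occurrences(
    suitability_grid(g2, matrix(0, 10, 10)), 5, seed = 1), "positive")
})

test_that("sampled occurrences recover the niche optimum", {
  st <- make_test_stack(n = 60, seed = 13)
  sc <- make_scenario("identical", layer_names = c("e1", "e2"))
  suit <- gaussian_niche_suitability(sc, "groupA", st)
  occ <- sample_occurrences(suit, 800, seed = 3, jitter = "none")
  env <- extract_env(st, occ)
  # sample mean of the niche variable within 2 SE of mu = 0
  se <- sd(env$e1) / sqrt(nrow(env))
  expect_lt(abs(mean(env$e1) - 0), 2 * se + 1e-9)
})

test_that("checklist metadata plants violations exactly as its ledger says", {
  g <- grid_spec(20, 20)
  suit <- suitability_grid(g, matrix(1, 20, 20))
  occ <- sample_occurrences(suit, 1000, seed = 4)
  # no violations -> everything survives the default filter
  clean <- attach_checklist_metadata(occ, fail_fraction = 0, seed = 10)
  kept <- filter_records(clean, filter_config(bbox = NULL))
  expect_equal(nrow(kept), 1000)
  expect_true(all(attr(kept, "rejections") == 0))
  # 20% duration violations, ledgered
  dirty <- attach_checklist_metadata(occ, fail_fraction = c(duration = 0.2),
                                     seed = 10)
  ledger <- attr(dirty, "fail_ledger")
  expect_length(ledger$duration, 200)
  expect_true(all(dirty$duration_minutes[dirty$id %in% ledger$duration] >= 360))
  kept2 <- filter_records(dirty, filter_config(bbox = NULL))
  expect_setequal(kept2$id, setdiff(dirty$id, ledger$duration))
  # determinism
  expect_identical(dirty,
                   attach_checklist_metadata(occ,
                                             fail_fraction = c(duration = 0.2),
                                             seed = 10))
})

test_that("canned scenarios encode the requested niche geometry", {
  sc0 <- make_scenario("identical")
  expect_true(all(dist(sc0$optima) == 0))
  sc4 <- make_scenario("divergent", separation = 4)
  expect_equal(abs(sc4$optima[1, 1] - sc4$optima[2, 1]) / sc4$breadths[1, 1], 4)
  sc3 <- make_scenario("three_group", separation = 4)
  h <- sc3$optima["hybrid", ]
  mid <- (sc3$optima[1, ] + sc3$optima[2, ]) / 2
  expect_gt(sqrt(sum((h - sc3$optima[1, ])^2)), 0)
  expect_gt(sqrt(sum((h - sc3$optima[2, ])^2)), 0)
  expect_gt(sqrt(sum((h - mid)^2)), 0)  # not merely intermediate
  expect_error(make_scenario("divergent", separation = -1), "separation")
})
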