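cell_stack <- function(members, grid = make_grid(1, 1)) {
  ensemble_stack(grid, sprintf("m%02d", seq_along(members)),
                 array(members, c(length(members), 1, 1)), "x", "fuzzy truth")
}

test_that("reduce_stack computes per-cell min/mean/max across members", {
  s <- cell_stack(c(0.2, 0.4, 0.9))
  expect_equal(reduce_stack(s, "min")$values[1, 1], 0.2)
  expect_equal(reduce_stack(s, "mean")$values[1, 1], 0.5)
  expect_equal(reduce_stack(s, "max")$values[1, 1], 0.9)

  g <- make_grid(4, 4)
  l <- rand_fuzzy(g)
  same <- layers_to_stack(list(a = l, b = l, c = l), "x")
  for (st in c("min", "mean", "max")) {
    expect_equal(reduce_stack(same, st)$values, l$values)
  }
  one <- cell_stack(0.7)
  for (st in c("min", "mean", "max")) {
    expect_equal(reduce_stack(one, st)$values[1, 1], 0.7)
  }
})

test_that("pointwise min <= mean <= max after reduction, everywhere", {
  set.seed(13)
  g <- make_grid(6, 6)
  s <- rand_stack(g, 7)
  m <- g$valid_mask
  expect_true(all(reduce_stack(s, "min")$values[m] <= reduce_stack(s, "mean")$values[m]))
  expect_true(all(reduce_stack(s, "mean")$values[m] <= reduce_stack(s, "max")$values[m]))
})

test_that("high_variability converts population sd with thresholds (0, 0.5)", {
  # half members at 0, half at 1: population sd attains its maximum 0.5
  s <- cell_stack(rep(c(0, 1), each = 10))
  expect_equal(high_variability(s)$values[1, 1], 1)
  # all equal: zero dispersion
  expect_equal(high_variability(cell_stack(rep(0.42, 20)))$values[1, 1], 0)
  # 1 member at 1, 19 at 0: sd = sqrt(0.05 * 0.95), fuzzified = 2 * sd
  s2 <- cell_stack(c(1, rep(0, 19)))
  expect_equal(high_variability(s2)$values[1, 1], 2 * sqrt(0.05 * 0.95),
               tolerance = 1e-12)
  expect_error(high_variability(cell_stack(0.5)), "at least 2")
  # sample variant is larger wherever members disagree
  expect_gt(high_variability(s2, sd = "sample")$values[1, 1],
            high_variability(s2)$values[1, 1])
})

test_that("high_variability is 0 iff all members agree, and permutation-invariant", {
  set.seed(14)
  g <- make_grid(5, 5)
  s <- rand_stack(g, 6)
  # plant agreement at two cells
  s$values[, 2, 3] <- 0.31
  s$values[, 4, 1] <- 0.9
  hv <- high_variability(s)
  expect_identical(hv$values[2, 3], 0)
  expect_identical(hv$values[4, 1], 0)
  disagree <- apply(s$values, c(2, 3), function(v) max(v) > min(v))
  expect_true(all((hv$values > 0)[disagree]))
  perm <- sample(6)
  s2 <- ensemble_stack(g, s$member_ids[perm], s$values[perm, , ], "x")
  expect_equal(high_variability(s2)$values, hv$values)
})

test_that("area_weighted_mean matches the weighted-sum definition", {
  g <- make_grid(1, 2, weights = matrix(c(1, 3), 1, 2))
  expect_equal(area_weighted_mean(make_layer(c(0, 1), g)), 0.75)
  gu <- make_grid(2, 3)
  v <- c(1, 2, 3, 4, 5, 6)
  expect_equal(area_weighted_mean(make_layer(v, gu)), mean(v))
  expect_equal(area_weighted_mean(make_layer(rep(0.4, 2), g)), 0.4)
  # linear in the layer, bounded by min and max
  set.seed(15)
  gw <- make_grid(4, 4, weights = matrix(runif(16), 4, 4))
  a <- make_layer(runif(16), gw); b <- make_layer(runif(16), gw)
  expect_equal(area_weighted_mean(make_layer(2 * a$values + 3 * b$values, gw)),
               2 * area_weighted_mean(a) + 3 * area_weighted_mean(b))
  expect_gte(area_weighted_mean(a), min(a$values))
  expect_lte(area_weighted_mean(a), max(a$values))
  gz <- make_grid(2, 2, weights = matrix(0, 2, 2))
  expect_error(area_weighted_mean(make_layer(rep(1, 4), gz)), "zero total weight")
})

test_that("scenario_summary brackets the regional risk", {
  g <- make_grid(3, 3)
  const <- fuzzy_layer(g, matrix(0.37, 3, 3))
  s <- layers_to_stack(list(a = const, b = const, c = const), "risk")
  sm <- scenario_summary(s)
  expect_equal(sm$mean, 0.37)
  expect_equal(sm$min, 0.37)
  expect_equal(sm$max, 0.37)
  expect_equal(sm$uncertainty, 0)
  expect_length(sm$member_means, 3L)

  set.seed(16)
  sr <- rand_stack(g, 8)
  smr <- scenario_summary(sr)
  expect_lte(smr$min, smr$mean)
  expect_lte(smr$mean, smr$max)
  expect_true(all(c(smr$min, smr$mean, smr$max, smr$uncertainty) >= 0))
  expect_true(all(c(smr$min, smr$mean, smr$max, smr$uncertainty) <= 1))
  expect_equal(mean(smr$member_means), smr$mean)
})

test_that("scenario_pair_uncertainty follows the paired |a - b| construction", {
  g <- make_grid(2, 2)
  mk <- function(v) layers_to_stack(list(m1 = fuzzy_layer(g, matrix(v, 2, 2))), "x")
  expect_equal(scenario_pair_uncertainty(mk(0.2), mk(0.6)), 0.4)
  expect_equal(scenario_pair_uncertainty(mk(0), mk(1)), 1)
  set.seed(17)
  s <- rand_stack(g, 4)
  expect_equal(scenario_pair_uncertainty(s, s), 0)
  # members matched by id, not position
  perm <- c(3, 1, 4, 2)
  s2 <- ensemble_stack(g, s$member_ids[perm], s$values[perm, , ], "x")
  expect_equal(scenario_pair_uncertainty(s, s2), 0)
  s3 <- ensemble_stack(g, paste0("other", 1:4), s$values, "x")
  expect_error(scenario_pair_uncertainty(s, s3), "unmatched member ids")
  # pooling two identical ensembles preserves their internal dispersion
  expect_equal(scenario_pair_uncertainty(s, s, method = "pooled"),
               area_weighted_mean(high_variability(s)))
})
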