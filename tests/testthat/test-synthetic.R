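test_that("synthetic_config validates its stated world", {
  expect_error(synthetic_config(n_members = 1), "n_members")
  expect_error(synthetic_config(zero_biomass_fraction = 1), "zero_biomass_fraction")
  expect_error(synthetic_config(periods = data.frame(
    name = c("baseline", "early"), forcing = c(0.1, 0.5))), "baseline")
  expect_error(synthetic_config(periods = data.frame(
    name = c("baseline", "a", "b"), forcing = c(0, 0.8, 0.4))), "nondecreasing")
  cfg <- synthetic_config()
  expect_equal(cfg$n_members, 20L)
  expect_equal(cfg$zero_biomass_fraction, 0.11)
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- synthetic_config(n_rows = 12, n_cols = 12, n_members = 3, seed = 5)
  b1 <- generate_bundle(cfg)
  b2 <- generate_bundle(cfg)
  expect_identical(b1$observed_biomass$values, b2$observed_biomass$values)
  expect_identical(b1$scenarios$rcp85_nfs$late$stacks$mc2_fire_frequency$values,
                   b2$scenarios$rcp85_nfs$late$stacks$mc2_fire_frequency$values)
  expect_identical(b1$scenarios$rcp45_fs$mid$veg_series$cf02$values,
                   b2$scenarios$rcp45_fs$mid$veg_series$cf02$values)
  b3 <- generate_bundle(synthetic_config(n_rows = 12, n_cols = 12,
                                         n_members = 3, seed = 6))
  expect_false(identical(b1$observed_biomass$values, b3$observed_biomass$values))
})

test_that("observed biomass has the exact zero-cell count", {
  b <- small_bundle()
  n_valid <- sum(b$grid$valid_mask)
  k <- sum(fuzzyrisk:::valid_values(b$observed_biomass) == 0)
  expect_identical(k, as.integer(ceiling(0.11 * n_valid)))
})

test_that("generated values respect their physical bounds", {
  b <- small_bundle()
  for (sn in names(b$scenarios)) for (pn in names(b$scenarios[[sn]])) {
    st <- b$scenarios[[sn]][[pn]]$stacks
    m <- b$grid$valid_mask
    for (i in seq_along(b$member_ids)) {
      ff <- st$mc2_fire_frequency$values[i, , ][m]
      expect_true(all(ff >= 0 & ff <= 1))
      expect_true(all(st$mc2_biomass_burned$values[i, , ][m] >= 0))
      expect_true(all(st$mc2_biomass$values[i, , ][m] > 0))
      expect_true(all(st$mc2_live_biomass$values[i, , ][m] > 0))
      expect_true(all(st$precip$values[i, , ][m] >= 0))
    }
    for (vs in b$scenarios[[sn]][[pn]]$veg_series) {
      for (y in seq_along(vs$years)) {
        expect_true(all(vs$values[y, , ][m] %in% b$departure_table$types))
      }
    }
  }
  expect_true(all(fuzzyrisk:::valid_values(b$observed_biomass) >= 0))
})

test_that("null forcing reproduces the baseline world in expectation", {
  cfg <- synthetic_config(
    n_rows = 25, n_cols = 25, n_members = 4, seed = 21,
    scenarios = data.frame(name = "null", rcp_forcing = 0, fire_mult = 1))
  b <- generate_bundle(cfg)
  sp <- b$scenarios$null$late
  expect_true(all(sp$deltas$delta_temperature == 0))
  expect_true(all(sp$deltas$delta_precipitation == 0))
  m <- b$grid$valid_mask
  base_ff <- b$baseline$mc2_fire_frequency$values[m]
  mean_ff <- apply(sp$stacks$mc2_fire_frequency$values, c(2, 3), mean)[m]
  expect_lt(abs(mean(mean_ff) - mean(base_ff)), 0.05)
  # departures are near zero: no warming shift, only annual noise
  dep <- fuzzyrisk:::departure_stack(b, "null", "late")
  expect_lt(mean(apply(dep$values, c(2, 3), mean)[m]), 0.2)
})

test_that("bundle write/read round trip preserves everything the pipeline uses", {
  cfg <- synthetic_config(n_rows = 8, n_cols = 9, n_members = 2, seed = 9,
                          n_veg_years = 3)
  b <- generate_bundle(cfg)
  d <- file.path(tempdir(), "bundlert")
  man <- write_bundle(b, d)
  b2 <- read_bundle(man)
  expect_true(same_grid(b$grid, b2$grid))
  expect_identical(b2$member_ids, b$member_ids)
  expect_identical(b2$observed_biomass$values, b$observed_biomass$values)
  for (v in c("mc2_biomass_burned", "mc2_fire_frequency", "mc2_biomass",
              "mc2_live_biomass", "tmax", "precip")) {
    expect_identical(b2$baseline[[v]]$values, b$baseline[[v]]$values)
    expect_identical(b2$scenarios$rcp85_fs$mid$stacks[[v]]$values,
                     b$scenarios$rcp85_fs$mid$stacks[[v]]$values)
  }
  expect_identical(b2$baseline$veg_series$values, b$baseline$veg_series$values)
  expect_identical(b2$scenarios$rcp45_nfs$early$veg_series$cf01$values,
                   b$scenarios$rcp45_nfs$early$veg_series$cf01$values)
  expect_identical(b2$departure_table$matrix, b$departure_table$matrix)
  expect_equal(b2$scenarios$rcp45_fs$late$deltas$delta_temperature,
               b$scenarios$rcp45_fs$late$deltas$delta_temperature)
  # manifest lists the four MC2 stacks for every scenario-period
  manifest <- jsonlite::read_json(man, simplifyVector = TRUE)
  for (sn in names(manifest$scenarios)) for (pn in names(manifest$scenarios[[sn]])) {
    expect_true(all(c("mc2_biomass_burned", "mc2_fire_frequency", "mc2_biomass",
                      "mc2_live_biomass") %in%
                      names(manifest$scenarios[[sn]][[pn]]$stacks)))
  }
  # unwritable destination errors
  f <- file.path(tempdir(), "plainfile"); writeLines("x", f)
  expect_error(write_bundle(b, file.path(f, "sub")), "cannot create")
})
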