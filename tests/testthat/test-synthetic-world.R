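test_that("identical configs and seeds give bit-identical worlds", {
  cfg <- world_config(grid_rows = 25, grid_cols = 25, n_years = 1, seed = 99)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(w1$yield$values, w2$yield$values)
  expect_identical(w1$daily_temp_C, w2$daily_temp_C)
  expect_identical(w1$covariates$machinery$values, w2$covariates$machinery$values)
  expect_identical(w1$truth$noise_field$values, w2$truth$noise_field$values)
})

test_that("zero-noise worlds realize the deterministic response exactly", {
  w <- generate_world(world_config(grid_rows = 25, grid_cols = 25, n_years = 1,
                                   noise_cv = 0, seed = 5))
  det <- true_yield(w$covariates, w$truth$potential_yield, w$truth$response_params)
  mask <- crop_mask(w)
  expect_equal(w$yield$values[mask], det$values[mask])
  expect_true(all(w$truth$noise_field$values == 1))
})

test_that("input rates are positively correlated over cropland", {
  w <- generate_world(world_config(seed = 1))
  mask <- crop_mask(w)
  expect_gt(cor(w$covariates$n_rate$values[mask], w$covariates$p_rate$values[mask]), 0)
  expect_gt(cor(w$covariates$n_rate$values[mask], w$covariates$k_rate$values[mask]), 0)
  expect_gt(cor(w$covariates$p_rate$values[mask],
                w$covariates$pest_herbicide$values[mask]), 0)
})

test_that("world structure honours its contracts", {
  w <- tiny_world()
  mask <- crop_mask(w)
  # yield positive wherever harvested area positive
  expect_true(all(w$yield$values[mask] > 0))
  expect_true(all(is.na(w$yield$values[!mask])))
  # covariates nonnegative, irrigation a percentage
  for (nm in model_covariates()) {
    expect_true(all(w$covariates[[nm]]$values >= 0), info = nm)
  }
  expect_true(all(w$covariates$irrigation_share$values <= 100))
  # machinery and labour constant within each country
  ctry <- w$country_id$values
  for (nm in c("machinery", "labour")) {
    per_country <- tapply(w$covariates[[nm]]$values, ctry, function(x) length(unique(x)))
    expect_true(all(per_country == 1), info = nm)
  }
})

test_that("too-small grids and bad parameters are rejected", {
  expect_error(world_config(grid_rows = 10, grid_cols = 10), "grid too small")
  expect_error(world_config(noise_cv = -0.1))
  expect_error(response_params(gamma = -1), "nonnegative")
  expect_error(response_params(floor = c(n_rate = 1.2)), "floors must be < 1")
  expect_error(response_params(k = c(n_rate = 1), floor = c(p_rate = 0)),
               "named over the same")
})

test_that("single-input saturating response matches hand evaluation", {
  # one cell, Y_pot = 10, single input with k*x = log(2), no floor,
  # no irrigation boost, neutral soil: factor 1/2, yield 5
  params <- response_params(k = c(n_rate = 1), floor = c(n_rate = 0),
                            gamma = 0, soil_depress = 0)
  gf1 <- function(x) grid_field(matrix(x, 1, 1))
  covs <- list(n_rate = gf1(log(2)), irrigation_share = gf1(0), soil_oc = gf1(1))
  y <- true_yield(covs, gf1(10), params)
  expect_equal(y$values[1, 1], 5.0)

  # saturation limit: huge input -> yield -> Y_pot
  y_inf <- true_yield(list(n_rate = gf1(1e6), irrigation_share = gf1(0),
                           soil_oc = gf1(1)), gf1(10), params)
  expect_equal(y_inf$values[1, 1], 10, tolerance = 1e-12)

  # zero input with zero floor kills the factor; default floors keep it positive
  y0 <- true_yield(list(n_rate = gf1(0), irrigation_share = gf1(0),
                        soil_oc = gf1(1)), gf1(10), params)
  expect_equal(y0$values[1, 1], 0)
})

test_that("counterfactuals are noise-matched and match hand evaluation", {
  w <- tiny_world()
  sc0 <- shock_scenario("none", shockable_covariates(), 0)
  expect_identical(true_counterfactual(w, sc0)$values, w$yield$values)

  # 50% shock on k*x = log(2): factor 1 - 2^(-1/2), yield ~ 2.929
  params <- response_params(k = c(n_rate = 1), floor = c(n_rate = 0),
                            gamma = 0, soil_depress = 0)
  gf1 <- function(x) grid_field(matrix(x, 1, 1))
  covs <- list(n_rate = gf1(log(2) / 2), irrigation_share = gf1(0), soil_oc = gf1(1))
  y <- true_yield(covs, gf1(10), params)
  expect_equal(y$values[1, 1], 10 * (1 - 2^(-0.5)), tolerance = 1e-12)
  expect_equal(y$values[1, 1], 2.9289, tolerance = 1e-4)
})

test_that("the true response is monotone nondecreasing in every shockable input", {
  w <- tiny_world()
  set.seed(31)
  cells <- sample(which(crop_mask(w)), 40)
  base <- true_yield(w$covariates, w$truth$potential_yield, w$truth$response_params)
  for (nm in shockable_covariates()) {
    bumped <- w$covariates
    bumped[[nm]]$values <- bumped[[nm]]$values * 1.25
    up <- true_yield(bumped, w$truth$potential_yield, w$truth$response_params)
    expect_true(all(up$values[cells] >= base$values[cells]), info = nm)
  }
})
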