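gfm <- function(v, n = 4, p = 5) grid_field(matrix(v, n, p))

test_that("high/low pesticide estimates average cellwise", {
  set.seed(21)
  hi <- gfm(runif(20, 1, 3)); lo <- gfm(runif(20, 0, 1))
  m <- pesticide_mean_estimate(hi, lo)
  expect_equal(m$values, (hi$values + lo$values) / 2)
  expect_equal(pesticide_mean_estimate(hi, hi)$values, hi$values)
  expect_equal(pesticide_mean_estimate(gfm(2), gfm(0))$values, matrix(1, 4, 5))
})

test_that("pesticide rescaling divides by the 97.5th percentile and caps at 1", {
  # constant positive field: the percentile equals the constant -> all ones
  expect_true(all(rescale_pesticide(gfm(3.7))$values == 1))
  # all-zero field stays zero (degenerate-percentile rule)
  expect_true(all(rescale_pesticide(gfm(0))$values == 0))
  # rates 1..40: type-7 quantile is 39.025; spot values follow exactly
  r <- rescale_pesticide(grid_field(matrix(1:40, 5, 8)))
  h <- (40 - 1) * 0.975 + 1          # type-7 interpolation position
  q <- 39 * (1 - (h - floor(h))) + 40 * (h - floor(h))
  expect_equal(q, 39.025)
  expect_equal(r$values[which(matrix(1:40, 5, 8) == 20)], 20 / 39.025)
  expect_equal(r$values[which(matrix(1:40, 5, 8) == 40)], 1)
  expect_true(all(r$values >= 0 & r$values <= 1))
  expect_error(rescale_pesticide(gfm(-1)), "nonnegative")
})

test_that("rescaling is idempotent only once the maximum is at most 1", {
  set.seed(2)
  r1 <- rescale_pesticide(gfm(runif(20, 0, 9)))
  r2 <- rescale_pesticide(r1)
  # the output maximum is 1, so a second pass rescales by its own 97.5th
  # percentile (< 1) and is NOT the identity
  expect_false(isTRUE(all.equal(r1$values, r2$values)))
})

test_that("pesticide grouping sums rescaled members per group", {
  set.seed(14)
  paper_map <- c(
    setNames(rep("Herbicides", 8), paste0("herb", 1:8)),
    setNames(rep("Insecticides", 6), paste0("ins", 1:6)),
    setNames(rep("Fungicides", 4), paste0("fun", 1:4)),
    setNames(rep("Others", 2), paste0("oth", 1:2))
  )
  fields <- lapply(setNames(nm = names(paper_map)), function(i) gfm(runif(20)))
  g <- group_pesticides(fields, paper_map)
  # elementwise-sum oracle per group
  for (grp in unique(paper_map)) {
    nm <- c(Herbicides = "pest_herbicide", Insecticides = "pest_insecticide",
            Fungicides = "pest_fungicide", Others = "pest_other")[[grp]]
    oracle <- Reduce(`+`, lapply(fields[names(paper_map)[paper_map == grp]],
                                 function(f) f$values))
    expect_equal(g[[nm]]$values, oracle)
  }
  # one pesticide per group passes through; duplicates double
  single <- group_pesticides(fields["herb1"], paper_map["herb1"])
  expect_equal(single$pest_herbicide$values, fields$herb1$values)
  expect_true(all(single$pest_insecticide$values == 0))
  twice <- group_pesticides(list(a = fields$herb1, b = fields$herb1),
                            c(a = "Herbicides", b = "Herbicides"))
  expect_equal(twice$pest_herbicide$values, 2 * fields$herb1$values)
  expect_error(group_pesticides(fields, paper_map[-1]), "missing from group map")
})

test_that("missing machinery values take their continent's unweighted mean", {
  cont <- c(a = "AF", b = "AF", c = "AF", d = "EU", e = "EU")
  full <- c(a = 10, b = 20, c = 30, d = 5, e = 7)
  expect_identical(fill_machinery(full, cont), full)
  expect_equal(fill_machinery(c(a = 10, b = NA, d = 5, e = 7), cont)[["b"]], 10)
  expect_equal(fill_machinery(c(a = 10, b = 20, c = NA, d = 5, e = 7), cont)[["c"]], 15)
  expect_error(fill_machinery(c(a = 10, d = NA, e = NA), cont), "no machinery data")
})

test_that("irrigation share is a percentage of harvested area", {
  tot <- gfm(100); irr <- gfm(25)
  expect_true(all(irrigation_share(irr, tot)$values == 25))
  expect_true(all(irrigation_share(tot, tot)$values == 100))
  z <- irrigation_share(gfm(0), gfm(0))
  expect_true(all(z$values == 0))
  expect_error(irrigation_share(gfm(-1), tot), "nonnegative")
  expect_error(irrigation_share(gfm(150), tot), "exceeds")
})

test_that("soil density converts and aggregates to a t/ha stock", {
  expect_true(all(soil_to_t_ha(gfm(0))$values == 0))
  # uniform 100 hg/m3 over 0.3 m -> 30 t/ha
  expect_true(all(soil_to_t_ha(gfm(100), depth_m = 0.3)$values == 30))
  # 2x2 fine block {10,20,30,40} -> mean 25 -> 7.5 t/ha
  fine <- grid_field(matrix(c(10, 30, 20, 40), 2, 2), cell_size = 0.5)
  coarse <- soil_to_t_ha(fine, depth_m = 0.3, factor = 2)
  expect_equal(dim(coarse$values), c(1L, 1L))
  expect_equal(coarse$values[1, 1], 7.5)
  expect_equal(coarse$cell_size, 1)
  expect_error(soil_to_t_ha(grid_field(matrix(1, 3, 3)), factor = 2),
               "integer multiple")
})

test_that("the feature table partitions cropland and round-trips cell values", {
  w <- tiny_world()
  bins <- bin_world(w)
  ft <- tiny_features()
  expect_equal(nrow(ft), sum(crop_mask(w)))
  expect_setequal(names(ft), c("cell", "row", "col", "bin_id", "country_id",
                               "harvested_area", model_covariates(), "yield"))
  # a row's values round-trip to the grid exactly
  i <- 57
  expect_identical(ft$yield[i], w$yield$values[ft$cell[i]])
  expect_identical(ft$n_rate[i], w$covariates$n_rate$values[ft$cell[i]])
  expect_identical(ft$soil_oc[i], w$covariates$soil_oc$values[ft$cell[i]])
  expect_identical(w$yield$values[cbind(ft$row[i], ft$col[i])], ft$yield[i])
  # bins partition the rows
  expect_equal(sum(table(ft$bin_id)), nrow(ft))
})

test_that("the default world populates all 25 bins with non-empty tables", {
  run <- study_run()
  expect_equal(sort(unique(run$features$bin_id)), 1:25)
  expect_true(all(table(run$features$bin_id) > 0))
})
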