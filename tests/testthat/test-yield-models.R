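test_that("spatial blocks are assigned whole to train or test", {
  ft <- tiny_features()
  ctl <- model_control(block_size_cells = 12, train_fraction = 0.75, seed = 5)
  sp <- spatial_block_split(ft, ctl)
  # partition: every row in exactly one set
  expect_equal(sum(sp$train) + sum(!sp$train), nrow(ft))
  # no block contributes to both sets
  expect_length(intersect(unique(sp$block_id[sp$train]),
                          unique(sp$block_id[!sp$train])), 0)
  expect_setequal(c(sp$train_blocks, sp$test_blocks), unique(sp$block_id))
})

test_that("the training share of blocks follows floor(fraction * n_blocks)", {
  # 100 blocks of 12x12 cells: one cell in each block is enough
  ft <- expand.grid(bi = 0:9, bj = 0:9)
  ft <- data.frame(row = ft$bi * 12 + 1, col = ft$bj * 12 + 1)
  sp <- spatial_block_split(ft, model_control(train_fraction = 0.75, seed = 2))
  expect_length(sp$train_blocks, 75)
  expect_length(sp$test_blocks, 25)
  # two blocks: one train, one test, perfectly disjoint
  ft2 <- data.frame(row = c(1, 1, 13, 13), col = c(1, 2, 1, 2))
  sp2 <- spatial_block_split(ft2, model_control(train_fraction = 0.75, seed = 1))
  expect_length(sp2$train_blocks, 1)
  expect_length(sp2$test_blocks, 1)
  expect_error(spatial_block_split(data.frame(row = 1:3, col = 1:3),
                                   model_control()), "at least 2")
})

test_that("no block leaks across train and test over many seeds", {
  ft <- tiny_features()
  ctl <- model_control(block_size_cells = 12)
  for (s in 1:100) {
    sp <- spatial_block_split(ft, ctl, seed = s)
    leak <- intersect(unique(sp$block_id[sp$train]), unique(sp$block_id[!sp$train]))
    expect_length(leak, 0)
  }
})

test_that("a constant training target predicts that constant", {
  ft <- tiny_features()
  ft$yield <- 3.25
  ctl <- model_control(n_trees = 50, n_iterations = 1, min_bin_rows = 5, seed = 2)
  fit <- suppressWarnings(fit_yield_models(ft, ctl))
  ok <- !is.na(fit$baseline_mean)
  expect_true(any(ok))
  expect_equal(fit$baseline_mean[ok], rep(3.25, sum(ok)))
})

test_that("forest predictions stay inside the training-yield range", {
  ft <- tiny_features()
  ctl <- model_control(n_trees = 100, n_iterations = 2, min_bin_rows = 10, seed = 4)
  fit <- suppressWarnings(fit_yield_models(ft, ctl))
  for (it in fit$iterations) {
    tr_range <- range(ft$yield[it$split$train])
    pr <- it$baseline[!is.na(it$baseline)]
    expect_true(all(pr >= tr_range[1] - 1e-12 & pr <= tr_range[2] + 1e-12))
  }
  # the same bound holds under an extreme scenario (mean-of-leaves property)
  ctrl_pred <- predict(fit, scenario = scenario_catalogue()$control)
  pr <- ctrl_pred[!is.na(ctrl_pred)]
  expect_true(all(pr >= min(ft$yield) - 1e-12 & pr <= max(ft$yield) + 1e-12))
})

test_that("the full fit is reproducible bit-identically under one master seed", {
  ft <- tiny_features()
  ctl <- model_control(n_trees = 60, n_iterations = 2, min_bin_rows = 10, seed = 11)
  f1 <- suppressWarnings(fit_yield_models(ft, ctl))
  f2 <- suppressWarnings(fit_yield_models(ft, ctl))
  expect_identical(f1$baseline_mean, f2$baseline_mean)
  expect_identical(f1$iterations[[1]]$split$train, f2$iterations[[1]]$split$train)
  expect_identical(f1$iterations[[2]]$metrics, f2$iterations[[2]]$metrics)
})

test_that("iteration bookkeeping stores one metrics row per fitted bin", {
  ft <- tiny_features()
  ctl <- model_control(n_trees = 50, n_iterations = 3, min_bin_rows = 10, seed = 9)
  fit <- suppressWarnings(fit_yield_models(ft, ctl))
  expect_length(fit$iterations, 3)
  for (it in fit$iterations) {
    expect_identical(sort(as.integer(names(it$models))), sort(it$metrics$bin_id))
    expect_true(all(it$metrics$n_train >= ctl$min_bin_rows))
  }
})

test_that("ranger agrees with an independent random-forest implementation", {
  skip_if_not_installed("randomForest")
  ft <- tiny_features()
  b <- as.integer(names(which.max(table(ft$bin_id))))
  d <- ft[ft$bin_id == b, ]
  tr <- seq_len(nrow(d)) %% 4 != 0
  x <- d[, model_covariates()]
  set.seed(33)
  rf <- randomForest::randomForest(x = x[tr, ], y = d$yield[tr], ntree = 300,
                                   mtry = 2, nodesize = 5)
  rg <- ranger::ranger(y = d$yield[tr], x = x[tr, ], num.trees = 300, mtry = 2,
                       min.node.size = 5, seed = 33, num.threads = 1)
  p_rf <- predict(rf, x[!tr, ])
  p_rg <- predict(rg, data = x[!tr, ], num.threads = 1)$predictions
  expect_gt(cor(p_rf, p_rg), 0.9)
  expect_lt(mean(abs(p_rf - p_rg)) / mean(d$yield), 0.1)
})
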