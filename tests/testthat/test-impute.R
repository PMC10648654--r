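test_that("hint vectors reveal mask entries at the configured rate", {
  m <- matrix(as.numeric(rbinom(1e4, 1, 0.7)), 100)
  h1 <- make_hint(m, 1, seed = 1)
  expect_identical(h1, m)
  h <- make_hint(m, 0.9, seed = 5)
  revealed <- h != 0.5
  expect_gte(mean(revealed), 0.88)
  expect_lte(mean(revealed), 0.92)
  expect_true(all(h[!revealed] == 0.5))
  expect_true(all(h[revealed] == m[revealed]))
  expect_error(make_hint(m, 0), "hint_rate")
  expect_error(gain_config(hint_rate = 1.2), "hint_rate")
})

test_that("generator contracts: shapes, identity block, observed preservation", {
  cfg <- gain_config(base_channels = 6L, seed = 2)
  ms <- build_modified_gain(cfg, c(16L, 16L))
  tk <- make_rank_tasks(1, seed = 9)[[1]]
  comp <- impute(ms$generator, tk, noise_seed = 3)
  expect_identical(dim(comp), dim(tk$image))
  # observed pixels bit-identical (exhaustive)
  obs <- tk$observed_mask == 1
  expect_identical(comp[obs], tk$image[obs])
  # mask all ones: output equals input exactly
  t1 <- imputation_task(tk$truth, matrix(1, 16, 16))
  expect_identical(impute(ms$generator, t1), tk$truth)
  # mask all zeros: entirely generated, in range
  t0 <- imputation_task(matrix(0, 16, 16), matrix(0, 16, 16))
  c0 <- impute(ms$generator, t0)
  expect_true(all(c0 >= 0 & c0 <= 1))
  # zeroed body isolates the identity path: raw generator output = fill
  gz <- ms$generator
  gz$params <- lapply(gz$params, function(p) p * 0)
  ns <- asNamespace("fundusflow")
  fill <- ns$gain_fill(tk, 3)
  raw <- ns$generator_raw(gz, list(fill), list(tk$observed_mask))$out[, , 1, 1]
  expect_equal(raw, fill, tolerance = 1e-12)
})

test_that("training records history and zero-missingness gives zero reconstruction", {
  cfg <- gain_config(epochs = 2L, learning_rate = 1e-3, batch_size = 4L,
                     base_channels = 4L, seed = 1)
  full <- lapply(make_rank_tasks(4, seed = 3), function(t_) {
    imputation_task(t_$truth, matrix(1, 16, 16), truth = t_$truth)
  })
  ms <- build_modified_gain(cfg, c(16L, 16L))
  tr <- train_gain(ms, full, cfg)
  expect_equal(nrow(tr$history), 2L)
  expect_equal(tr$history$recon, c(0, 0))
  expect_error(train_gain(ms, list(), cfg), "empty")
})

test_that("dynamic re-imputation is fresh per epoch, reproducible, observed-safe", {
  cfg <- gain_config(base_channels = 4L, seed = 6)
  ms <- build_modified_gain(cfg, c(16L, 16L))
  tasks <- make_rank_tasks(2, seed = 4)
  e1 <- dynamic_impute_hook(ms$generator, 1L, tasks)
  e2 <- dynamic_impute_hook(ms$generator, 2L, tasks)
  miss <- tasks[[1]]$observed_mask == 0
  expect_false(identical(e1[[1]]$image[miss], e2[[1]]$image[miss]))
  expect_identical(dynamic_impute_hook(ms$generator, 2L, tasks)[[1]]$image,
                   e2[[1]]$image)
  for (ep in 1:5) {
    r <- dynamic_impute_hook(ms$generator, ep, tasks)
    for (i in 1:2) {
      obs <- tasks[[i]]$observed_mask == 1
      expect_identical(r[[i]]$image[obs], tasks[[i]]$image[obs])
    }
  }
})

test_that("classical baselines obey their closed forms and shared contracts", {
  # constant image: mean fill is exact
  m <- matrix(1, 8, 8)
  m[3:4, 3:4] <- 0
  tc <- imputation_task(matrix(0.4, 8, 8) * m, m, truth = matrix(0.4, 8, 8))
  expect_equal(rmse_missing(baseline_impute("mean", list(tc)), list(tc)), 0)
  # two-valued image hiding one value: error equals the value gap
  img <- matrix(0.2, 4, 4)
  img[1, 1] <- 0.8
  mm <- matrix(1, 4, 4)
  mm[1, 1] <- 0
  t2 <- imputation_task(img * mm, mm, truth = img)
  got <- baseline_impute("mean", list(t2))[[1]][1, 1]
  expect_equal(got, 0.2)
  expect_equal(rmse_missing(baseline_impute("mean", list(t2)), list(t2)),
               0.6)
  tasks <- make_rank_tasks(3, seed = 11)
  for (meth in c("mean", "chained_regression", "ridge", "autoencoder")) {
    comp <- baseline_impute(meth, tasks, seed = 2)
    for (i in seq_along(tasks)) {
      obs <- tasks[[i]]$observed_mask == 1
      expect_identical(comp[[i]][obs], tasks[[i]]$image[obs])
    }
  }
  expect_error(baseline_impute("nngp", tasks), "unknown")
  # pluggable registration interface
  register_imputer("const_fill", function(tasks) {
    lapply(tasks, function(t_) matrix(0.5, nrow(t_$image), ncol(t_$image)))
  })
  expect_true("const_fill" %in% registered_imputers())
  cf <- baseline_impute("const_fill", tasks)
  expect_equal(cf[[1]][tasks[[1]]$observed_mask == 0][1], 0.5)
})

test_that("imputer ranking orders by RMSE then FID then name", {
  r1 <- imputer_report("mice_like", 0.145, 1)
  r2 <- imputer_report("modified_gain", 0.0945, 0.47)
  expect_equal(rank_imputers(list(r1, r2))[[1]]$model_name, "modified_gain")
  r3 <- imputer_report("a", 0.1, 0.56)
  r4 <- imputer_report("b", 0.1, 0.47)
  expect_equal(rank_imputers(list(r3, r4))[[1]]$model_name, "b")
  expect_equal(rank_imputers(list(r1))[[1]]$model_name, "mice_like")
  expect_error(rank_imputers(list()), "reports")
  expect_error(imputer_report("x", -1, 0), ">= 0")
})
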