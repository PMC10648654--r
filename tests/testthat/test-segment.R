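test_that("spatial attention: range, zero propagation, shape preservation", {
  set.seed(3)
  for (shape in list(c(16, 16, 4, 1), c(8, 12, 8, 2))) {
    f <- array(rnorm(prod(shape)), shape)
    out <- spatial_attention_forward(f, seed = 2)
    expect_identical(dim(out), as.integer(shape))
    # residual gate bounds: out/f between 1x and 2x where f != 0
    ratio <- out / f
    expect_true(all(ratio[f != 0] >= 1 - 1e-9 & ratio[f != 0] <= 2 + 1e-9))
  }
  # zero input with zero-initialized convolution: attention 0.5, output 0
  z <- spatial_attention_forward(array(0, c(8, 8, 3, 1)),
                                 params = list(W = array(0, c(3, 3, 2, 1)),
                                               b = 0))
  expect_equal(max(abs(z)), 0)
})

test_that("multi-residual block reduces to identity with zeroed weights", {
  ns <- asNamespace("fundusflow")
  for (units in c(1L, 3L)) {
    nodes <- list(x = ns$nn_node("input", opts = list(name = "x")))
    r <- ns$add_mrb(nodes, "x", "blk", 3L, units)
    net <- list(nodes = r$nodes, out = r$out)
    params <- ns$nn_init(net, 1L)
    zero <- lapply(params, function(p) p * 0)
    x <- array(rnorm(8 * 8 * 3), c(8, 8, 3, 1))
    expect_equal(ns$nn_forward(net, zero, list(x = x))$out, x)
    # gradient reaches the first unit from the block output
    fw <- ns$nn_forward(net, params, list(x = x))
    bw <- ns$nn_backward(net, params, fw,
                         array(1, dim(fw$out)) / length(fw$out))
    expect_gt(max(abs(bw$grads$blk_c1a.W)), 0)
  }
})

test_that("architectures: shape and range contracts, baseline equivalence", {
  cfg <- segmenter_config(depth = 2L, base_channels = 6L, seed = 4)
  m <- build_mra_unet(cfg)
  x <- matrix(runif(32 * 48), 32, 48)
  pr <- predict_mask(m, x)
  expect_identical(dim(pr$probability_map), c(32L, 48L))
  expect_true(all(pr$probability_map >= 0 & pr$probability_map <= 1))
  # same-seed builds share identical initial parameters
  expect_identical(build_mra_unet(cfg)$params, build_mra_unet(cfg)$params)
  # degenerate config equals the registered plain U-Net baseline
  cfg0 <- cfg
  cfg0$attention_enabled <- FALSE
  cfg0$residual_units_per_block <- 1L
  deg <- build_mra_unet(cfg0)
  base <- build_unet_baseline(cfg)
  expect_equal(fundusflow:::n_params(deg$params),
               fundusflow:::n_params(base$params))
  expect_error(predict_mask(m, matrix(0, 31, 31)), "divisible")
  expect_error(segmenter_config(depth = 1), "depth")
})

test_that("thresholding is monotone and saturates at zero", {
  m <- build_mra_unet(segmenter_config(depth = 2L, base_channels = 4L,
                                       seed = 9))
  x <- matrix(runif(32 * 32), 32)
  m03 <- predict_mask(m, x, threshold = 0.3)$binary_mask
  m07 <- predict_mask(m, x, threshold = 0.7)$binary_mask
  expect_true(all(m07 <= m03))
  p <- predict_mask(m, x, threshold = 1e-12)
  expect_true(all(p$binary_mask[p$probability_map > 1e-12] == 1))
})

test_that("metrics are perfect when prediction equals truth", {
  s <- small_phantoms(1, 3)[[1]]
  oracle <- list(perfect = function(image) s$mask)
  rep_ <- evaluate_models(oracle, list(s))
  expect_equal(rep_$dice, 100)
  expect_equal(rep_$accuracy, 100)
  expect_equal(rep_$precision, 100)
  expect_equal(rep_$recall, 100)
  expect_error(evaluate_models(list(), list(s)), "at least one")
})

test_that("a single sample is memorized to near-perfect training Dice", {
  ph <- small_phantoms(1, 77)
  m <- build_mra_unet(segmenter_config(depth = 2L, base_channels = 8L,
                                       seed = 1))
  r <- train_segmenter(m, ph, epochs = 150L, learning_rate = 1e-2,
                       batch_size = 1L, seed = 2)
  expect_equal(nrow(r$history), 150L)
  expect_lt(tail(r$history$loss, 1), r$history$loss[1])
  d <- predict_mask(r$model, ph[[1]]$image, truth = ph[[1]]$mask)$metrics$dice
  expect_gt(d, 99)
  expect_error(train_segmenter(m, list()), "samples")
  nomask <- ph
  nomask[[1]]$mask <- NULL
  expect_error(train_segmenter(m, nomask), "mask")
})
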