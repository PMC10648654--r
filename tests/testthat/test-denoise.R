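test_that("MD block: zero propagation, shape, full-rank reconstruction", {
  pz <- md_block_params(4, zero = TRUE)
  z <- md_block_forward(array(0, c(8, 8, 4, 1)), pz, mf_rank = 4,
                        mf_iterations = 10)
  expect_lt(max(abs(z)), 1e-8)
  p <- md_block_params(4, seed = 3)
  f <- array(rnorm(12 * 8 * 4 * 2), c(12, 8, 4, 2))
  o <- md_block_forward(f, p, mf_rank = 4, mf_iterations = 10)
  expect_identical(dim(o), dim(f))
  expect_error(md_block_forward(array(0, c(4, 4, 3, 1)), p), "channel")
  # full-rank converged MF reconstruction reproduces its input: use a map
  # whose flattened channels-by-pixels matrix is square (8 channels, 8 px)
  x1 <- array(runif(2 * 4 * 8), c(2, 4, 8, 1))
  ns <- asNamespace("fundusflow")
  rec <- ns$mf_reconstruct_map(x1, rank = 8, iterations = 6000, seed = 1)
  expect_lt(sqrt(sum((rec - x1)^2)) / sqrt(sum(x1^2)), 1e-3)
})

test_that("both denoisers are shape-preserving with seed-deterministic builds", {
  m1 <- build_mf_unet(mf_unet_config(base_channels = 4L, mf_rank = 2L,
                                     mf_iterations = 5L), seed = 2)
  m2 <- build_d_unet(d_unet_config(depth = 2L, base_channels = 4L), seed = 2)
  x <- matrix(runif(32 * 32), 32)
  for (m in list(m1, m2)) {
    y <- denoise_images(m, x)
    expect_identical(dim(y[[1]]), c(32L, 32L))
    expect_true(all(y[[1]] >= 0 & y[[1]] <= 1))
  }
  expect_gt(fundusflow:::n_params(m1$params), 0)
  m1b <- build_mf_unet(mf_unet_config(base_channels = 4L, mf_rank = 2L,
                                      mf_iterations = 5L), seed = 2)
  expect_identical(m1$params, m1b$params)
  # depth-1 D-U-Net has exactly one pooling and one transpose-conv stage
  d1 <- build_d_unet(d_unet_config(depth = 1L, base_channels = 4L))
  ops <- vapply(d1$net$nodes, `[[`, character(1), "op")
  expect_equal(sum(ops == "pool2"), 1L)
  expect_equal(sum(ops == "convT"), 1L)
  # indivisible input errors with a padding hint
  expect_error(denoise_images(m2, matrix(0, 30, 30)), "divisible")
  # zero image through a zero-parameter D-U-Net stays zero
  m2z <- m2
  m2z$params <- lapply(m2$params, function(p) p * 0)
  expect_equal(max(abs(denoise_images(m2z, matrix(0, 32, 32),
                                      clip = FALSE)[[1]])), 0)
})

test_that("training minimizes L1: identity task converges, history is per-epoch", {
  ph <- small_phantoms(8, 5)
  pairs <- lapply(ph, function(s) list(noisy = s$image, clean = s$image))
  m <- build_d_unet(d_unet_config(depth = 2L, base_channels = 6L), seed = 1)
  r <- train_denoiser(m, pairs, epochs = 20L, batch_size = 4L,
                      learning_rate = 2e-3, seed = 1)
  expect_length(r$loss_history, 20L)
  expect_lt(tail(r$loss_history, 1), 0.01)
  expect_lt(tail(r$loss_history, 1), r$loss_history[1])
  expect_error(train_denoiser(m, list()), "empty")
})

test_that("select_best ranks by PSNR with SSIM and order tie-breaks", {
  set.seed(6)
  clean <- matrix(runif(400), 20)
  # hand-constructed PSNR ladder: uniform offsets of known MSE
  mk <- function(delta) pmin(clean + delta, 1)
  cands <- list(denoise_candidate(mk(0.12), "worst"),
                denoise_candidate(mk(0.06), "mid"),
                denoise_candidate(mk(0.03), "best"))
  ps <- vapply(cands, function(cd) psnr(clean, cd$image), numeric(1))
  expect_true(ps[1] < ps[2] && ps[2] < ps[3])
  expect_equal(as.integer(select_best(cands, clean)), 3L)
  # clean copy dominates through the PSNR cap
  cands2 <- list(denoise_candidate(mk(0.2), "noisy"),
                 denoise_candidate(clean, "clean"))
  expect_equal(as.integer(select_best(cands2, clean)), 2L)
  # identical candidates: first wins
  cands3 <- list(denoise_candidate(clean, "a"), denoise_candidate(clean, "b"))
  expect_equal(as.integer(select_best(cands3, clean)), 1L)
  # no-reference proxy path is flagged
  nr <- select_best(cands)
  expect_true(isTRUE(attr(nr, "proxy")))
  expect_error(select_best(list()), "candidates")
})

test_that("gradients are finite at a seeded batch for the MF-UNet", {
  ns <- asNamespace("fundusflow")
  m <- build_mf_unet(mf_unet_config(base_channels = 4L, mf_rank = 2L,
                                    mf_iterations = 5L), seed = 3)
  x <- ns$as_batch(lapply(1:2, function(i) matrix(runif(256), 16)))
  fw <- ns$nn_forward(m$net, m$params, list(x = x))
  g <- array(sign(fw$out), dim(fw$out)) / length(fw$out)
  bw <- ns$nn_backward(m$net, m$params, fw, g)
  expect_true(all(vapply(bw$grads, function(gr) all(is.finite(gr)),
                         logical(1))))
})
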