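test_that("linear schedule invariants hold across configurations", {
  sch <- build_schedule(1000L)
  expect_length(sch$beta, 1000L)
  expect_true(all(diff(sch$alpha_bar) < 0))
  expect_lt(sch$alpha_bar[1000], 5e-5)
  expect_equal(sch$alpha_bar[1], 1 - sch$beta[1])
  # single step with forced-equal endpoints
  s1 <- build_schedule(1L, 0.01, 0.01)
  expect_equal(s1$alpha_bar, 0.99)
  for (be in c(0.01, 0.05, 0.1)) {
    s <- build_schedule(50L, 1e-4, be)
    expect_true(all(s$beta > 0 & s$beta < 1))
    expect_true(all(diff(s$alpha_bar) < 0))
  }
  expect_error(build_schedule(10L, 0.2, 0.1), "beta")
})

test_that("forward diffusion follows the closed-form marginal and is seeded", {
  sch <- build_schedule(1000L)
  x0 <- array(0, c(10, 10, 1, 50))
  for (t_ in c(1L, 500L, 1000L)) {
    draws <- as.vector(forward_diffuse(x0, t_, sch, noise_seed = t_))
    expect_equal(mean(draws), 0, tolerance = 0.05)
    expect_equal(stats::var(draws), 1 - sch$alpha_bar[t_],
                 tolerance = 0.05 * max(1 - sch$alpha_bar[t_], 0.01))
  }
  expect_identical(forward_diffuse(x0, 7L, sch, 3), forward_diffuse(x0, 7L, sch, 3))
  expect_error(forward_diffuse(x0, 0L, sch), "range")
  # at t = T the signal is gone: correlation with x0 below 0.05
  set.seed(2)
  xs <- array(rnorm(1600), c(4, 4, 1, 100))
  xT <- forward_diffuse(xs, 1000L, sch, 9)
  expect_lt(abs(cor(as.vector(xs), as.vector(xT))), 0.05)
})

test_that("autoencoder round-trips shapes, including the full-scale latent", {
  cfg <- autoencoder_config(latent_channels = 4L, latent_height = 8L,
                            latent_width = 8L, epochs = 3L, seed = 2)
  imgs <- lapply(small_phantoms(6, 3), `[[`, "image")
  ae <- train_autoencoder(imgs, cfg)
  lat <- encode_images(ae$encoder, imgs)
  expect_identical(dim(lat), c(8L, 8L, 4L, 6L))
  out <- decode_latents(ae$decoder, lat)
  expect_identical(dim(out[[1]]), c(32L, 32L))
  expect_true(all(unlist(out) >= 0 & unlist(out) <= 1))
  expect_lt(tail(ae$history, 1), ae$history[1])
  # full-scale latent (20 x 28 x 20) from a 112 x 80 input, untrained build
  pcfg <- autoencoder_config(latent_channels = 20L, latent_height = 28L,
                             latent_width = 20L, epochs = 1L)
  ns <- asNamespace("fundusflow")
  nets <- ns$build_ae_nets(pcfg, 112L, 80L, 1L)
  z <- ns$nn_forward(nets$encoder$net, nets$encoder$params,
                     list(x = ns$as_batch(list(matrix(0.5, 112, 80)))))$out
  expect_identical(dim(z), c(28L, 20L, 20L, 1L))
  expect_error(ns$build_ae_nets(pcfg, 100L, 80L, 1L), "incompatible")
})

test_that("latent denoiser: analytic initial loss, per-epoch history, learning", {
  sch <- build_schedule(200L)
  set.seed(5)
  lat <- array(rnorm(8 * 8 * 2 * 6, 0, 1), c(8, 8, 2, 6))
  r <- train_latent_denoiser(lat, sch, epochs = 30L, seed = 4)
  expect_length(r$history, 30L)
  expect_lt(tail(r$history, 1), r$history[1])
  # a zero-output model scores the variance of the standard-normal target
  ns <- asNamespace("fundusflow")
  zm <- ns$build_eps_net(2L, 4L, 1L)
  zm$params <- lapply(zm$params, function(p) p * 0)
  t_ <- rep(100L, 6)
  ab <- sch$alpha_bar[t_]
  eps <- with(list(), {set.seed(9); array(rnorm(length(lat)), dim(lat))})
  zt <- sqrt(ab[1]) * lat + sqrt(1 - ab[1]) * eps
  pred <- ns$eps_predict(zm, zt, t_ / 200)$out
  expect_equal(mean((pred - eps)^2), 1, tolerance = 0.1)
  expect_error(train_latent_denoiser(array(0, c(2, 2, 1, 0)), sch), "empty")
})

test_that("sampling is deterministic, counted, and bounded", {
  cfg <- autoencoder_config(latent_channels = 3L, latent_height = 8L,
                            latent_width = 8L, epochs = 2L, seed = 3)
  imgs <- lapply(small_phantoms(4, 8), `[[`, "image")
  ae <- train_autoencoder(imgs, cfg)
  attr(ae$decoder, "latent_shape") <- c(8L, 8L)
  lat <- encode_images(ae$encoder, imgs)
  sch <- build_schedule(100L)
  ldm <- train_latent_denoiser(lat, sch, epochs = 10L, seed = 2)
  s1 <- sample_ldm(ae$decoder, ldm, sch, n = 5, seed = 7, ddim_steps = 10)
  s2 <- sample_ldm(ae$decoder, ldm, sch, n = 5, seed = 7, ddim_steps = 10)
  expect_identical(s1, s2)
  expect_length(s1, 5L)
  expect_true(all(unlist(s1) >= 0 & unlist(s1) <= 1))
  # ancestral sampler path
  s3 <- sample_ldm(ae$decoder, ldm, sch, n = 2, seed = 1)
  expect_length(s3, 2L)
  expect_error(sample_ldm(ae$decoder, ldm, sch, n = 0), "n must")

  # dataset expansion bookkeeping: originals + generated, manifest provenance
  orig <- small_phantoms(4, 8)
  comp <- list(decoder = ae$decoder, noise_model = ldm, schedule = sch,
               seed = 5, ddim_steps = 10)
  aug <- augment_dataset(orig, 6L, comp)
  expect_length(aug$samples, 10L)
  expect_equal(sum(aug$manifest$origin == "original"), 4L)
  expect_equal(sum(aug$manifest$origin == "generated"), 6L)
  expect_true(all(vapply(aug$samples[5:10],
                         function(s) is.null(s$mask), logical(1))))
  id0 <- augment_dataset(orig, 0L, comp)
  expect_identical(id0$samples, orig)
})

test_that("generation scoring: FID zero on identical sets, IS at least 1", {
  ex <- phantom_extractor(5L, n_train = 12L, size = c(32L, 32L))
  imgs <- lapply(small_phantoms(6, 4), `[[`, "image")
  same <- evaluate_generation(imgs, imgs, ex)
  expect_lt(same$fid, 1e-6)
  expect_gte(same$is, 1)
  expect_equal(same$extractor, ex$name)
  noise <- lapply(1:6, function(i) {
    fundusflow:::with_seed(i, matrix(runif(1024), 32))
  })
  diff <- evaluate_generation(imgs, noise, ex)
  expect_gt(diff$fid, same$fid)
  expect_error(evaluate_generation(imgs[1], imgs, ex), "at least 2")
})
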