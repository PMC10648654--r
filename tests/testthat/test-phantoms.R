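test_that("generator honours count, determinism and mask geometry", {
  cfg <- phantom_config(width = 48L, height = 48L, n_images = 5L, seed = 7L)
  ph <- generate_phantoms(cfg)
  expect_length(ph, 5L)
  expect_identical(ph, generate_phantoms(cfg))
  ns <- asNamespace("fundusflow")
  fov <- ns$fov_geometry(48, 48, cfg$fov_margin)
  inside <- ns$fov_mask(48, 48, fov)
  for (s in ph) {
    expect_identical(dim(s$image), dim(s$mask))
    expect_true(all(s$mask %in% c(0, 1)))
    expect_true(all(s$image >= 0 & s$image <= 1))
    # outside the FOV both image and mask are background
    expect_equal(sum(s$mask[!inside]), 0)
    expect_equal(sum(s$image[!inside]), 0)
    frac <- vessel_fraction(s)
    expect_gte(frac, 0.02)
    expect_lte(frac, 0.25)
    # vessels darker than background inside the FOV
    expect_lt(mean(s$image[s$mask == 1]),
              mean(s$image[s$mask == 0 & inside]))
  }
  expect_error(phantom_config(vessel_depth = 0), "vessel_depth")
  expect_error(phantom_config(width = 16), "32")
  # depth 1: a single unbranched root vessel
  ph1 <- generate_phantoms(phantom_config(width = 48L, height = 48L,
                                          n_images = 3L, seed = 3L,
                                          vessel_depth = 1L))
  for (s in ph1) expect_gt(vessel_fraction(s), 0)
})

test_that("noise families follow their stated laws and spare the mask", {
  s <- small_phantoms(1, 5, width = 100L, height = 100L)[[1]]
  # level 0 is the exact identity
  s0 <- add_noise(s, noise_spec("gaussian", 0, seed = 1))
  expect_identical(s0$image, s$image)
  # gaussian moment check on a constant image; at level 0.1 the 0.5-mean
  # image stays 5 sigma from the clip boundaries, so the additive law is
  # observable without truncation bias
  flat <- s
  flat$image <- matrix(0.5, 100, 100)
  g <- add_noise(flat, noise_spec("gaussian", 0.1, seed = 2))
  expect_true(all(g$image > 0 & g$image < 1))
  expect_equal(stats::sd(g$image - flat$image), 0.1, tolerance = 0.005)
  # salt and pepper corrupts a binomial fraction with equal salt/pepper
  sp <- add_noise(flat, noise_spec("salt_pepper", 0.5, seed = 3))
  frac <- mean(sp$image %in% c(0, 1))
  expect_gte(frac, 0.47)
  expect_lte(frac, 0.53)
  # speckle is multiplicative
  sk <- add_noise(flat, noise_spec("speckle", 0.1, seed = 4))
  expect_equal(stats::sd(sk$image / 0.5 - 1), 0.1, tolerance = 0.01)
  # degradations never alter the mask
  expect_identical(g$mask, s$mask)
  expect_identical(sp$mask, s$mask)
  expect_error(noise_spec("poisson", 0.1), "arg")
  # meta records the applied spec
  expect_equal(g$meta$noise$family, "gaussian")
})

test_that("occlusion reaches the target rate with first-crossing control", {
  s <- structure(list(image = matrix(0.5, 64, 64),
                      mask = matrix(0, 64, 64),
                      meta = list(fov = NULL)), class = "fundus_sample")
  r0 <- occlude(s, occlusion_spec(0, 4, seed = 1))
  expect_true(all(r0$missing_mask == 1))
  expect_identical(r0$sample$image, s$image)
  r <- occlude(s, occlusion_spec(0.2, 4L, seed = 2))
  frac <- mean(r$missing_mask == 0)
  expect_gte(frac, 0.20)
  expect_lte(frac, 0.22)
  expect_true(all(r$sample$image[r$missing_mask == 0] == 0))
  r2 <- occlude(s, occlusion_spec(0.2, 4L, seed = 2))
  expect_identical(r$missing_mask, r2$missing_mask)
  expect_error(occlude(s, occlusion_spec(0.1, 128L)), "larger")
  expect_error(occlusion_spec(1), "missing_rate")
})

test_that("PNG round trip preserves images, masks and the manifest", {
  ph <- small_phantoms(2, 9)
  dir <- tempfile("phantoms")
  write_phantoms(ph, dir)
  back <- read_phantoms(dir)
  expect_length(back, 2)
  # 8-bit quantization tolerance
  expect_lt(max(abs(back[[1]]$image - ph[[1]]$image)), 1 / 255)
  expect_identical(back[[1]]$mask, ph[[1]]$mask)
  man <- utils::read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                           header = TRUE)
  expect_equal(nrow(man), 2)
  unlink(dir, recursive = TRUE)
})
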