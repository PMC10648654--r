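# Shared fixtures: everything is generated in code at test time.

small_phantoms <- function(n, seed, width = 32L, height = 32L) {
  generate_phantoms(phantom_config(width = width, height = height,
                                   n_images = n, seed = seed))
}

noisy_pairs <- function(samples, level, family = "gaussian", seed0 = 1000L) {
  lapply(seq_along(samples), function(i) {
    list(noisy = add_noise(samples[[i]],
                           noise_spec(family, level, seed0 + i))$image,
         clean = samples[[i]]$image)
  })
}

mean_psnr <- function(images, references) {
  mean(mapply(function(d, s) psnr(s, d), images, references))
}

# An extractor stub whose features are the raw pixels (for hand-checkable
# moment computations).
pixel_extractor <- function(dim_) {
  list(name = "identity_pixels", feature_dim = dim_, n_classes = 2L,
       features = function(image) as.numeric(image)[seq_len(dim_)],
       probs = function(image) {
         z <- c(mean(image), 1 - mean(image))
         exp(z) / sum(exp(z))
       })
}
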