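# Latent-diffusion augmentation: a compression autoencoder trained with L1 +
# perceptual + patch-adversarial losses, a latent-space DDPM with a fixed
# linear variance schedule (1000 steps at full scale), ancestral (and
# optional DDIM) sampling, and IS/FID evaluation of the generated images.

#' Compression autoencoder configuration
#'
#' The full-scale latent is (20 channels x 28 x 20); the desk preset
#' shrinks both the latent and the training budget.
#'
#' @param latent_channels,latent_height,latent_width Latent dimensions.
#' @param base_channels Convolution width of encoder/decoder.
#' @param loss_weights List with `l1` (> 0), `perceptual`, `adversarial`.
#' @param epochs,learning_rate,batch_size,seed Training recipe.
#' @return An `autoencoder_config`.
#' @export
autoencoder_config <- function(latent_channels = 20L, latent_height = 28L,
                               latent_width = 20L, base_channels = 8L,
                               loss_weights = list(l1 = 1, perceptual = 0.1,
                                                   adversarial = 0.05),
                               epochs = 60L, learning_rate = 2e-3,
                               batch_size = 8L, seed = 1L) {
  if (latent_channels < 1 || latent_height < 1 || latent_width < 1) {
    stop("latent dimensions must be >= 1")
  }
  if (is.null(loss_weights$l1) || loss_weights$l1 <= 0) {
    stop("loss_weights$l1 must be > 0")
  }
  if (any(unlist(loss_weights) < 0)) stop("loss weights must be >= 0")
  structure(list(latent_channels = as.integer(latent_channels),
                 latent_height = as.integer(latent_height),
                 latent_width = as.integer(latent_width),
                 base_channels = as.integer(base_channels),
                 loss_weights = loss_weights, epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "autoencoder_config")
}

#' Linear variance schedule for the diffusion chain
#'
#' Per-step variances `beta_t` interpolated linearly from `beta_start` to
#' `beta_end` over `steps` steps, with the cumulative signal-retention
#' products `alpha_bar_t = prod(1 - beta_s)`.
#'
#' @param steps Chain length T (default 1000).
#' @param beta_start,beta_end Schedule endpoints, `0 < beta_start <=
#'   beta_end < 1` (the standard linear range 1e-4 to 0.02 by default).
#' @return A `diffusion_schedule` with fields `steps`, `beta`, `alpha_bar`.
#' @export
build_schedule <- function(steps = 1000L, beta_start = 1e-4,
                           beta_end = 0.02) {
  if (beta_start <= 0 || beta_end >= 1 || beta_start > beta_end) {
    stop("need 0 < beta_start <= beta_end < 1")
  }
  beta <- seq(beta_start, beta_end, length.out = steps)
  structure(list(steps = as.integer(steps), beta = beta,
                 alpha_bar = cumprod(1 - beta)),
            class = "diffusion_schedule")
}

#' Closed-form forward diffusion
#'
#' `x_t = sqrt(alpha_bar_t) x_0 + sqrt(1 - alpha_bar_t) eps` with seeded
#' standard-normal noise: the marginal of the forward chain at step `t`,
#' no step-by-step simulation required.
#'
#' @param x0 Latent batch array `(h, w, c, n)`.
#' @param t Step index in `[1, T]`.
#' @param schedule A [build_schedule()].
#' @param noise_seed Integer seed.
#' @return Array of the same shape.
#' @export
forward_diffuse <- function(x0, t, schedule, noise_seed = 1L) {
  if (t < 1 || t > schedule$steps) stop("t out of range")
  ab <- schedule$alpha_bar[t]
  with_seed(noise_seed, {
    eps <- array(stats::rnorm(length(x0)), dim(x0))
    sqrt(ab) * x0 + sqrt(1 - ab) * eps
  })
}

ae_pool_levels <- function(H, W, config) {
  kh <- log2(H / config$latent_height)
  kw <- log2(W / config$latent_width)
  if (abs(kh - round(kh)) > 1e-9 || abs(kw - round(kw)) > 1e-9 ||
      kh != kw || kh < 1) {
    stop("image ", H, " x ", W, " incompatible with latent ",
         config$latent_height, " x ", config$latent_width,
         "; sides must be latent size times a shared power of 2 ",
         "(e.g. ", config$latent_height * 4L, " x ",
         config$latent_width * 4L, ")")
  }
  as.integer(round(kh))
}

build_ae_nets <- function(config, H, W, seed) {
  k <- ae_pool_levels(H, W, config)
  c_ <- config$base_channels
  enc <- list(x = nn_node("input", opts = list(name = "x")),
              c0 = nn_node("conv", "x", list(k = 3L, cin = 1L, cout = c_)),
              r0 = nn_node("relu", "c0"))
  cur <- "r0"
  for (l in seq_len(k)) {
    enc[[paste0("p", l)]] <- nn_node("pool2", cur)
    enc[[paste0("c", l)]] <- nn_node("conv", paste0("p", l),
                                     list(k = 3L, cin = c_, cout = c_))
    enc[[paste0("r", l)]] <- nn_node("relu", paste0("c", l))
    cur <- paste0("r", l)
  }
  enc$lat <- nn_node("conv", cur, list(k = 1L, cin = c_,
                                       cout = config$latent_channels))
  enc_net <- list(nodes = enc, out = "lat")
  dec <- list(z = nn_node("input", opts = list(name = "z")),
              c0 = nn_node("conv", "z", list(k = 3L,
                                             cin = config$latent_channels,
                                             cout = c_)),
              r0 = nn_node("relu", "c0"))
  cur <- "r0"
  for (l in seq_len(k)) {
    dec[[paste0("u", l)]] <- nn_node("up2", cur)
    dec[[paste0("c", l)]] <- nn_node("conv", paste0("u", l),
                                     list(k = 3L, cin = c_, cout = c_))
    dec[[paste0("r", l)]] <- nn_node("relu", paste0("c", l))
    cur <- paste0("r", l)
  }
  dec$head <- nn_node("conv", cur, list(k = 3L, cin = c_, cout = 1L))
  dec$out <- nn_node("sigmoid", "head")
  dec_net <- list(nodes = dec, out = "out")
  pd <- list(x = nn_node("input", opts = list(name = "x")),
             c1 = nn_node("conv", "x", list(k = 3L, cin = 1L, cout = c_)),
             r1 = nn_node("lrelu", "c1", list(slope = 0.2)),
             p1 = nn_node("pool2", "r1"),
             c2 = nn_node("conv", "p1", list(k = 3L, cin = c_, cout = c_)),
             r2 = nn_node("lrelu", "c2", list(slope = 0.2)),
             p2 = nn_node("pool2", "r2"),
             head = nn_node("conv", "p2", list(k = 1L, cin = c_, cout = 1L)))
  pd_net <- list(nodes = pd, out = "head")
  list(encoder = list(net = enc_net, params = nn_init(enc_net,
                                                      derive_seed(seed, 1L))),
       decoder = list(net = dec_net, params = nn_init(dec_net,
                                                      derive_seed(seed, 2L))),
       patchd = list(net = pd_net, params = nn_init(pd_net,
                                                    derive_seed(seed, 3L))))
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Train the compression autoencoder
#'
#' Loss = `l1 * L1(recon, x) + perceptual * MSE(features(recon),
#' features(x)) + adversarial * patch-adversarial` (non-saturating logistic
#' patch discriminator).  The perceptual term uses the injected feature
#' extractor's convolutional maps.
#'
#' @param images List of image matrices, all the same size, compatible with
#'   the configured latent grid.
#' @param config An [autoencoder_config()].
#' @param extractor Feature extractor handle (for the perceptual term);
#'   `NULL` disables it.
#' @return List with `encoder`, `decoder`, `patch_discriminator`, `history`
#'   (per-epoch mean reconstruction L1) and `config`.
#' @export
train_autoencoder <- function(images, config = autoencoder_config(),
                              extractor = NULL) {
  H <- nrow(images[[1]])
  W <- ncol(images[[1]])
  nets <- build_ae_nets(config, H, W, config$seed)
  enc <- nets$encoder
  dec <- nets$decoder
  pd <- nets$patchd
  est <- adamax_init(enc$params)
  dst <- adamax_init(dec$params)
  pst <- adamax_init(pd$params)
  lw <- config$loss_weights
  use_pc <- !is.null(extractor) && lw$perceptual > 0
  use_adv <- lw$adversarial > 0
  history <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    batches <- with_seed(derive_seed(config$seed, ep),
                         minibatches(length(images), config$batch_size))
    l1s <- c()
    for (bi in batches) {
      xb <- as_batch(images[bi])
      efw <- nn_forward(enc$net, enc$params, list(x = xb))
      dfw <- nn_forward(dec$net, dec$params, list(z = efw$out))
      recon <- dfw$out
      n <- length(recon)
      l1s <- c(l1s, mean(abs(recon - xb)) * length(bi))
      grecon <- lw$l1 * sign(recon - xb) / n
      if (use_pc) {
        pfx <- nn_forward(extractor$net, extractor$params, list(x = xb))
        pfr <- nn_forward(extractor$net, extractor$params, list(x = recon))
        dP <- (pfr$out - pfx$out)
        gp <- nn_backward(extractor$net, extractor$params, pfr,
                          2 * dP / length(dP))$gx$x
        grecon <- grecon + lw$perceptual * gp
      }
      if (use_adv) {
        # discriminator step: real vs reconstruction
        rfw <- nn_forward(pd$net, pd$params, list(x = xb))
        ffw <- nn_forward(pd$net, pd$params, list(x = recon))
        gr <- -1 / (1 + exp(rfw$out)) / length(rfw$out)
        gf <- (1 / (1 + exp(-ffw$out))) / length(ffw$out)
        br <- nn_backward(pd$net, pd$params, rfw, gr)
        bf <- nn_backward(pd$net, pd$params, ffw, gf)
        gsum <- br$grads
        for (nm in names(gsum)) gsum[[nm]] <- gsum[[nm]] + bf$grads[[nm]]
        stp <- adamax_step(pd$params, gsum, pst, config$learning_rate)
        pd$params <- stp$params
        pst <- stp$state
        # generator (autoencoder) adversarial term
        ffw <- nn_forward(pd$net, pd$params, list(x = recon))
        gadv <- nn_backward(pd$net, pd$params, ffw,
                            -(1 / (1 + exp(ffw$out))) /
                              length(ffw$out))$gx$x
        grecon <- grecon + lw$adversarial * gadv
      }
      bdec <- nn_backward(dec$net, dec$params, dfw, grecon)
      benc <- nn_backward(enc$net, enc$params, efw, bdec$gx$z)
      std <- adamax_step(dec$params, bdec$grads, dst, config$learning_rate)
      dec$params <- std$params
      dst <- std$state
      ste <- adamax_step(enc$params, benc$grads, est, config$learning_rate)
      enc$params <- ste$params
      est <- ste$state
    }
    history[ep] <- sum(l1s) / length(images)
  }
  list(encoder = enc, decoder = dec, patch_discriminator = pd,
       history = history, config = config)
}

#' Encode images to latents
#'
#' @param encoder Encoder component from [train_autoencoder()].
#' @param images List of image matrices.
#' @return Latent array `(latent_height, latent_width, latent_channels, n)`.
#' @export
encode_images <- function(encoder, images) {
  nn_forward(encoder$net, encoder$params, list(x = as_batch(images)))$out
}

#' Decode latents to images
#'
#' @param decoder Decoder component from [train_autoencoder()].
#' @param latents Latent array `(h, w, c, n)`.
#' @return List of image matrices in `[0, 1]`.
#' @export
decode_latents <- function(decoder, latents) {
  y <- nn_forward(decoder$net, decoder$params, list(z = latents))$out
  batch_to_list(y)
}

build_eps_net <- function(latent_channels, base_channels, seed) {
  c_ <- base_channels
  nodes <- list(
    z = nn_node("input", opts = list(name = "z")),
    tc = nn_node("input", opts = list(name = "tc")),
    cat = nn_node("concat", c("z", "tc")),
    c1 = nn_node("conv", "cat", list(k = 3L, cin = latent_channels + 1L,
                                     cout = c_)),
    r1 = nn_node("relu", "c1"),
    c2 = nn_node("conv", "r1", list(k = 3L, cin = c_, cout = c_)),
    r2 = nn_node("relu", "c2"),
    head = nn_node("conv", "r2", list(k = 3L, cin = c_,
                                      cout = latent_channels))
  )
  net <- list(nodes = nodes, out = "head")
  list(net = net, params = nn_init(net, seed))
}

eps_predict <- function(model, z, tfrac) {
  d <- dim(z)
  tc <- array(rep(tfrac, each = d[1] * d[2]), c(d[1], d[2], 1L, d[4]))
  nn_forward(model$net, model$params, list(z = z, tc = tc))
}

#' Train the latent noise-prediction model
#'
#' Epsilon-parameterized DDPM training in latent space: at uniformly drawn
#' steps `t`, minimize the MSE between the true and predicted noise of the
#' closed-form forward marginal.
#'
#' @param latents Latent array `(h, w, c, n)` from [encode_images()].
#' @param schedule A [build_schedule()].
#' @param epochs Training epochs.
#' @param learning_rate Adamax step size.
#' @param seed Integer seed.
#' @param base_channels Width of the noise-prediction convnet.
#' @return List with `model` and per-epoch `history` of the epsilon MSE.
#' @export
train_latent_denoiser <- function(latents, schedule, epochs = 150L,
                                  learning_rate = 2e-3, seed = 1L,
                                  base_channels = 12L) {
  d <- dim(latents)
  if (is.null(d) || d[4] < 1) stop("empty latent set")
  model <- build_eps_net(d[3], base_channels, derive_seed(seed, 1L))
  state <- adamax_init(model$params)
  history <- numeric(epochs)
  Tn <- schedule$steps
  for (ep in seq_len(epochs)) {
    r <- with_seed(derive_seed(seed, ep), {
      t_ <- base::sample.int(Tn, d[4], replace = TRUE)
      eps <- array(stats::rnorm(length(latents)), d)
      list(t = t_, eps = eps)
    })
    ab <- schedule$alpha_bar[r$t]
    sab <- rep(sqrt(ab), each = d[1] * d[2] * d[3])
    s1ab <- rep(sqrt(1 - ab), each = d[1] * d[2] * d[3])
    zt <- array(sab * as.vector(latents) + s1ab * as.vector(r$eps), d)
    fw <- eps_predict(model, zt, r$t / Tn)
    diff <- fw$out - r$eps
    history[ep] <- mean(diff^2)
    bw <- nn_backward(model$net, model$params, fw, 2 * diff / length(diff))
    st <- adamax_step(model$params, bw$grads, state, learning_rate)
    model$params <- st$params
    state <- st$state
  }
  list(model = model, history = history)
}

#' Sample images from the latent diffusion model
#'
#' Ancestral DDPM sampling from `t = T` down to 1 using the predicted noise
#' and the schedule, then decoding through the autoencoder.  `ddim_steps`
#' switches to deterministic DDIM sampling on an evenly spaced
#' sub-schedule (faster; used by the desk presets).
#'
#' @param decoder Decoder component.
#' @param noise_model From [train_latent_denoiser()].
#' @param schedule A [build_schedule()].
#' @param n Number of images (>= 1).
#' @param seed Integer seed; fixed seeds give bit-identical sample sets.
#' @param ddim_steps Optional number of DDIM steps.
#' @return List of `n` image matrices in `[0, 1]`.
#' @export
sample_ldm <- function(decoder, noise_model, schedule, n, seed = 1L,
                       ddim_steps = NULL) {
  if (n < 1) stop("n must be >= 1")
  ln <- noise_model$model$net$nodes$head$opts$cout
  # latent grid inferred from the decoder input conv
  dshape <- attr(decoder, "latent_shape")
  if (is.null(dshape)) stop("decoder lacks latent_shape attribute")
  d <- c(dshape[1], dshape[2], ln, n)
  Tn <- schedule$steps
  z <- with_seed(derive_seed(seed, 0L),
                 array(stats::rnorm(prod(d)), d))
  if (is.null(ddim_steps)) {
    for (t_ in seq(Tn, 1L)) {
      ab <- schedule$alpha_bar[t_]
      a <- 1 - schedule$beta[t_]
      eps_hat <- eps_predict(noise_model$model, z, rep(t_ / Tn, n))$out
      mu <- (z - schedule$beta[t_] / sqrt(1 - ab) * eps_hat) / sqrt(a)
      if (t_ > 1L) {
        nz <- with_seed(derive_seed(seed, t_),
                        array(stats::rnorm(prod(d)), d))
        z <- mu + sqrt(schedule$beta[t_]) * nz
      } else {
        z <- mu
      }
    }
  } else {
    ts <- unique(round(seq(Tn, 1L, length.out = ddim_steps)))
    for (i in seq_along(ts)) {
      t_ <- ts[i]
      ab <- schedule$alpha_bar[t_]
      eps_hat <- eps_predict(noise_model$model, z, rep(t_ / Tn, n))$out
      x0 <- (z - sqrt(1 - ab) * eps_hat) / sqrt(ab)
      ab_prev <- if (i < length(ts)) schedule$alpha_bar[ts[i + 1L]] else 1
      z <- sqrt(ab_prev) * x0 + sqrt(1 - ab_prev) * eps_hat
    }
  }
  decode_latents(decoder, z)
}

#' Expand a dataset with generated images
#'
#' Returns the originals plus `n_generated` sampled images.  Generated
#' images carry no ground-truth vessel mask by default (augmentation is
#' then used where masks are not required); opt-in pseudo-labeling through
#' a trained segmenter is flagged in the manifest as non-canonical.
#'
#' @param originals List of `fundus_sample` objects.
#' @param n_generated Number of images to sample.
#' @param components List with `decoder`, `noise_model`, `schedule`, `seed`,
#'   and optional `ddim_steps`.
#' @param pseudo_label_with Optional trained segmenter used to pseudo-label
#'   generated images.
#' @return List with `samples` (originals then generated) and `manifest`
#'   (a data frame recording the provenance of every item).
#' @export
augment_dataset <- function(originals, n_generated, components,
                            pseudo_label_with = NULL) {
  gen <- list()
  if (n_generated > 0) {
    imgs <- sample_ldm(components$decoder, components$noise_model,
                       components$schedule, n_generated,
                       seed = components$seed,
                       ddim_steps = components$ddim_steps)
    gen <- lapply(seq_along(imgs), function(i) {
      msk <- NULL
      if (!is.null(pseudo_label_with)) {
        msk <- predict_mask(pseudo_label_with, imgs[[i]])$binary_mask
      }
      structure(list(image = imgs[[i]], mask = msk,
                     meta = list(seed = components$seed,
                                 generated = TRUE,
                                 pseudo_labeled = !is.null(msk),
                                 noise = NULL, occlusion = NULL,
                                 fov = NULL)),
                class = "fundus_sample")
    })
  }
  manifest <- data.frame(
    index = seq_len(length(originals) + length(gen)),
    origin = c(rep("original", length(originals)),
               rep("generated", length(gen))),
    pseudo_labeled = c(rep(FALSE, length(originals)),
                       vapply(gen, function(s)
                         isTRUE(s$meta$pseudo_labeled), logical(1))))
  list(samples = c(originals, gen), manifest = manifest)
}

#' IS / FID evaluation of generated images
#'
#' @param real,generated Lists of image matrices (>= 2 each).
#' @param extractor Feature-extractor handle.
#' @return List with `is` (inception score of the generated set), `fid`
#'   (Frechet distance between the two sets' feature Gaussians) and
#'   `extractor` (its name, recorded in every report).
#' @export
evaluate_generation <- function(real, generated, extractor) {
  if (length(real) < 2 || length(generated) < 2) {
    stop("need at least 2 images per set")
  }
  er <- embed_images(real, extractor)
  eg <- embed_images(generated, extractor)
  list(is = inception_score(eg$posterior),
       fid = frechet_distance(er$stats, eg$stats),
       extractor = extractor$name)
}
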