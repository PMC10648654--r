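# Denoising stage: a two-stage U-shaped CNN whose bottleneck MD block
# reconstructs its features through nonnegative matrix factorization, a
# plainer D-U-Net (max-pool contraction, transpose-convolution expansion),
# an L1 training loop with Adamax, and the PSNR/SSIM best-candidate
# selector that picks the final noise-free image.

#' MF-UNet configuration
#'
#' @param stages Number of serial U-shaped stages (default 2, the dual-stage
#'   horizontal layout).
#' @param base_channels Feature channels per stage.
#' @param leaky_slope Leaky-ReLU slope (default 0.02).
#' @param mf_rank Rank of the MD block's matrix factorization.
#' @param mf_iterations Multiplicative update sweeps per MD reconstruction.
#' @return An `mf_unet_config` list.
#' @export
mf_unet_config <- function(stages = 2L, base_channels = 8L,
                           leaky_slope = 0.02, mf_rank = 8L,
                           mf_iterations = 30L) {
  if (stages < 1) stop("stages must be >= 1")
  if (leaky_slope <= 0 || leaky_slope >= 1) stop("leaky_slope must be in (0,1)")
  if (mf_rank < 1) stop("mf_rank must be >= 1")
  structure(list(stages = as.integer(stages),
                 base_channels = as.integer(base_channels),
                 leaky_slope = leaky_slope, mf_rank = as.integer(mf_rank),
                 mf_iterations = as.integer(mf_iterations)),
            class = "mf_unet_config")
}

#' D-U-Net configuration
#'
#' Full-scale training defaults (100 epochs, batch 128, learning rate
#' 0.0001); [desk_preset()] shrinks them for desk-scale runs.
#'
#' @param depth Number of pooling levels.
#' @param base_channels Feature channels.
#' @param epochs Default training epochs.
#' @param batch_size Default batch size.
#' @param learning_rate Default Adamax learning rate.
#' @return A `d_unet_config` list.
#' @export
d_unet_config <- function(depth = 2L, base_channels = 8L, epochs = 100L,
                          batch_size = 128L, learning_rate = 1e-4) {
  if (depth < 1) stop("depth must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate),
            class = "d_unet_config")
}

#' Desk-scale training preset
#'
#' Scales a full-scale-recipe config down to sizes that train in seconds on a
#' single CPU (small batches, few epochs, higher learning rate), leaving the
#' architecture untouched.
#'
#' @param config A `d_unet_config` (or any list with epochs/batch fields).
#' @return The adjusted config.
#' @export
desk_preset <- function(config) {
  config$epochs <- 5L
  config$batch_size <- 16L
  config$learning_rate <- 2e-3
  config
}

# ---- MD block ---------------------------------------------------------------

#' Parameters for a standalone MD block
#'
#' @param channels Feature channels the block operates on.
#' @param seed Integer seed.
#' @param zero Initialize all weights and biases to zero (for structural
#'   checks).
#' @return Named list of convolution weights/biases.
#' @export
md_block_params <- function(channels, seed = 1L, zero = FALSE) {
  if (zero) {
    z3 <- array(0, c(3, 3, channels, channels))
    z1 <- array(0, c(1, 1, channels, channels))
    return(list(W1 = z3, b1 = numeric(channels), W2 = z3,
                b2 = numeric(channels), W3 = z3, b3 = numeric(channels),
                Wp = z1, bp = numeric(channels)))
  }
  with_seed(seed, {
    std3 <- sqrt(2 / (9 * channels))
    mk3 <- function() array(stats::rnorm(9 * channels^2, 0, std3),
                            c(3, 3, channels, channels))
    list(W1 = mk3(), b1 = numeric(channels),
         W2 = mk3(), b2 = numeric(channels),
         W3 = mk3(), b3 = numeric(channels),
         Wp = array(stats::rnorm(channels^2, 0, sqrt(2 / channels)),
                    c(1, 1, channels, channels)),
         bp = numeric(channels))
  })
}

#' MD (matrix-factorization denoising) block, forward only
#'
#' Sum of a three-layer 3x3 leaky-ReLU path and a 1x1 path, composed with a
#' rank-`mf_rank` NMF reconstruction of the flattened (channels x pixels)
#' map.  Shape-preserving.
#'
#' @param features `(H, W, C, N)` array with `C` matching the block.
#' @param params From [md_block_params()].
#' @param leaky_slope Leaky-ReLU slope.
#' @param mf_rank,mf_iterations NMF reconstruction parameters.
#' @param seed Seed for the NMF initialization.
#' @return `(H, W, C, N)` array.
#' @export
md_block_forward <- function(features, params, leaky_slope = 0.02,
                             mf_rank = 8L, mf_iterations = 30L, seed = 1L) {
  if (dim(features)[3] != dim(params$W1)[3]) {
    stop("md_block_forward: channel mismatch")
  }
  lre <- function(x) x * ifelse(x >= 0, 1, leaky_slope)
  h <- lre(conv2d_forward(features, params$W1, params$b1)$y)
  h <- lre(conv2d_forward(h, params$W2, params$b2)$y)
  h <- lre(conv2d_forward(h, params$W3, params$b3)$y)
  p <- conv2d_forward(features, params$Wp, params$bp)$y
  mf_reconstruct_map(h + p, rank = mf_rank, iterations = mf_iterations,
                     seed = seed)
}

# ---- MF-UNet graph ----------------------------------------------------------

#' Build the MF-UNet denoiser
#'
#' `stages` serial U-shaped stages: a coder block (three stacked 3x3 +
#' leaky-ReLU units with a 1x1 shortcut), max-pool to the bottleneck, an MD
#' block whose feature map is reconstructed by low-rank NMF, upsampling, and
#' a decoder fused with the coder output.  An FFU (single 3x3 convolution +
#' element-wise addition) carries features between consecutive stages.  The
#' output head predicts a residual added to the input image.
#'
#' @param config An [mf_unet_config()].
#' @param seed Seed for parameter initialization.
#' @return A `fundus_denoiser` model object.
#' @export
build_mf_unet <- function(config = mf_unet_config(), seed = 1L) {
  c_ <- config$base_channels
  s <- config$leaky_slope
  nodes <- list(img = nn_node("input", opts = list(name = "x")))
  nodes$e1c <- nn_node("conv", "img", list(k = 3L, cin = 1L, cout = c_))
  nodes$e1 <- nn_node("lrelu", "e1c", list(slope = s))
  fin <- "e1"
  for (st in seq_len(config$stages)) {
    p <- function(x) paste0("s", st, "_", x)
    cv <- function(from, nm, k = 3L, cin = c_, cout = c_, isc = 1) {
      nodes[[p(nm)]] <<- nn_node("conv", from,
                                 list(k = k, cin = cin, cout = cout,
                                      init_scale = isc))
      p(nm)
    }
    ac <- function(from, nm) {
      nodes[[p(nm)]] <<- nn_node("lrelu", from, list(slope = s))
      p(nm)
    }
    # coder: three stacked units + 1x1 shortcut
    u <- fin
    for (k in 1:3) u <- ac(cv(u, paste0("cu", k)), paste0("cr", k))
    sc <- cv(fin, "csc", k = 1L)
    nodes[[p("coder")]] <- nn_node("add", c(u, sc))
    nodes[[p("pool")]] <- nn_node("pool2", p("coder"))
    # MD block at the bottleneck
    m <- p("pool")
    for (k in 1:3) m <- ac(cv(m, paste0("md", k)), paste0("mr", k))
    mp <- cv(p("pool"), "mdp", k = 1L)
    nodes[[p("mdsum")]] <- nn_node("add", c(m, mp))
    nodes[[p("mf")]] <- nn_node("mf", p("mdsum"),
                                list(rank = config$mf_rank,
                                     iterations = config$mf_iterations,
                                     seed = derive_seed(seed, 100L + st)))
    nodes[[p("up")]] <- nn_node("up2", p("mf"))
    dc <- ac(cv(p("up"), "dec"), "decr")
    nodes[[p("out")]] <- nn_node("add", c(dc, p("coder")))
    if (st < config$stages) {
      ff <- cv(p("out"), "ffu")
      nodes[[paste0("fuse", st)]] <- nn_node("add", c(ff, "e1"))
      fin <- paste0("fuse", st)
    } else {
      nodes$head <- nn_node("conv", p("out"),
                            list(k = 1L, cin = c_, cout = 1L,
                                 init_scale = 0.05))
      nodes$res <- nn_node("add", c("head", "img"))
    }
  }
  net <- list(nodes = nodes, out = "res")
  structure(list(net = net, params = nn_init(net, seed), config = config,
                 kind = "mf_unet", pool_levels = 1L),
            class = c("mf_unet", "fundus_denoiser"))
}

#' Build the D-U-Net denoiser
#'
#' Contraction path with max-pooling, expansion path with 2x2 transpose
#' convolutions and skip concatenation, plus a global input-to-output
#' residual connection (restoration residual).
#'
#' @param config A [d_unet_config()].
#' @param seed Seed for parameter initialization.
#' @return A `fundus_denoiser` model object.
#' @export
build_d_unet <- function(config = d_unet_config(), seed = 1L) {
  c_ <- config$base_channels
  nodes <- list(img = nn_node("input", opts = list(name = "x")))
  nodes$ec <- nn_node("conv", "img", list(k = 3L, cin = 1L, cout = c_))
  nodes$er <- nn_node("lrelu", "ec", list(slope = 0.02))
  cur <- "er"
  skips <- character(config$depth)
  for (l in seq_len(config$depth)) {
    nodes[[paste0("dc", l)]] <- nn_node("conv", cur,
                                        list(k = 3L, cin = c_, cout = c_))
    nodes[[paste0("dr", l)]] <- nn_node("lrelu", paste0("dc", l),
                                        list(slope = 0.02))
    skips[l] <- paste0("dr", l)
    nodes[[paste0("pool", l)]] <- nn_node("pool2", paste0("dr", l))
    cur <- paste0("pool", l)
  }
  nodes$bc <- nn_node("conv", cur, list(k = 3L, cin = c_, cout = c_))
  nodes$br <- nn_node("lrelu", "bc", list(slope = 0.02))
  cur <- "br"
  for (l in rev(seq_len(config$depth))) {
    nodes[[paste0("ut", l)]] <- nn_node("convT", cur,
                                        list(cin = c_, cout = c_))
    nodes[[paste0("cat", l)]] <- nn_node("concat",
                                         c(paste0("ut", l), skips[l]))
    nodes[[paste0("uc", l)]] <- nn_node("conv", paste0("cat", l),
                                        list(k = 3L, cin = 2L * c_,
                                             cout = c_))
    nodes[[paste0("ur", l)]] <- nn_node("lrelu", paste0("uc", l),
                                        list(slope = 0.02))
    cur <- paste0("ur", l)
  }
  nodes$head <- nn_node("conv", cur, list(k = 1L, cin = c_, cout = 1L,
                                          init_scale = 0.05))
  nodes$res <- nn_node("add", c("head", "img"))
  net <- list(nodes = nodes, out = "res")
  structure(list(net = net, params = nn_init(net, seed), config = config,
                 kind = "d_unet", pool_levels = config$depth),
            class = c("d_unet", "fundus_denoiser"))
}

check_divisible <- function(model, H, W) {
  f <- 2^model$pool_levels
  if (H %% f != 0 || W %% f != 0) {
    stop("input sides must be divisible by ", f,
         "; pad the image to ", f * ceiling(H / f), " x ",
         f * ceiling(W / f))
  }
}

#' Run a denoiser on images
#'
#' @param model A `fundus_denoiser`.
#' @param images A list of image matrices (or a single matrix).
#' @param clip Clip output to `[0, 1]` (default TRUE).
#' @return List of denoised image matrices.
#' @export
denoise_images <- function(model, images, clip = TRUE) {
  if (is.matrix(images)) images <- list(images)
  check_divisible(model, nrow(images[[1]]), ncol(images[[1]]))
  x <- as_batch(images)
  y <- nn_forward(model$net, model$params, list(x = x))$out
  out <- batch_to_list(y)
  if (clip) out <- lapply(out, function(m) pmin(pmax(m, 0), 1))
  out
}

minibatches <- function(n, batch_size) {
  idx <- base::sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

#' Train a denoiser on (noisy, clean) pairs
#'
#' Minimizes the mean L1 reconstruction loss with the Adamax optimizer
#' (the training recipe's "Adamx" read as Adamax).
#'
#' @param model A `fundus_denoiser`.
#' @param pairs List of `list(noisy=, clean=)` image-matrix pairs.
#' @param optimizer_name Only `"adamax"` is implemented.
#' @param learning_rate Adamax step size.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param seed Seed for shuffling.
#' @return List with the trained `model` and per-epoch `loss_history`.
#' @export
train_denoiser <- function(model, pairs, optimizer_name = "adamax",
                           learning_rate = 2e-3, epochs = 5L,
                           batch_size = 16L, seed = 1L) {
  if (length(pairs) == 0) stop("empty training set")
  optimizer_name <- match.arg(optimizer_name, "adamax")
  check_divisible(model, nrow(pairs[[1]]$noisy), ncol(pairs[[1]]$noisy))
  state <- adamax_init(model$params)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    batches <- with_seed(derive_seed(seed, ep), {
      minibatches(length(pairs), batch_size)
    })
    ep_loss <- 0
    for (bi in batches) {
      xb <- as_batch(lapply(pairs[bi], `[[`, "noisy"))
      yb <- as_batch(lapply(pairs[bi], `[[`, "clean"))
      fw <- nn_forward(model$net, model$params, list(x = xb))
      diff <- fw$out - yb
      ep_loss <- ep_loss + mean(abs(diff)) * length(bi)
      g <- sign(diff) / length(diff)
      bw <- nn_backward(model$net, model$params, fw, g)
      st <- adamax_step(model$params, bw$grads, state, learning_rate)
      model$params <- st$params
      state <- st$state
    }
    history[ep] <- ep_loss / length(pairs)
  }
  list(model = model, loss_history = history)
}

#' Construct a denoised-image candidate
#'
#' @param image Denoised image matrix.
#' @param source Model identifier string.
#' @return A `denoise_candidate`.
#' @export
denoise_candidate <- function(image, source) {
  structure(list(image = image, source = source,
                 psnr_vs_ref = NA_real_, ssim_vs_ref = NA_real_),
            class = "denoise_candidate")
}

median_filter3 <- function(img) {
  H <- nrow(img); W <- ncol(img)
  pad <- matrix(0, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- img
  pad[1, ] <- pad[2, ]; pad[H + 2L, ] <- pad[H + 1L, ]
  pad[, 1] <- pad[, 2]; pad[, W + 2L] <- pad[, W + 1L]
  stack <- vapply(1:9, function(k) {
    di <- (k - 1L) %% 3L
    dj <- (k - 1L) %/% 3L
    as.vector(pad[di + seq_len(H), dj + seq_len(W)])
  }, numeric(H * W))
  matrix(apply(stack, 1L, stats::median), H, W)
}

#' Select the best noise-free candidate
#'
#' With a clean reference, ranks candidates by PSNR, breaking ties by SSIM
#' and then by list order.  Without a reference, ranks by a no-reference
#' proxy (SSIM of each candidate against its own median-filtered version);
#' the result then carries `attr(, "proxy") = TRUE`.
#'
#' @param candidates List of [denoise_candidate()] objects.
#' @param reference Clean image matrix, or `NULL`.
#' @return Index of the winning candidate; attributes `psnr`/`ssim` hold the
#'   per-candidate scores used.
#' @export
select_best <- function(candidates, reference = NULL) {
  if (length(candidates) == 0) stop("no candidates")
  # SSIM window adapted to small images (largest odd width <= 11)
  wdim <- min(vapply(candidates, function(cd) min(dim(cd$image)), numeric(1)))
  w <- min(11L, wdim - (1 - wdim %% 2))
  sw <- if (w >= 3) ssim_weights(window = w) else NULL
  ssim_or0 <- function(a, b) if (is.null(sw)) 0 else ssim(a, b, sw)
  if (!is.null(reference)) {
    ps <- vapply(candidates, function(cd) psnr(reference, cd$image),
                 numeric(1))
    ss <- vapply(candidates, function(cd) ssim_or0(reference, cd$image),
                 numeric(1))
    best <- order(-ps, -ss, seq_along(candidates))[1]
    out <- best
    attr(out, "psnr") <- ps
    attr(out, "ssim") <- ss
    out
  } else {
    ss <- vapply(candidates, function(cd) {
      ssim_or0(cd$image, median_filter3(cd$image))
    }, numeric(1))
    best <- order(-ss, seq_along(candidates))[1]
    out <- best
    attr(out, "ssim") <- ss
    attr(out, "proxy") <- TRUE
    out
  }
}

#' Table-3-style noise sweep report for a set of denoisers
#'
#' Evaluates mean PSNR and SSIM of each model's output against the clean
#' reference at each noise level, alongside the noisy-input baseline.
#'
#' @param models Named list of trained `fundus_denoiser` objects.
#' @param samples Clean `fundus_sample` list to degrade and evaluate on.
#' @param levels Noise levels to sweep.
#' @param family Noise family.
#' @param seed Seed for the degradations.
#' @return A data frame: one row per model (plus the noisy baseline), PSNR
#'   and SSIM columns per level.
#' @export
noise_sweep_report <- function(models, samples,
                               levels = c(0.1, 0.25, 0.5, 0.75),
                               family = "gaussian", seed = 1L) {
  rows <- list()
  for (lv in levels) {
    noisy <- lapply(seq_along(samples), function(i) {
      add_noise(samples[[i]], noise_spec(family, lv, derive_seed(seed, i)))
    })
    rows[[paste0("noisy_", lv)]] <- c(
      psnr = mean(mapply(function(n, s) psnr(s$image, n$image),
                         noisy, samples)),
      ssim = mean(mapply(function(n, s) ssim(s$image, n$image),
                         noisy, samples)))
    for (mn in names(models)) {
      den <- denoise_images(models[[mn]], lapply(noisy, `[[`, "image"))
      rows[[paste0(mn, "_", lv)]] <- c(
        psnr = mean(mapply(function(d, s) psnr(s$image, d), den, samples)),
        ssim = mean(mapply(function(d, s) ssim(s$image, d), den, samples)))
    }
  }
  model_names <- c("noisy", names(models))
  out <- data.frame(model = model_names)
  for (lv in levels) {
    out[[paste0("psnr_", lv)]] <- vapply(model_names, function(mn) {
      key <- paste0(ifelse(mn == "noisy", "noisy", mn), "_", lv)
      rows[[key]]["psnr"]
    }, numeric(1))
    out[[paste0("ssim_", lv)]] <- vapply(model_names, function(mn) {
      key <- paste0(ifelse(mn == "noisy", "noisy", mn), "_", lv)
      rows[[key]]["ssim"]
    }, numeric(1))
  }
  out
}
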