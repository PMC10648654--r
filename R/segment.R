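# Vessel segmentation: a U-Net whose levels are multi-residual blocks
# (densely connected residual convolutional units) and whose skip features
# pass through a spatial-attention residual block before fusion (MRA-UNet),
# plus the plain U-Net baseline obtained by disabling both, a Dice + binary
# cross-entropy trainer, prediction, and model comparison reports.

#' Segmenter configuration
#'
#' Full-scale recipe: 200 epochs, learning rate 0.0001, batch 256.  Desk presets
#' (see [desk_preset()] use) shrink the budget; the architecture fields are
#' independent of scale.
#'
#' @param depth Encoder levels (>= 2).
#' @param base_channels Channels at the top level.
#' @param residual_units_per_block Residual units per block (>= 2 makes the
#'   blocks "multi-residual"; 1 degenerates to single residual units).
#' @param attention_enabled Apply the spatial-attention residual block to
#'   skip features.
#' @param epochs,learning_rate,batch_size Training recipe defaults.
#' @param threshold Probability threshold for mask binarization.
#' @param seed Integer seed.
#' @return A `segmenter_config`.
#' @export
segmenter_config <- function(depth = 2L, base_channels = 8L,
                             residual_units_per_block = 2L,
                             attention_enabled = TRUE, epochs = 200L,
                             learning_rate = 1e-4, batch_size = 256L,
                             threshold = 0.5, seed = 1L) {
  if (depth < 2) stop("depth must be >= 2")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  if (residual_units_per_block < 1) {
    stop("residual_units_per_block must be >= 1")
  }
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 residual_units_per_block =
                   as.integer(residual_units_per_block),
                 attention_enabled = isTRUE(attention_enabled),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), threshold = threshold,
                 seed = as.integer(seed)),
            class = "segmenter_config")
}

#' Spatial-attention residual block, forward only
#'
#' Pools channel statistics (mean and max along channels), maps them through
#' a convolution and a sigmoid to a per-location attention map in `[0, 1]`,
#' and returns `features + features * attention` (residual form).
#'
#' @param features `(H, W, C, N)` array.
#' @param params List with `W` (3x3x2x1 convolution) and `b`; seeded random
#'   when `NULL`.
#' @param seed Seed used when `params` is `NULL`.
#' @return Array of the input shape.
#' @export
spatial_attention_forward <- function(features, params = NULL, seed = 1L) {
  if (is.null(params)) {
    params <- with_seed(seed, list(
      W = array(stats::rnorm(18, 0, sqrt(2 / 18)), c(3, 3, 2, 1)),
      b = 0))
  }
  d <- dim(features)
  pooled <- array(0, c(d[1], d[2], 2L, d[4]))
  for (n in seq_len(d[4])) {
    sl <- features[, , , n, drop = FALSE]
    pooled[, , 1L, n] <- apply(sl[, , , 1, drop = FALSE], c(1, 2), mean)
    pooled[, , 2L, n] <- apply(sl[, , , 1, drop = FALSE], c(1, 2), max)
  }
  a <- 1 / (1 + exp(-conv2d_forward(pooled, params$W, params$b)$y))
  ab <- array(a[, , rep(1L, d[3]), , drop = FALSE], d)
  features + features * ab
}

# Append a multi-residual block to a node list.  Unit k receives the sum of
# all previous unit outputs (dense forward connections) and adds its
# convolutional transform to the previous output (identity skip), so
# zero-initialized body weights give a pure identity path.
add_mrb <- function(nodes, input, prefix, channels, units) {
  outs <- input
  prev <- input
  for (k in seq_len(units)) {
    inname <- if (length(outs) == 1L) outs else {
      nodes[[paste0(prefix, "_in", k)]] <- nn_node("add", outs)
      paste0(prefix, "_in", k)
    }
    c1 <- paste0(prefix, "_c", k, "a")
    nodes[[c1]] <- nn_node("conv", inname,
                           list(k = 3L, cin = channels, cout = channels))
    r1 <- paste0(prefix, "_r", k)
    nodes[[r1]] <- nn_node("lrelu", c1, list(slope = 0.1))
    # tempered init of the unit's output conv keeps the dense residual
    # sums from inflating feature magnitudes with depth
    c2 <- paste0(prefix, "_c", k, "b")
    nodes[[c2]] <- nn_node("conv", r1,
                           list(k = 3L, cin = channels, cout = channels,
                                init_scale = 0.3))
    ok <- paste0(prefix, "_o", k)
    nodes[[ok]] <- nn_node("add", c(prev, c2))
    outs <- c(outs, ok)
    prev <- ok
  }
  list(nodes = nodes, out = prev)
}

add_attention <- function(nodes, input, prefix, channels) {
  nodes[[paste0(prefix, "_pool")]] <- nn_node("chanpool", input)
  nodes[[paste0(prefix, "_conv")]] <- nn_node("conv", paste0(prefix, "_pool"),
                                              list(k = 3L, cin = 2L,
                                                   cout = 1L))
  nodes[[paste0(prefix, "_sig")]] <- nn_node("sigmoid", paste0(prefix, "_conv"))
  nodes[[paste0(prefix, "_gate")]] <- nn_node("gate",
                                              c(input, paste0(prefix, "_sig")))
  list(nodes = nodes, out = paste0(prefix, "_gate"))
}

#' Build the MRA-UNet segmenter
#'
#' U-shaped encoder/decoder with a multi-residual block at every level and a
#' spatial-attention residual block applied to each skip connection before
#' fusion.  With `attention_enabled = FALSE` and
#' `residual_units_per_block = 1` this is the registered plain-U-Net
#' baseline.  Single-channel sigmoid output.
#'
#' @param config A [segmenter_config()].
#' @param seed Seed for parameter initialization.
#' @return A `fundus_segmenter` model object.
#' @export
build_mra_unet <- function(config = segmenter_config(), seed = config$seed) {
  c_ <- config$base_channels
  u <- config$residual_units_per_block
  nodes <- list(img = nn_node("input", opts = list(name = "x")))
  nodes$ec <- nn_node("conv", "img", list(k = 3L, cin = 1L, cout = c_))
  nodes$er <- nn_node("lrelu", "ec", list(slope = 0.1))
  cur <- "er"
  skips <- character(config$depth - 1L)
  for (l in seq_len(config$depth - 1L)) {
    r <- add_mrb(nodes, cur, paste0("enc", l), c_, u)
    nodes <- r$nodes
    if (config$attention_enabled) {
      a <- add_attention(nodes, r$out, paste0("att", l), c_)
      nodes <- a$nodes
      skips[l] <- a$out
    } else {
      skips[l] <- r$out
    }
    nodes[[paste0("pool", l)]] <- nn_node("pool2", r$out)
    cur <- paste0("pool", l)
  }
  r <- add_mrb(nodes, cur, "bott", c_, u)
  nodes <- r$nodes
  cur <- r$out
  for (l in rev(seq_len(config$depth - 1L))) {
    nodes[[paste0("up", l)]] <- nn_node("up2", cur)
    nodes[[paste0("ucat", l)]] <- nn_node("concat",
                                          c(paste0("up", l), skips[l]))
    nodes[[paste0("uc", l)]] <- nn_node("conv", paste0("ucat", l),
                                        list(k = 3L, cin = 2L * c_,
                                             cout = c_))
    nodes[[paste0("ur", l)]] <- nn_node("lrelu", paste0("uc", l), list(slope = 0.1))
    r <- add_mrb(nodes, paste0("ur", l), paste0("dec", l), c_, u)
    nodes <- r$nodes
    cur <- r$out
  }
  # near-zero head init keeps the sigmoid unsaturated at the start of
  # training (the dense residual connections amplify feature magnitudes)
  nodes$head <- nn_node("conv", cur, list(k = 1L, cin = c_, cout = 1L,
                                          init_scale = 0.1))
  nodes$prob <- nn_node("sigmoid", "head")
  net <- list(nodes = nodes, out = "prob")
  structure(list(net = net, params = nn_init(net, seed), config = config,
                 pool_levels = config$depth - 1L),
            class = c("mra_unet", "fundus_segmenter"))
}

#' Build the plain U-Net baseline
#'
#' The registered baseline: [build_mra_unet()] with attention disabled and
#' a single residual unit per block.
#'
#' @param config A [segmenter_config()]; its attention/residual fields are
#'   overridden.
#' @param seed Seed for parameter initialization.
#' @return A `fundus_segmenter`.
#' @export
build_unet_baseline <- function(config = segmenter_config(), seed = config$seed) {
  config$attention_enabled <- FALSE
  config$residual_units_per_block <- 1L
  m <- build_mra_unet(config, seed)
  class(m) <- c("plain_unet", "fundus_segmenter")
  m
}

segmenter_forward <- function(model, images) {
  check_divisible(model, nrow(images[[1]]), ncol(images[[1]]))
  nn_forward(model$net, model$params, list(x = as_batch(images)))
}

dice_bce_grad <- function(p, y) {
  n <- length(p)
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  gbce <- (pc - y) / (pc * (1 - pc)) / n
  sm <- 1
  num <- 2 * sum(p * y) + sm
  den <- sum(p) + sum(y) + sm
  gdice <- -(2 * y * den - num) / den^2
  bce <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
  dice_l <- 1 - num / den
  list(grad = gbce + gdice, loss = bce + dice_l)
}

#' Train a segmenter
#'
#' Minimizes an equally weighted Dice + binary cross-entropy compound loss
#' with Adamax; records per-epoch training loss, and validation Dice when a
#' validation split is supplied.
#'
#' @param model A `fundus_segmenter`.
#' @param samples List of `fundus_sample` objects with masks.
#' @param epochs,learning_rate,batch_size Training recipe (defaults from the
#'   model's config).
#' @param validation Optional list of held-out `fundus_sample` objects.
#' @param seed Shuffling seed.
#' @param epoch_hook Optional `function(epoch, samples) -> samples` applied
#'   at the start of every epoch (used for dynamic re-imputation, where
#'   missing regions are re-drawn through the current imputation generator
#'   each epoch).
#' @return List with trained `model` and `history` (data frame with `loss`
#'   and, when validated, `val_dice`).
#' @export
train_segmenter <- function(model, samples, epochs = NULL,
                            learning_rate = NULL, batch_size = NULL,
                            validation = NULL, seed = 1L,
                            epoch_hook = NULL) {
  if (length(samples) == 0) stop("no training samples")
  if (any(vapply(samples, function(s) is.null(s$mask), logical(1)))) {
    stop("all training samples must carry masks")
  }
  cfg <- model$config
  if (is.null(epochs)) epochs <- cfg$epochs
  if (is.null(learning_rate)) learning_rate <- cfg$learning_rate
  if (is.null(batch_size)) batch_size <- cfg$batch_size
  state <- adamax_init(model$params)
  history <- data.frame(epoch = seq_len(epochs), loss = NA_real_,
                        val_dice = NA_real_)
  for (ep in seq_len(epochs)) {
    samples_ep <- if (is.null(epoch_hook)) samples else
      epoch_hook(ep, samples)
    batches <- with_seed(derive_seed(seed, ep),
                         minibatches(length(samples_ep), batch_size))
    ep_loss <- 0
    for (bi in batches) {
      fw <- segmenter_forward(model, lapply(samples_ep[bi], `[[`, "image"))
      yb <- as_batch(lapply(samples_ep[bi], `[[`, "mask"))
      gl <- dice_bce_grad(fw$out, yb)
      ep_loss <- ep_loss + gl$loss * length(bi)
      bw <- nn_backward(model$net, model$params, fw, gl$grad)
      st <- adamax_step(model$params, bw$grads, state, learning_rate)
      model$params <- st$params
      state <- st$state
    }
    history$loss[ep] <- ep_loss / length(samples_ep)
    if (!is.null(validation)) {
      history$val_dice[ep] <- mean(vapply(validation, function(s) {
        predict_mask(model, s$image, truth = s$mask)$metrics$dice
      }, numeric(1)))
    }
  }
  list(model = model, history = history)
}

#' Segment an image
#'
#' @param model A `fundus_segmenter` (trained or untrained).
#' @param image Image matrix.
#' @param threshold Binarization threshold (default from config).
#' @param truth Optional ground-truth mask; when given, pixel metrics are
#'   attached (Dice in set-overlap form `2TP/(2TP+FP+FN)`, plus the Eq-style
#'   harmonic-mean form as `dice_pr`).
#' @return A `segmentation_result`: `probability_map`, `binary_mask`, and
#'   `metrics` (percent) when truth is supplied.
#' @export
predict_mask <- function(model, image, threshold = NULL, truth = NULL) {
  if (is.null(threshold)) threshold <- model$config$threshold
  fw <- segmenter_forward(model, list(image))
  p <- fw$out[, , 1L, 1L]
  bm <- (p > threshold) * 1
  metrics <- NULL
  if (!is.null(truth)) {
    cc <- confusion(bm, truth)
    pra <- precision_recall_accuracy(cc)
    metrics <- list(dice = dice_overlap(cc),
                    dice_pr = dice_from_pr(pra$precision, pra$recall),
                    accuracy = pra$accuracy, precision = pra$precision,
                    recall = pra$recall)
  }
  structure(list(probability_map = p, binary_mask = bm, metrics = metrics),
            class = "segmentation_result")
}

#' @export
predict.fundus_segmenter <- function(object, image, threshold = NULL,
                                     truth = NULL, ...) {
  predict_mask(object, image, threshold, truth)
}

#' Compare segmentation models on a test set
#'
#' One row per model with mean Dice / accuracy / precision / recall in
#' percent over the test samples (set-overlap Dice), plus wall-clock
#' prediction time (logged, never asserted).
#'
#' @param models Named list of `fundus_segmenter` objects (or functions
#'   `image -> binary mask` for oracle rows).
#' @param test_samples List of `fundus_sample` objects with masks.
#' @return A data frame report.
#' @export
evaluate_models <- function(models, test_samples) {
  if (length(models) == 0 || length(test_samples) == 0) {
    stop("need at least one model and one sample")
  }
  rows <- lapply(names(models), function(mn) {
    m <- models[[mn]]
    t0 <- Sys.time()
    mets <- vapply(test_samples, function(s) {
      bm <- if (is.function(m)) m(s$image) else
        predict_mask(m, s$image)$binary_mask
      cc <- confusion(bm, s$mask)
      pra <- precision_recall_accuracy(cc)
      c(dice = dice_overlap(cc), accuracy = pra$accuracy,
        precision = if (is.na(pra$precision)) 0 else pra$precision,
        recall = if (is.na(pra$recall)) 0 else pra$recall)
    }, numeric(4))
    data.frame(model = mn, dice = mean(mets["dice", ]),
               accuracy = mean(mets["accuracy", ]),
               precision = mean(mets["precision", ]),
               recall = mean(mets["recall", ]),
               seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  })
  do.call(rbind, rows)
}
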