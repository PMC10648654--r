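# Evaluation metrics shared by every stage: PSNR, SSIM, RMSE, pixel
# confusion counts and the derived percentages, the Dice score in both its
# precision/recall (harmonic-mean) form and the set-overlap form, the
# inception score, and the Frechet distance between feature Gaussians.

#' Peak signal-to-noise ratio
#'
#' `10 log10(L^2 / MSE)` with `L` the maximum pixel value.  A perfect match
#' (MSE = 0) returns the documented cap of 100 dB so that reports never
#' contain infinities.
#'
#' @param reference,test Numeric arrays of identical shape.
#' @param max_value Maximum pixel value L (default 1 for unit-scale images).
#' @return PSNR in decibels.
#' @export
psnr <- function(reference, test, max_value = 1) {
  if (!identical(dim(reference), dim(test)) ||
      length(reference) != length(test)) {
    stop("psnr: shape mismatch")
  }
  if (max_value <= 0) stop("max_value must be > 0")
  mse <- mean((as.numeric(reference) - as.numeric(test))^2)
  if (mse == 0) return(100)
  min(10 * log10(max_value^2 / mse), 100)
}

#' SSIM weight and window parameters
#'
#' The exponents default to 1; the window is the standard 11 x 11
#' Gaussian with sigma 1.5, and the stabilizers are `c1 = (0.01 L)^2`,
#' `c2 = (0.03 L)^2`.
#'
#' @param alpha,beta,gamma Component exponents.
#' @param window Odd window width in pixels (>= 3).
#' @param window_sigma Gaussian window sigma in pixels.
#' @param max_value Intensity scale L.
#' @param c1,c2 Stabilizers; derived from `max_value` when `NULL`.
#' @return An `ssim_weights` list.
#' @export
ssim_weights <- function(alpha = 1, beta = 1, gamma = 1, window = 11L,
                         window_sigma = 1.5, max_value = 1,
                         c1 = NULL, c2 = NULL) {
  if (window %% 2 == 0 || window < 3) stop("window must be odd and >= 3")
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 window = as.integer(window), window_sigma = window_sigma,
                 c1 = if (is.null(c1)) (0.01 * max_value)^2 else c1,
                 c2 = if (is.null(c2)) (0.03 * max_value)^2 else c2),
            class = "ssim_weights")
}

ssim_filter <- function(img, kern) {
  r <- (nrow(kern) - 1L) %/% 2L
  x <- array(img, c(nrow(img), ncol(img), 1L, 1L))
  Wk <- array(kern, c(dim(kern), 1L, 1L))
  y <- conv2d_forward(x, Wk, 0)$y[, , 1L, 1L]
  # zero-padded borders are invalid: keep the interior
  y[(r + 1L):(nrow(img) - r), (r + 1L):(ncol(img) - r), drop = FALSE]
}

#' Structural similarity index
#'
#' Mean over sliding Gaussian windows of `l^alpha * c^beta * s^gamma` with
#' the standard luminance/contrast/structure components.  Symmetric in its
#' two arguments; 1 means identical images.
#'
#' @param reference,test Numeric matrices of identical shape on the intensity
#'   scale declared in `weights`.
#' @param weights An [ssim_weights()].
#' @return SSIM in `[-1, 1]`.
#' @export
ssim <- function(reference, test, weights = ssim_weights()) {
  x <- as.matrix(reference)
  y <- as.matrix(test)
  if (!identical(dim(x), dim(y))) stop("ssim: shape mismatch")
  w <- weights$window
  if (w > min(dim(x))) stop("ssim: window larger than image")
  r <- (w - 1L) %/% 2L
  g <- exp(-((-r:r)^2) / (2 * weights$window_sigma^2))
  kern <- outer(g, g)
  kern <- kern / sum(kern)
  mux <- ssim_filter(x, kern)
  muy <- ssim_filter(y, kern)
  sxx <- pmax(ssim_filter(x * x, kern) - mux^2, 0)
  syy <- pmax(ssim_filter(y * y, kern) - muy^2, 0)
  sxy <- ssim_filter(x * y, kern) - mux * muy
  c1 <- weights$c1
  c2 <- weights$c2
  l <- (2 * mux * muy + c1) / (mux^2 + muy^2 + c1)
  cc <- (2 * sqrt(sxx) * sqrt(syy) + c2) / (sxx + syy + c2)
  s <- (sxy + c2 / 2) / (sqrt(sxx) * sqrt(syy) + c2 / 2)
  # with the default exponents of 1 this is the plain l * c * s product;
  # non-integer exponents assume the component maps are positive
  mean(l^weights$alpha * cc^weights$beta * s^weights$gamma)
}

#' Root mean squared error
#'
#' @param predicted,truth Equal-length numeric vectors (N >= 1).
#' @return `sqrt(mean((predicted - truth)^2))`.
#' @export
rmse <- function(predicted, truth) {
  p <- as.numeric(predicted)
  t_ <- as.numeric(truth)
  if (length(p) == 0) stop("rmse: empty input")
  if (length(p) != length(t_)) stop("rmse: length mismatch")
  sqrt(mean((p - t_)^2))
}

#' Pixel-level confusion counts
#'
#' @param pred_mask,true_mask Binary arrays of identical shape (values 0/1;
#'   vessel = 1).
#' @return A `confusion_counts` list with fields `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(pred_mask, true_mask) {
  p <- as.numeric(pred_mask)
  t_ <- as.numeric(true_mask)
  if (!identical(dim(pred_mask), dim(true_mask))) {
    stop("confusion: shape mismatch")
  }
  if (!all(p %in% c(0, 1)) || !all(t_ %in% c(0, 1))) {
    stop("confusion: masks must be binary")
  }
  structure(list(tp = sum(p == 1 & t_ == 1), tn = sum(p == 0 & t_ == 0),
                 fp = sum(p == 1 & t_ == 0), fn = sum(p == 0 & t_ == 1)),
            class = "confusion_counts")
}

#' Precision, recall and accuracy (percent)
#'
#' Undefined rates (zero denominator) are returned as `NA` rather than a
#' silent 0.
#'
#' @param c A `confusion_counts`.
#' @return List with `precision`, `recall`, `accuracy` in percent.
#' @export
precision_recall_accuracy <- function(c) {
  tot <- c$tp + c$tn + c$fp + c$fn
  if (tot == 0) stop("empty confusion counts")
  list(precision = if (c$tp + c$fp == 0) NA_real_ else
         100 * c$tp / (c$tp + c$fp),
       recall = if (c$tp + c$fn == 0) NA_real_ else
         100 * c$tp / (c$tp + c$fn),
       accuracy = 100 * (c$tp + c$tn) / tot)
}

#' Dice score from precision and recall (harmonic-mean form)
#'
#' `2 P R / (P + R)`.  Degenerate input (P + R = 0) returns `NA`.
#'
#' @param precision,recall Percentages in `[0, 100]`.
#' @return Dice in percent, or `NA` when undefined.
#' @export
dice_from_pr <- function(precision, recall) {
  if (is.na(precision) || is.na(recall)) return(NA_real_)
  if (precision + recall == 0) return(NA_real_)
  2 * precision * recall / (precision + recall)
}

#' Dice score in direct set-overlap form
#'
#' `2 TP / (2 TP + FP + FN)`, in percent.  Reports state which Dice form
#' they used, since the two differ whenever precision != recall.
#'
#' @param c A `confusion_counts`.
#' @return Dice in percent, or `NA` when the mask union is empty.
#' @export
dice_overlap <- function(c) {
  den <- 2 * c$tp + c$fp + c$fn
  if (den == 0) return(NA_real_)
  100 * 2 * c$tp / den
}

#' Feature-moment summary of an image set
#'
#' @param mean Feature mean vector.
#' @param cov Feature covariance matrix (symmetric PSD within 1e-8).
#' @param n Number of images summarized.
#' @return A `feature_stats` list.
#' @export
feature_stats <- function(mean, cov, n) {
  cov <- as.matrix(cov)
  if (length(mean) != nrow(cov) || nrow(cov) != ncol(cov)) {
    stop("mean length must equal cov dimension")
  }
  if (max(abs(cov - t(cov))) > 1e-8) stop("cov must be symmetric")
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("cov must be positive semi-definite")
  structure(list(mean = as.numeric(mean), cov = cov, n = n),
            class = "feature_stats")
}

#' Per-image class posteriors
#'
#' @param probs Matrix, one row per image, one column per class; each row
#'   must sum to 1 within 1e-9.
#' @return A `class_posterior` with the row matrix and the empirical marginal.
#' @export
class_posterior <- function(probs) {
  probs <- as.matrix(probs)
  if (any(probs < 0)) stop("posterior entries must be nonnegative")
  if (max(abs(rowSums(probs) - 1)) > 1e-9) {
    stop("each posterior row must sum to 1")
  }
  structure(list(probs = probs, marginal = colMeans(probs)),
            class = "class_posterior")
}

#' Inception score
#'
#' `exp(mean_x KL(p(y|x) || p(y)))` with `p(y)` the empirical marginal and
#' the `0 log 0` convention.  Always >= 1; equals the class count K for K
#' balanced one-hot posteriors.
#'
#' @param posterior A [class_posterior()].
#' @return Scalar score >= 1.
#' @export
inception_score <- function(posterior) {
  if (!inherits(posterior, "class_posterior")) {
    posterior <- class_posterior(posterior)
  }
  p <- posterior$probs
  q <- posterior$marginal
  kl <- apply(p, 1L, function(row) {
    nz <- row > 0
    sum(row[nz] * log(row[nz] / q[nz]))
  })
  exp(mean(kl))
}

# Principal matrix square root via eigendecomposition (product of two PSD
# matrices has nonnegative spectrum; tiny imaginary residue is discarded).
mat_sqrt <- function(m) {
  if (nrow(m) == 1L) return(matrix(sqrt(max(m[1, 1], 0)), 1L, 1L))
  e <- eigen(m)
  v <- e$vectors
  s <- v %*% diag(sqrt(as.complex(e$values)), nrow(m)) %*% solve(v)
  if (max(abs(Im(s))) > 1e-6) {
    warning("matrix square root has non-trivial imaginary part; discarded")
  }
  Re(s)
}

#' Frechet distance between two feature Gaussians
#'
#' `||mu_r - mu_g||^2 + Tr(S_r + S_g - 2 (S_r S_g)^{1/2})`, the Frechet
#' (Wasserstein-2) distance between the Gaussian fits of real and generated
#' feature embeddings.
#'
#' @param real,gen `feature_stats` of matching dimension.
#' @return Distance >= 0 (0 at identical stats).
#' @export
frechet_distance <- function(real, gen) {
  if (length(real$mean) != length(gen$mean)) {
    stop("frechet_distance: dimension mismatch")
  }
  covmean <- mat_sqrt(real$cov %*% gen$cov)
  d <- sum((real$mean - gen$mean)^2) +
    sum(diag(real$cov + gen$cov - 2 * covmean))
  max(d, 0)
}

#' Embed an image set through a feature extractor
#'
#' Stacks per-image feature vectors into [feature_stats()] and per-image
#' class probabilities into a [class_posterior()].  When there are no more
#' images than feature dimensions the covariance is ridge-regularized
#' (1e-6 on the diagonal) and flagged via the `"regularized"` attribute.
#'
#' @param images List of image matrices.
#' @param extractor A feature-extractor handle exposing `features(image)`
#'   and `probs(image)`, e.g. [phantom_extractor()].
#' @return List with elements `stats` and `posterior`.
#' @export
embed_images <- function(images, extractor) {
  feats <- t(vapply(images, extractor$features,
                    numeric(extractor$feature_dim)))
  probs <- t(vapply(images, extractor$probs, numeric(extractor$n_classes)))
  mu <- colMeans(feats)
  n <- nrow(feats)
  cv <- if (n > 1) stats::cov(feats) else
    matrix(0, ncol(feats), ncol(feats))
  cv <- (cv + t(cv)) / 2
  regularized <- FALSE
  if (n <= ncol(feats)) {
    cv <- cv + diag(1e-6, ncol(feats))
    regularized <- TRUE
  }
  st <- feature_stats(mu, cv, n)
  attr(st, "regularized") <- regularized
  list(stats = st, posterior = class_posterior(probs))
}

#' Default phantom-trained feature extractor
#'
#' A small seeded convolutional feature extractor (fixed random filters,
#' global mean/sd pooling) with a multinomial-logistic head trained on
#' phantom vessel-density tertiles.  It fills the role that a pretrained
#' deep classifier plays in inception-score / FID evaluation, without any
#' download; a genuinely pretrained network can be injected through the same
#' handle interface.
#'
#' @param seed Integer seed (controls filters, training phantoms and head).
#' @param n_train Number of phantoms used to fit the head.
#' @param size `c(height, width)` of the internal training phantoms.
#' @return An extractor handle: list with `name`, `feature_dim`, `n_classes`,
#'   `features(image)`, `probs(image)`, and the differentiable `net`/`params`
#'   used for perceptual losses.
#' @export
phantom_extractor <- function(seed = 42L, n_train = 24L, size = c(48L, 48L)) {
  net <- list(nodes = list(
    in1 = nn_node("input", opts = list(name = "x")),
    c1 = nn_node("conv", "in1", list(k = 3L, cin = 1L, cout = 6L)),
    r1 = nn_node("relu", "c1"),
    p1 = nn_node("pool2", "r1"),
    c2 = nn_node("conv", "p1", list(k = 3L, cin = 6L, cout = 6L)),
    r2 = nn_node("relu", "c2")
  ), out = "r2")
  params <- nn_init(net, derive_seed(seed, 1L))
  feat_of_map <- function(fmap) {
    C <- dim(fmap)[3]
    out <- numeric(2L * C)
    for (cc in seq_len(C)) {
      v <- fmap[, , cc, 1L]
      out[cc] <- mean(v)
      out[C + cc] <- stats::sd(v)
    }
    out
  }
  features <- function(image) {
    x <- array(image, c(nrow(image), ncol(image), 1L, 1L))
    feat_of_map(nn_forward(net, params, list(x = x))$out)
  }
  # head: vessel-density tertiles of seeded phantoms
  cfg <- phantom_config(width = size[2], height = size[1],
                        n_images = n_train, seed = derive_seed(seed, 2L))
  ph <- generate_phantoms(cfg)
  X <- t(vapply(ph, function(s) features(s$image), numeric(12L)))
  dens <- vapply(ph, vessel_fraction, numeric(1))
  lab <- as.integer(cut(dens, stats::quantile(dens, c(0, 1/3, 2/3, 1)),
                        include.lowest = TRUE, labels = FALSE))
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl < 1e-8] <- 1
  Xs <- scale(X, ctr, scl)
  K <- 3L
  Wh <- matrix(0, ncol(X) + 1L, K)
  Y <- diag(K)[lab, , drop = FALSE]
  Xa <- cbind(1, Xs)
  for (it in seq_len(300L)) {
    Z <- Xa %*% Wh
    Z <- Z - apply(Z, 1L, max)
    P <- exp(Z) / rowSums(exp(Z))
    Wh <- Wh - 0.5 * (crossprod(Xa, P - Y) / nrow(Xa) + 1e-4 * Wh)
  }
  probs <- function(image) {
    f <- (features(image) - ctr) / scl
    z <- c(1, f) %*% Wh
    z <- z - max(z)
    p <- exp(z)
    as.numeric(p / sum(p))
  }
  list(name = "phantom_conv_tertile", feature_dim = 12L, n_classes = K,
       features = features, probs = probs, net = net, params = params)
}
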