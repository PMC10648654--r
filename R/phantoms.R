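# Synthetic fundus phantoms: a circular field of view, a recursive branching
# vessel tree rendered dark-on-light, and parametric degradations (noise,
# patch occlusion).  Stands in for DRIVE-style data so that every pipeline
# stage can be exercised without downloads.

#' Phantom generator configuration
#'
#' Defines the geometry and stochasticity of the synthetic fundus generator.
#' Defaults emulate a desk-scale DRIVE-like dataset: 40 images at 128 x 96
#' (the 768 x 584 acquisition aspect, scaled down).
#'
#' @param width,height Image size in pixels (each >= 32).
#' @param n_images Number of samples to generate.
#' @param seed Integer seed; identical configs with identical seeds yield
#'   bit-identical samples.
#' @param vessel_depth Maximum branching generations (>= 1).
#' @param root_width Root vessel width in pixels.
#' @param width_decay Per-generation width ratio, in (0, 1).
#' @param background_level Background intensity in `[0, 1]`.
#' @param fov_margin Margin between the circular field of view and the frame,
#'   as a fraction of `min(width, height)`.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(width = 128L, height = 96L, n_images = 40L,
                           seed = 1L, vessel_depth = 4L, root_width = 3,
                           width_decay = 0.8, background_level = 0.65,
                           fov_margin = 0.04) {
  if (width < 32 || height < 32) {
    stop("phantom dimensions must be at least 32 x 32")
  }
  if (n_images < 1) stop("n_images must be >= 1")
  if (vessel_depth < 1) stop("vessel_depth must be >= 1")
  if (width_decay <= 0 || width_decay >= 1) stop("width_decay must be in (0,1)")
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_images = as.integer(n_images), seed = as.integer(seed),
                 vessel_depth = as.integer(vessel_depth),
                 root_width = root_width, width_decay = width_decay,
                 background_level = background_level,
                 fov_margin = fov_margin),
            class = "phantom_config")
}

fov_geometry <- function(width, height, fov_margin) {
  list(cx = (width + 1) / 2, cy = (height + 1) / 2,
       r = (min(width, height) / 2) * (1 - fov_margin))
}

fov_mask <- function(width, height, fov) {
  xg <- matrix(rep(seq_len(width), each = height), nrow = height)
  yg <- matrix(rep(seq_len(height), times = width), nrow = height)
  (xg - fov$cx)^2 + (yg - fov$cy)^2 <= fov$r^2
}

disk_offsets <- function(radius) {
  r <- max(radius, 0.5)
  ri <- ceiling(r)
  off <- expand.grid(dy = -ri:ri, dx = -ri:ri)
  off[off$dx^2 + off$dy^2 <= r^2 + 1e-9, , drop = FALSE]
}

# Rasterize one branch (and, recursively, its children) into `mask`
# (an environment holding the matrix, to avoid copies).
draw_branch <- function(env, pos, ang, gen, cfg, fov, seg_len) {
  H <- cfg$height
  W <- cfg$width
  w <- cfg$root_width * cfg$width_decay^(gen - 1)
  off <- disk_offsets(w / 2)
  len <- seg_len * 0.85^(gen - 1)
  nstep <- max(2L, ceiling(len / 0.5))
  for (s in seq_len(nstep)) {
    ang <- ang + stats::rnorm(1, 0, 0.07)
    pos <- pos + 0.5 * c(cos(ang), sin(ang))
    if ((pos[1] - fov$cx)^2 + (pos[2] - fov$cy)^2 > (0.98 * fov$r)^2) {
      return(invisible(pos))
    }
    xi <- round(pos[1]) + off$dx
    yi <- round(pos[2]) + off$dy
    ok <- xi >= 1 & xi <= W & yi >= 1 & yi <= H
    env$mask[cbind(yi[ok], xi[ok])] <- 1
  }
  if (gen < cfg$vessel_depth) {
    spread <- stats::runif(1, 0.35, 0.7)
    draw_branch(env, pos, ang - spread, gen + 1L, cfg, fov, seg_len)
    draw_branch(env, pos, ang + spread, gen + 1L, cfg, fov, seg_len)
  }
  invisible(pos)
}

# Separable Gaussian blur on a matrix (same-size output).
gaussian_blur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  K <- outer(k, k)
  x <- array(img, c(nrow(img), ncol(img), 1L, 1L))
  Wk <- array(K, c(2L * r + 1L, 2L * r + 1L, 1L, 1L))
  conv2d_forward(x, Wk, 0)$y[, , 1L, 1L]
}

render_phantom <- function(cfg, sample_seed) {
  with_seed(sample_seed, {
    H <- cfg$height
    W <- cfg$width
    fov <- fov_geometry(W, H, cfg$fov_margin)
    inside <- fov_mask(W, H, fov)
    env <- new.env()
    env$mask <- matrix(0, H, W)
    seg_len <- 0.6 * fov$r
    n_fov <- sum(inside)
    tries <- 0L
    a_disc <- stats::runif(1, 0, 2 * pi)
    repeat {
      tries <- tries + 1L
      disc <- c(fov$cx + 0.8 * fov$r * cos(a_disc),
                fov$cy + 0.8 * fov$r * sin(a_disc))
      root_ang <- a_disc + pi + stats::runif(1, -0.5, 0.5)
      draw_branch(env, disc, root_ang, 1L, cfg, fov, seg_len)
      frac <- sum(env$mask[inside]) / n_fov
      if (frac >= 0.02 || tries >= 8L || frac > 0.22) break
      a_disc <- a_disc + stats::runif(1, 1.5, 2.5)
    }
    env$mask[!inside] <- 0
    xg <- matrix(rep(seq_len(W), each = H), nrow = H)
    yg <- matrix(rep(seq_len(H), times = W), nrow = H)
    rho2 <- ((xg - fov$cx)^2 + (yg - fov$cy)^2) / fov$r^2
    bg <- cfg$background_level * (1 - 0.25 * pmin(rho2, 1))
    texture <- 0.02 * gaussian_blur(matrix(stats::rnorm(H * W), H, W), 1.2)
    soft <- pmin(gaussian_blur(env$mask, 0.6) * 1.4, 1)
    img <- bg + texture - 0.35 * soft
    img[!inside] <- 0
    img <- pmin(pmax(img, 0), 1)
    structure(list(image = img, mask = env$mask,
                   meta = list(seed = sample_seed, noise = NULL,
                               occlusion = NULL, fov = fov)),
              class = "fundus_sample")
  })
}

#' Generate synthetic fundus samples
#'
#' Renders `config$n_images` seeded phantoms, each a smooth radial background
#' with a darker anti-aliased recursive vessel tree inside a circular field
#' of view, paired with its exact binary vessel mask.
#'
#' @param config A [phantom_config()].
#' @return A list of `fundus_sample` objects (fields `image`, `mask`, `meta`).
#' @export
generate_phantoms <- function(config) {
  if (!inherits(config, "phantom_config")) config <- do.call(phantom_config, config)
  lapply(seq_len(config$n_images), function(i) {
    render_phantom(config, derive_seed(config$seed, i))
  })
}

#' Noise specification
#'
#' @param family One of `"gaussian"`, `"salt_pepper"`, `"speckle"`.
#' @param level Noise level in (0, 1]; for gaussian/speckle this is the
#'   standard deviation on the `[0, 1]` intensity scale, for salt-and-pepper
#'   the corrupted-pixel fraction.  The sweep levels used throughout are
#'   0.1, 0.25, 0.5 and 0.75.
#' @param seed Integer seed.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(family, level, seed = 1L) {
  family <- match.arg(family, c("gaussian", "salt_pepper", "speckle"))
  if (level < 0 || level > 1) stop("noise level must be in (0, 1]")
  structure(list(family = family, level = level, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Apply parametric noise to a sample
#'
#' Gaussian: adds N(0, level^2) and clips to `[0, 1]`.  Salt-and-pepper:
#' independently corrupts each pixel with probability `level`, setting it to
#' 0 or 1 with equal probability.  Speckle: multiplies by `1 + N(0, level^2)`
#' and clips.  The ground-truth mask is never altered; `meta$noise` records
#' the applied specification.  A level of exactly 0 is the identity.
#'
#' @param sample A `fundus_sample`.
#' @param spec A [noise_spec()].
#' @return The degraded `fundus_sample`.
#' @export
add_noise <- function(sample, spec) {
  stopifnot(inherits(sample, "fundus_sample"))
  if (!spec$family %in% c("gaussian", "salt_pepper", "speckle")) {
    stop("unknown noise family: ", spec$family)
  }
  img <- sample$image
  if (spec$level == 0) {
    sample$meta$noise <- spec
    return(sample)
  }
  img <- with_seed(spec$seed, {
    n <- length(img)
    if (spec$family == "gaussian") {
      pmin(pmax(img + stats::rnorm(n, 0, spec$level), 0), 1)
    } else if (spec$family == "speckle") {
      pmin(pmax(img * (1 + stats::rnorm(n, 0, spec$level)), 0), 1)
    } else {
      hit <- stats::runif(n) < spec$level
      val <- stats::rbinom(n, 1L, 0.5)
      out <- img
      out[hit] <- val[hit]
      out
    }
  })
  sample$image <- matrix(img, nrow(sample$image), ncol(sample$image))
  sample$meta$noise <- spec
  sample
}

#' Occlusion specification
#'
#' @param missing_rate Target fraction of in-FOV pixels to mark missing,
#'   in `[0, 1)`.
#' @param patch_size Side length of the square occlusion patches (>= 1).
#' @param seed Integer seed.
#' @return An `occlusion_spec` list.
#' @export
occlusion_spec <- function(missing_rate, patch_size = 4L, seed = 1L) {
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)")
  }
  if (patch_size < 1) stop("patch_size must be >= 1")
  structure(list(missing_rate = missing_rate,
                 patch_size = as.integer(patch_size), seed = as.integer(seed)),
            class = "occlusion_spec")
}

#' Occlude a sample with seeded square patches
#'
#' Seeded square patches are marked missing until the in-FOV missing fraction
#' first reaches the target rate; missing pixels are filled with the sentinel
#' value 0.  The ground-truth mask is untouched.
#'
#' @param sample A `fundus_sample`.
#' @param spec An [occlusion_spec()].
#' @return A list with the occluded `sample` and `missing_mask` (1 = observed,
#'   0 = missing).
#' @export
occlude <- function(sample, spec) {
  stopifnot(inherits(sample, "fundus_sample"))
  H <- nrow(sample$image)
  W <- ncol(sample$image)
  if (spec$patch_size > min(H, W)) stop("occlusion patch larger than image")
  inside <- if (!is.null(sample$meta$fov)) {
    fov_mask(W, H, sample$meta$fov)
  } else matrix(TRUE, H, W)
  m <- matrix(1, H, W)
  if (spec$missing_rate > 0) {
    n_fov <- sum(inside)
    fov_idx <- which(inside, arr.ind = TRUE)
    half <- (spec$patch_size - 1L) %/% 2L
    with_seed(spec$seed, {
      repeat {
        frac <- sum(m[inside] == 0) / n_fov
        if (frac >= spec$missing_rate) break
        ctr <- fov_idx[base::sample.int(nrow(fov_idx), 1L), ]
        rows <- pmin(pmax(ctr[1] - half + 0:(spec$patch_size - 1L), 1L), H)
        cols <- pmin(pmax(ctr[2] - half + 0:(spec$patch_size - 1L), 1L), W)
        m[rows, cols] <- 0
      }
    })
  }
  sample$image[m == 0] <- 0
  sample$meta$occlusion <- spec
  list(sample = sample, missing_mask = m)
}

#' Write phantoms to disk as 8-bit PNGs with a manifest
#'
#' Images are written as 8-bit grayscale PNG, masks as 0/255 PNG, plus a
#' tab-separated manifest (filename, mask filename, seed, degradation
#' fields).
#'
#' @param samples List of `fundus_sample` objects.
#' @param dir Output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
write_phantoms <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    fi <- sprintf("img_%03d.png", i)
    fm <- sprintf("mask_%03d.png", i)
    png::writePNG(s$image, file.path(dir, fi))
    png::writePNG(s$mask, file.path(dir, fm))
    data.frame(filename = fi, mask_filename = fm, seed = s$meta$seed,
               noise_family = if (is.null(s$meta$noise)) NA else s$meta$noise$family,
               noise_level = if (is.null(s$meta$noise)) NA else s$meta$noise$level,
               missing_rate = if (is.null(s$meta$occlusion)) NA else
                 s$meta$occlusion$missing_rate,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a phantom dataset written by [write_phantoms()]
#'
#' @param dir Directory containing the manifest and PNGs.
#' @return A list of `fundus_sample` objects.
#' @export
read_phantoms <- function(dir) {
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    img <- png::readPNG(file.path(dir, manifest$filename[i]))
    msk <- png::readPNG(file.path(dir, manifest$mask_filename[i]))
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    if (length(dim(msk)) == 3L) msk <- msk[, , 1L]
    structure(list(image = img, mask = round(msk),
                   meta = list(seed = manifest$seed[i], noise = NULL,
                               occlusion = NULL, fov = NULL)),
              class = "fundus_sample")
  })
}

#' Fraction of in-FOV pixels labelled vessel
#' @param sample A `fundus_sample`.
#' @return Scalar fraction.
#' @export
vessel_fraction <- function(sample) {
  inside <- if (!is.null(sample$meta$fov)) {
    fov_mask(ncol(sample$image), nrow(sample$image), sample$meta$fov)
  } else matrix(TRUE, nrow(sample$image), ncol(sample$image))
  sum(sample$mask[inside]) / sum(inside)
}
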