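# End-to-end orchestration: degrade -> denoise + per-image best-candidate
# selection -> imputation (ranked, with the dynamic re-imputation hook) ->
# latent-diffusion augmentation -> split -> segmentation -> stage reports.
# Every stage emits a machine-readable StageReport; a fixed seed reproduces
# every report byte-identically (timing fields excluded).

#' Deterministic hash of a configuration object
#'
#' @param x Any serializable R object.
#' @return MD5 digest string, stable across re-runs of identical configs.
#' @export
config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(serialize(x, NULL, version = 2), tf)
  unname(tools::md5sum(tf))
}

#' Stage report container
#'
#' The machine-readable analogue of a results table: one row per
#' model/candidate, one column per metric.
#'
#' @param stage Stage name.
#' @param rows Data frame of per-model metrics.
#' @param config The configuration that produced the stage.
#' @param seed Seed in force.
#' @return A `stage_report`.
#' @export
stage_report <- function(stage, rows, config, seed) {
  if (!all(vapply(rows[vapply(rows, is.numeric, logical(1))],
                  function(col) all(is.finite(col) | is.na(col)),
                  logical(1)))) {
    stop("stage report metrics must be finite")
  }
  structure(list(stage = stage, rows = rows,
                 config_hash = config_hash(config), seed = seed),
            class = "stage_report")
}

# Strip wall-clock columns before byte-identity comparisons.
report_without_timing <- function(report) {
  report$rows <- report$rows[, setdiff(names(report$rows), "seconds"),
                             drop = FALSE]
  report
}

#' Pipeline configuration
#'
#' @param phantom A [phantom_config()] describing the input data.
#' @param noise A [noise_spec()] applied to every image (or `NULL`).
#' @param occlusion An [occlusion_spec()] (or `NULL`).
#' @param denoiser_models Character subset of `c("mf_unet", "d_unet")`.
#' @param imputer_models Character vector of imputer names
#'   (`"modified_gain"`, `"gain"`, `"mean"`, `"chained_regression"`,
#'   `"ridge"`, `"autoencoder"`).
#' @param augmentation List `list(enabled=, n_generated=, pseudo_label=)`.
#' @param split List `list(train_fraction=, seed=)`.
#' @param segmenters Character subset of `c("mra_unet", "unet", "oracle")`.
#' @param training Desk-scale training budget for each stage.
#' @param output_dir Directory for reports and manifests, or `NULL`.
#' @param seed Master seed.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(phantom = phantom_config(width = 48L,
                                                     height = 32L,
                                                     n_images = 24L),
                            noise = noise_spec("gaussian", 0.25),
                            occlusion = occlusion_spec(0.2, 4L),
                            denoiser_models = "d_unet",
                            imputer_models = c("modified_gain", "mean"),
                            augmentation = list(enabled = FALSE,
                                                n_generated = 0L,
                                                pseudo_label = FALSE),
                            split = list(train_fraction = 0.8, seed = 1L),
                            segmenters = "mra_unet",
                            training = list(denoise_epochs = 12L,
                                            denoise_lr = 2e-3,
                                            gain_epochs = 40L,
                                            gain_lr = 3e-3,
                                            ae_epochs = 40L,
                                            ldm_epochs = 120L,
                                            seg_epochs = 15L,
                                            seg_lr = 4e-3,
                                            batch_size = 8L,
                                            ddim_steps = 50L),
                            output_dir = NULL, seed = 1L) {
  if (split$train_fraction <= 0 || split$train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  if (length(segmenters) < 1) stop("at least one segmenter required")
  structure(list(phantom = phantom, noise = noise, occlusion = occlusion,
                 denoiser_models = denoiser_models,
                 imputer_models = imputer_models,
                 augmentation = augmentation, split = split,
                 segmenters = segmenters, training = training,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Seeded train/test split
#'
#' Shuffles with the given seed and takes `floor(train_fraction * N)`
#' samples for training; the partition is disjoint and exhaustive.
#'
#' @param samples List of samples (N >= 2).
#' @param train_fraction Fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with `train` and `test`.
#' @export
split_dataset <- function(samples, train_fraction = 0.8, seed = 1L) {
  n <- length(samples)
  if (n < 2) stop("need at least 2 samples to split")
  idx <- with_seed(seed, base::sample.int(n))
  ntr <- floor(train_fraction * n)
  list(train = samples[idx[seq_len(ntr)]],
       test = samples[idx[(ntr + 1L):n]])
}

degrade_samples <- function(samples, noise, occlusion, seed) {
  tasks <- vector("list", length(samples))
  out <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    if (!is.null(noise)) {
      ns <- noise
      ns$seed <- derive_seed(seed, 31L * i)
      s <- add_noise(s, ns)
    }
    m <- matrix(1, nrow(s$image), ncol(s$image))
    if (!is.null(occlusion)) {
      os <- occlusion
      os$seed <- derive_seed(seed, 53L * i)
      oc <- occlude(s, os)
      s <- oc$sample
      m <- oc$missing_mask
    }
    tasks[[i]] <- imputation_task(s$image, m, truth = samples[[i]]$image)
    out[[i]] <- s
  }
  list(samples = out, tasks = tasks)
}

make_segmenter <- function(name, seed, train_cfg) {
  cfg <- segmenter_config(depth = 2L, base_channels = 8L, seed = seed)
  switch(name,
         mra_unet = build_mra_unet(cfg, seed),
         unet = build_unet_baseline(cfg, seed),
         stop("unknown segmenter: ", name))
}

train_eval_segmenters <- function(names_, train, test, tr, seed,
                                  epoch_hook = NULL) {
  models <- list()
  for (nm in names_) {
    if (nm == "oracle") {
      models[["oracle"]] <- local({
        lookup <- new.env()
        for (s in c(train, test)) {
          assign(config_hash(s$image), s$mask, envir = lookup)
        }
        function(image) get(config_hash(image), envir = lookup)
      })
    } else {
      m <- make_segmenter(nm, derive_seed(seed, match(nm, names_)), tr)
      r <- train_segmenter(m, train, epochs = tr$seg_epochs,
                           learning_rate = tr$seg_lr,
                           batch_size = tr$batch_size, seed = seed,
                           epoch_hook = epoch_hook)
      models[[nm]] <- r$model
    }
  }
  evaluate_models(models, test)
}

run_denoise_stage <- function(clean, degraded, config) {
  tr <- config$training
  pairs <- lapply(seq_along(clean), function(i) {
    list(noisy = degraded[[i]]$image, clean = clean[[i]]$image)
  })
  models <- list()
  for (nm in config$denoiser_models) {
    m <- switch(nm,
                mf_unet = build_mf_unet(mf_unet_config(base_channels = 6L,
                                                       mf_rank = 4L,
                                                       mf_iterations = 10L),
                                        seed = derive_seed(config$seed, 71L)),
                d_unet = build_d_unet(d_unet_config(depth = 2L,
                                                    base_channels = 8L),
                                      seed = derive_seed(config$seed, 72L)),
                stop("unknown denoiser: ", nm))
    models[[nm]] <- train_denoiser(m, pairs, learning_rate = tr$denoise_lr,
                                   epochs = tr$denoise_epochs,
                                   batch_size = tr$batch_size,
                                   seed = derive_seed(config$seed, 73L))$model
  }
  # per-image best candidate (Algorithm-1 style choice by PSNR and SSIM)
  chosen <- vector("list", length(degraded))
  rows <- list()
  for (i in seq_along(degraded)) {
    cands <- lapply(names(models), function(nm) {
      denoise_candidate(denoise_images(models[[nm]],
                                       degraded[[i]]$image)[[1]], nm)
    })
    best <- select_best(cands, reference = clean[[i]]$image)
    s <- degraded[[i]]
    s$image <- cands[[best]]$image
    chosen[[i]] <- s
  }
  for (nm in names(models)) {
    den <- denoise_images(models[[nm]], lapply(degraded, `[[`, "image"))
    rows[[nm]] <- data.frame(
      model = nm,
      psnr = mean(mapply(function(d, s) psnr(s$image, d), den, clean)),
      ssim = mean(mapply(function(d, s) ssim(s$image, d), den, clean)))
  }
  noisy_row <- data.frame(
    model = "noisy_input",
    psnr = mean(mapply(function(d, s) psnr(s$image, d$image),
                       degraded, clean)),
    ssim = mean(mapply(function(d, s) ssim(s$image, d$image),
                       degraded, clean)))
  list(denoised = chosen, models = models,
       report_rows = rbind(noisy_row, do.call(rbind, rows)))
}

run_impute_stage <- function(denoised, tasks, config, extractor) {
  tr <- config$training
  # refresh task images with the denoised versions (observed pixels)
  tasks <- lapply(seq_along(tasks), function(i) {
    t_ <- tasks[[i]]
    t_$image <- t_$observed_mask * denoised[[i]]$image
    t_
  })
  shape <- dim(tasks[[1]]$image)
  completed <- list()
  reports <- list()
  gain_gen <- NULL
  for (nm in config$imputer_models) {
    if (nm %in% c("modified_gain", "gain")) {
      gcfg <- gain_config(epochs = tr$gain_epochs,
                          learning_rate = tr$gain_lr,
                          batch_size = tr$batch_size,
                          seed = derive_seed(config$seed, 81L))
      models <- build_modified_gain(gcfg, shape,
                                    modified = (nm == "modified_gain"))
      trn <- train_gain(models, tasks, gcfg)
      comp <- lapply(tasks, function(t_) {
        impute(trn$models$generator, t_,
               noise_seed = derive_seed(config$seed, 82L))
      })
      if (nm == "modified_gain") gain_gen <- trn$models$generator
    } else {
      comp <- baseline_impute(nm, tasks,
                              seed = derive_seed(config$seed, 83L))
    }
    completed[[nm]] <- comp
    fid <- evaluate_generation(lapply(tasks, `[[`, "truth"), comp,
                               extractor)$fid
    reports[[nm]] <- imputer_report(nm, rmse_missing(comp, tasks), fid)
  }
  ranked <- rank_imputers(reports)
  best <- ranked[[1]]$model_name
  list(completed = completed[[best]], best = best, generator = gain_gen,
       tasks = tasks,
       report_rows = do.call(rbind, lapply(ranked, function(r) {
         data.frame(model = r$model_name, rmse = r$rmse_missing,
                    fid = r$fid)
       })))
}

#' Run the full preprocessing + segmentation pipeline
#'
#' Executes the orchestration end to end: phantom generation, degradation,
#' Step 1 (train all configured denoisers, per-image best candidate by
#' PSNR/SSIM), Step 2 (train/apply all configured imputers, rank by
#' RMSE/FID, keep the best; the dynamic re-imputation hook is active during
#' segmentation training when the winning imputer is the GAIN), Step 3
#' (latent-diffusion augmentation when enabled), then split, segmentation
#' training and evaluation.  Each stage emits a [stage_report()]; a run
#' manifest captures seeds and the configuration hash.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report`: list of stage reports, the training-pool
#'   manifest, and the final segmentation report.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  seed <- config$seed
  tr <- config$training
  reports <- list()
  clean <- generate_phantoms(config$phantom)
  extractor <- phantom_extractor(derive_seed(seed, 7L), n_train = 18L,
                                 size = c(32L, 32L))
  deg <- degrade_samples(clean, config$noise, config$occlusion, seed)
  current <- deg$samples
  gain_gen <- NULL
  tasks <- NULL
  if (length(config$denoiser_models) > 0 && !is.null(config$noise)) {
    st <- run_denoise_stage(clean, current, config)
    current <- st$denoised
    reports$denoise <- stage_report("denoise", st$report_rows, config, seed)
  }
  if (length(config$imputer_models) > 0 && !is.null(config$occlusion)) {
    st <- run_impute_stage(current, deg$tasks, config, extractor)
    for (i in seq_along(current)) current[[i]]$image <- st$completed[[i]]
    gain_gen <- st$generator
    tasks <- st$tasks
    reports$impute <- stage_report("impute", st$report_rows, config, seed)
  }
  pool <- current
  manifest <- data.frame(index = seq_along(pool), origin = "original",
                         pseudo_labeled = FALSE)
  if (isTRUE(config$augmentation$enabled) &&
      config$augmentation$n_generated > 0) {
    imgs <- lapply(pool, `[[`, "image")
    H <- nrow(imgs[[1]])
    W <- ncol(imgs[[1]])
    acfg <- autoencoder_config(latent_channels = 6L,
                               latent_height = H %/% 4L,
                               latent_width = W %/% 4L,
                               epochs = tr$ae_epochs,
                               seed = derive_seed(seed, 91L))
    ae <- train_autoencoder(imgs, acfg, extractor = extractor)
    attr(ae$decoder, "latent_shape") <- c(H %/% 4L, W %/% 4L)
    lat <- encode_images(ae$encoder, imgs)
    sch <- build_schedule(1000L)
    ldm <- train_latent_denoiser(lat, sch, epochs = tr$ldm_epochs,
                                 seed = derive_seed(seed, 92L))
    aug <- augment_dataset(pool, config$augmentation$n_generated,
                           list(decoder = ae$decoder, noise_model = ldm,
                                schedule = sch,
                                seed = derive_seed(seed, 93L),
                                ddim_steps = tr$ddim_steps))
    manifest <- aug$manifest
    pool <- aug$samples
    gen_imgs <- lapply(pool[manifest$origin == "generated"], `[[`, "image")
    ev <- evaluate_generation(imgs, gen_imgs, extractor)
    reports$augment <- stage_report("augment",
                                    data.frame(model = "ldm", is = ev$is,
                                               fid = ev$fid), config, seed)
  }
  labeled <- pool[vapply(pool, function(s) !is.null(s$mask), logical(1))]
  sp <- split_dataset(labeled, config$split$train_fraction,
                      config$split$seed)
  hook <- NULL
  if (!is.null(gain_gen) && !is.null(tasks)) {
    # dynamic imputation: missing regions of every training image are
    # re-drawn through the trained generator at each segmentation epoch
    hook <- function(epoch, samples) {
      lapply(samples, function(s) {
        i <- s$meta$pipeline_index
        if (is.null(i) || i > length(tasks)) return(s)
        t_ <- tasks[[i]]
        t_$image <- t_$observed_mask * s$image
        s$image <- impute(gain_gen, t_,
                          noise_seed = derive_seed(gain_gen$config$seed,
                                                   epoch * 10007L + i))
        s
      })
    }
  }
  # tag pool indices so the hook can find each sample's task
  for (i in seq_along(sp$train)) {
    sp$train[[i]]$meta$pipeline_index <-
      match_sample_index(sp$train[[i]], current)
  }
  seg <- train_eval_segmenters(config$segmenters, sp$train, sp$test, tr,
                               derive_seed(seed, 95L), epoch_hook = hook)
  reports$segment <- stage_report("segment", seg, config, seed)
  out <- list(reports = reports, manifest = manifest,
              n_train = length(sp$train), n_test = length(sp$test),
              config_hash = config_hash(config), seed = seed)
  class(out) <- "pipeline_report"
  if (!is.null(config$output_dir)) write_pipeline_report(out,
                                                         config$output_dir)
  out
}

match_sample_index <- function(sample, pool) {
  for (i in seq_along(pool)) {
    if (identical(pool[[i]]$meta$seed, sample$meta$seed)) return(i)
  }
  NULL
}

#' Write a pipeline report to disk
#'
#' Stage tables as TSV plus a JSON summary.
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_pipeline_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report$reports)) {
    utils::write.table(report$reports[[nm]]$rows,
                       file.path(dir, paste0(nm, "_report.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.table(report$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(config_hash = report$config_hash,
                            seed = report$seed,
                            n_train = report$n_train,
                            n_test = report$n_test),
                       file.path(dir, "run.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Segmentation with vs without the preprocessing stage
#'
#' Runs the segmentation stage twice on identical splits and seeds: once on
#' the degraded inputs directly, once through denoising + imputation, and
#' reports the per-model Dice delta (the with-minus-without improvement).
#'
#' @param config A [pipeline_config()] with degradations enabled.
#' @return List with `with_preprocessing`, `without_preprocessing` (stage
#'   reports) and `delta` (data frame, one row per segmenter).
#' @export
compare_preprocessing <- function(config = pipeline_config()) {
  seed <- config$seed
  tr <- config$training
  clean <- generate_phantoms(config$phantom)
  extractor <- phantom_extractor(derive_seed(seed, 7L), n_train = 18L,
                                 size = c(32L, 32L))
  deg <- degrade_samples(clean, config$noise, config$occlusion, seed)

  run_branch <- function(samples) {
    sp <- split_dataset(samples, config$split$train_fraction,
                        config$split$seed)
    train_eval_segmenters(config$segmenters, sp$train, sp$test, tr,
                          derive_seed(seed, 95L))
  }
  without <- run_branch(deg$samples)
  pre <- deg$samples
  if (length(config$denoiser_models) > 0 && !is.null(config$noise)) {
    st <- run_denoise_stage(clean, pre, config)
    pre <- st$denoised
  }
  if (length(config$imputer_models) > 0 && !is.null(config$occlusion)) {
    st <- run_impute_stage(pre, deg$tasks, config, extractor)
    for (i in seq_along(pre)) pre[[i]]$image <- st$completed[[i]]
  }
  with_ <- run_branch(pre)
  delta <- data.frame(model = with_$model,
                      dice_with = with_$dice,
                      dice_without = without$dice[match(with_$model,
                                                        without$model)])
  delta$delta <- delta$dice_with - delta$dice_without
  list(with_preprocessing = stage_report("segment_with", with_, config, seed),
       without_preprocessing = stage_report("segment_without", without,
                                            config, seed),
       delta = delta)
}
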