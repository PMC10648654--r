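Package: fundusflow
Title: Multi-Stage Preprocessing and Attention U-Net Segmentation for Retinal Fundus Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: A two-stage framework for retinal blood-vessel segmentation on
    fundus images, exercised end-to-end on synthetic fundus phantoms.  The
    preprocessing stage removes noise with two trainable denoisers (a
    U-shaped CNN with a matrix-factorization bottleneck block and a
    D-U-Net), selects the best candidate by PSNR/SSIM, fills missing
    regions by dynamic generative-adversarial imputation (a modified GAIN
    with Wasserstein objective, hint vectors and network deconvolution)
    against classical baselines, and enlarges the training set with a
    latent diffusion model.  The segmentation stage is a U-Net with
    multi-residual blocks and spatial-attention residual blocks (MRA-UNet)
    with a plain U-Net baseline.  Includes a seeded vascular-phantom
    generator with ground-truth masks, the full metric suite (PSNR, SSIM,
    RMSE, confusion-based rates, Dice, inception score, Frechet distance),
    and an orchestration layer with reproducible stage reports.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    png,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
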