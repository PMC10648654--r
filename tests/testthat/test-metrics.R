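test_that("psnr matches closed forms, caps at zero error, decreases with MSE", {
  x <- matrix(runif(400), 20)
  expect_equal(psnr(x, x), 100)
  expect_equal(psnr(matrix(0, 20, 20), matrix(25.5, 20, 20), 255), 20)
  # brute-force MSE oracle on two specific 3x3 integer arrays
  a <- matrix(c(10, 200, 30, 40, 50, 60, 70, 80, 90), 3)
  b <- matrix(c(12, 190, 35, 38, 55, 61, 69, 85, 88), 3)
  mse <- 0
  for (i in 1:3) for (j in 1:3) mse <- mse + (a[i, j] - b[i, j])^2
  mse <- mse / 9
  expect_equal(psnr(a, b, 255), 10 * log10(255^2 / mse))
  expect_error(psnr(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
  # strict decrease along an MSE-ordered family
  base <- matrix(0.5, 15, 15)
  vals <- vapply(c(0.01, 0.05, 0.1, 0.2), function(d) {
    psnr(base, base + d)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("ssim is 1 on identity, symmetric, and closed-form on constants", {
  set.seed(4)
  x <- matrix(runif(400), 20)
  expect_equal(ssim(x, x), 1)
  y <- pmin(pmax(x + rnorm(400, 0, 0.1), 0), 1)
  expect_equal(ssim(x, y), ssim(y, x))
  expect_true(ssim(x, y) >= -1 && ssim(x, y) <= 1)
  # distinct constants: contrast/structure degenerate-stabilized to 1
  a <- 0.3
  b <- 0.6
  c1 <- 1e-4
  expect_equal(ssim(matrix(a, 16, 16), matrix(b, 16, 16)),
               (2 * a * b + c1) / (a^2 + b^2 + c1), tolerance = 1e-10)
  expect_error(ssim(matrix(0, 4, 4), matrix(0, 4, 4)), "window")
})

test_that("rmse matches hand arithmetic and is homogeneous", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  v <- runif(10)
  w <- runif(10)
  expect_equal(rmse(3 * v, 3 * w), 3 * rmse(v, w))
  expect_error(rmse(numeric(0), numeric(0)), "empty")
})

test_that("confusion counts match a brute-force pixel loop", {
  p <- matrix(c(rep(1, 10), rep(0, 90)), 10)
  expect_equal(unclass(confusion(p, p))[c("tp", "tn", "fp", "fn")],
               list(tp = 10, tn = 90, fp = 0, fn = 0))
  tm <- matrix(rbinom(100, 1, 0.3), 10)
  allone <- matrix(1, 10, 10)
  cc <- confusion(allone, tm)
  expect_equal(cc$tp, sum(tm))
  expect_equal(cc$fp, 100 - sum(tm))
  expect_equal(cc$fn + cc$tn, 0)
  set.seed(9)
  for (rep_ in 1:5) {
    pm <- matrix(rbinom(64, 1, 0.5), 8)
    tm <- matrix(rbinom(64, 1, 0.5), 8)
    tp <- tn <- fp <- fn <- 0
    for (i in 1:8) for (j in 1:8) {
      if (pm[i, j] == 1 && tm[i, j] == 1) tp <- tp + 1
      if (pm[i, j] == 0 && tm[i, j] == 0) tn <- tn + 1
      if (pm[i, j] == 1 && tm[i, j] == 0) fp <- fp + 1
      if (pm[i, j] == 0 && tm[i, j] == 1) fn <- fn + 1
    }
    cc <- confusion(pm, tm)
    expect_equal(c(cc$tp, cc$tn, cc$fp, cc$fn), c(tp, tn, fp, fn))
    expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, 64)
  }
  expect_error(confusion(matrix(0.5, 2, 2), matrix(0, 2, 2)), "binary")
})

test_that("precision/recall/accuracy percentages and boundary semantics", {
  cc <- structure(list(tp = 9, tn = 89, fp = 1, fn = 1),
                  class = "confusion_counts")
  pra <- precision_recall_accuracy(cc)
  expect_equal(pra$precision, 90)
  expect_equal(pra$recall, 90)
  expect_equal(pra$accuracy, 98)
  perfect <- precision_recall_accuracy(
    structure(list(tp = 5, tn = 5, fp = 0, fn = 0),
              class = "confusion_counts"))
  expect_equal(unlist(perfect), c(precision = 100, recall = 100,
                                  accuracy = 100))
  deg <- precision_recall_accuracy(
    structure(list(tp = 0, tn = 5, fp = 3, fn = 0),
              class = "confusion_counts"))
  expect_equal(deg$precision, 0)
  expect_true(is.na(deg$recall))
})

test_that("Dice forms: harmonic mean of P/R and set overlap", {
  expect_equal(dice_from_pr(70, 70), 70)
  # Eq-9 form on the reported precision/recall pair
  expect_equal(dice_from_pr(95.68, 95.45), 95.5648, tolerance = 1e-4)
  expect_true(is.na(dice_from_pr(0, 0)))
  # harmonic <= arithmetic mean
  set.seed(2)
  for (i in 1:20) {
    p <- runif(1, 1, 100)
    r <- runif(1, 1, 100)
    expect_lte(dice_from_pr(p, r), (p + r) / 2 + 1e-12)
  }
  cc <- structure(list(tp = 10, tn = 80, fp = 5, fn = 5),
                  class = "confusion_counts")
  expect_equal(dice_overlap(cc), 100 * 20 / 30)
})

test_that("inception score bounds and one-hot closed form", {
  K <- 4
  expect_equal(inception_score(class_posterior(diag(K))), K)
  expect_equal(inception_score(class_posterior(matrix(1 / K, 6, K))), 1)
  set.seed(11)
  for (i in 1:10) {
    p <- matrix(rgamma(5 * K, 1), 5)
    p <- p / rowSums(p)
    s <- inception_score(class_posterior(p))
    expect_gte(s, 1)
    expect_lte(s, K + 1e-9)
  }
  expect_error(class_posterior(matrix(c(0.5, 0.4), 1)), "sum to 1")
})

test_that("frechet distance closed forms, symmetry, nonnegativity", {
  s1 <- feature_stats(0, matrix(1), 10)
  s2 <- feature_stats(1, matrix(1), 10)
  expect_equal(frechet_distance(s1, s2), 1)
  expect_equal(frechet_distance(s1, s1), 0)
  set.seed(3)
  A <- crossprod(matrix(rnorm(9), 3))
  B <- crossprod(matrix(rnorm(9), 3))
  fa <- feature_stats(rnorm(3), A, 10)
  fb <- feature_stats(rnorm(3), B, 10)
  expect_equal(frechet_distance(fa, fb), frechet_distance(fb, fa),
               tolerance = 1e-8)
  expect_gte(frechet_distance(fa, fb), 0)
  expect_error(frechet_distance(s1, fa), "dimension")
})

test_that("embed_images moments match hand computation with a pixel stub", {
  ex <- pixel_extractor(4L)
  imgs <- list(matrix(c(1, 2, 3, 4), 2), matrix(c(2, 2, 4, 4), 2))
  e <- embed_images(imgs, ex)
  F_ <- rbind(c(1, 2, 3, 4), c(2, 2, 4, 4))
  expect_equal(e$stats$mean, colMeans(F_))
  expect_equal(e$stats$cov, cov(F_) + diag(1e-6, 4), tolerance = 1e-12)
  expect_true(attr(e$stats, "regularized"))
  expect_equal(rowSums(e$posterior$probs), c(1, 1))
  # one repeated image: zero covariance before the ridge
  er <- embed_images(list(imgs[[1]], imgs[[1]], imgs[[1]]), ex)
  expect_equal(max(abs(er$stats$cov - diag(1e-6, 4))), 0, tolerance = 1e-12)
})

test_that("default phantom extractor yields valid posteriors and features", {
  ex <- phantom_extractor(7L, n_train = 12L, size = c(32L, 32L))
  img <- matrix(runif(32 * 32), 32)
  expect_length(ex$features(img), ex$feature_dim)
  p <- ex$probs(img)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_true(all(p >= 0))
})
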