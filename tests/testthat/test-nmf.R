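test_that("multiplicative updates are non-increasing and fix exact factorizations", {
  set.seed(3)
  v <- matrix(runif(64, 0.1, 1), 8)
  f <- mf_init(v, 3, seed = 1)
  objs <- numeric(50)
  for (i in 1:50) {
    f <- mf_update(v, f, 1)
    objs[i] <- mf_objective(v, f)
  }
  expect_true(all(diff(objs) <= 1e-10))
  # exact rank-1 factorization is a fixed point
  w <- matrix(runif(8, 0.5, 1), 8, 1)
  h <- matrix(runif(6, 0.5, 1), 1, 6)
  f0 <- factor_pair(w, h)
  f1 <- mf_update(w %*% h, f0, 5)
  expect_lt(max(abs(f1$w %*% f1$h - w %*% h)), 1e-9)
  expect_error(mf_update(matrix(-1, 2, 2), mf_init(matrix(1, 2, 2), 1)),
               "nonnegative")
})

test_that("multiplicative updates are competitive with an ALS-with-clipping oracle", {
  set.seed(7)
  v <- matrix(runif(64, 0.05, 1), 8)
  rank <- 2L
  f <- mf_update(v, mf_init(v, rank, seed = 2), 200)
  err_mu <- sqrt(mf_objective(v, f))
  # independent oracle: alternating least squares with nonnegativity clipping
  set.seed(2)
  W <- matrix(runif(8 * rank, 0.2, 1), 8)
  H <- matrix(runif(rank * 8, 0.2, 1), rank)
  for (i in 1:200) {
    H <- pmax(solve(crossprod(W) + diag(1e-10, rank), crossprod(W, v)), 0)
    Wt <- pmax(solve(tcrossprod(H) + diag(1e-10, rank), H %*% t(v)), 0)
    W <- t(Wt)
  }
  err_als <- sqrt(sum((v - W %*% H)^2))
  expect_lte(err_mu, err_als * 1.05)
})

test_that("full-rank NMF reconstruction recovers the matrix", {
  set.seed(5)
  v <- matrix(runif(64, 0.1, 1), 8)
  f <- mf_update(v, mf_init(v, 8, seed = 1), 2000)
  expect_lt(sqrt(mf_objective(v, f)) / sqrt(sum(v^2)), 1e-3)
})
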