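# Finite-difference checks of the graph engine that every architecture
# rests on.

num_grad <- function(fun, arr, i, eps = 1e-6) {
  a1 <- arr
  a1[i] <- a1[i] + eps
  a2 <- arr
  a2[i] <- a2[i] - eps
  (fun(a1) - fun(a2)) / (2 * eps)
}

test_that("convolution primitives agree with finite differences", {
  set.seed(1)
  ns <- asNamespace("fundusflow")
  x <- array(rnorm(6 * 8 * 2 * 2), c(6, 8, 2, 2))
  W <- array(rnorm(3 * 3 * 2 * 3, 0, 0.3), c(3, 3, 2, 3))
  b <- rnorm(3)
  f <- ns$conv2d_forward(x, W, b)
  gy <- array(rnorm(length(f$y)), dim(f$y))
  bk <- ns$conv2d_backward(gy, W, f$cache)
  lossW <- function(Wp) sum(ns$conv2d_forward(x, Wp, b)$y * gy)
  lossx <- function(xp) sum(ns$conv2d_forward(xp, W, b)$y * gy)
  for (i in c(1, 20, 50)) {
    expect_equal(num_grad(lossW, W, i), bk$gW[i], tolerance = 1e-6)
  }
  for (i in c(1, 40, 90)) {
    expect_equal(num_grad(lossx, x, i), bk$gx[i], tolerance = 1e-6)
  }
  Wt <- array(rnorm(2 * 2 * 2 * 3, 0, 0.3), c(2, 2, 2, 3))
  bt <- rnorm(3)
  ft <- ns$convT2_forward(x, Wt, bt)
  gyt <- array(rnorm(length(ft$y)), dim(ft$y))
  bkt <- ns$convT2_backward(gyt, x, Wt)
  lossWt <- function(Wp) sum(ns$convT2_forward(x, Wp, bt)$y * gyt)
  for (i in c(1, 10, 24)) {
    expect_equal(num_grad(lossWt, Wt, i), bkt$gW[i], tolerance = 1e-6)
  }
})

test_that("a composite graph backpropagates correctly end to end", {
  ns <- asNamespace("fundusflow")
  nn_node <- ns$nn_node
  net <- list(nodes = list(
    x = nn_node("input", opts = list(name = "x")),
    c1 = nn_node("conv", "x", list(k = 3L, cin = 1L, cout = 3L)),
    r1 = nn_node("lrelu", "c1", list(slope = 0.1)),
    p1 = nn_node("pool2", "r1"),
    c2 = nn_node("conv", "p1", list(k = 3L, cin = 3L, cout = 3L)),
    u1 = nn_node("up2", "c2"),
    a1 = nn_node("add", c("u1", "r1")),
    cp = nn_node("chanpool", "a1"),
    cg = nn_node("conv", "cp", list(k = 3L, cin = 2L, cout = 1L)),
    sg = nn_node("sigmoid", "cg"),
    gt = nn_node("gate", c("a1", "sg")),
    hd = nn_node("conv", "gt", list(k = 1L, cin = 3L, cout = 1L))
  ), out = "hd")
  params <- ns$nn_init(net, 4L)
  x <- array(rnorm(8 * 8), c(8, 8, 1, 1))
  fw <- ns$nn_forward(net, params, list(x = x))
  gy <- array(rnorm(64), dim(fw$out))
  bw <- ns$nn_backward(net, params, fw, gy)
  loss_p <- function(nm, i) {
    p2 <- params
    function(v) {
      p2[[nm]][i] <- v
      sum(ns$nn_forward(net, p2, list(x = x))$out * gy)
    }
  }
  for (nm in c("c1.W", "c2.W", "cg.W", "hd.W", "c1.b")) {
    f1 <- loss_p(nm, 1)
    eps <- 1e-6
    num <- (f1(params[[nm]][1] + eps) - f1(params[[nm]][1] - eps)) / (2 * eps)
    expect_equal(num, bw$grads[[nm]][1], tolerance = 1e-5)
  }
  # input gradient
  lossx <- function(xp) sum(ns$nn_forward(net, params, list(x = xp))$out * gy)
  for (i in c(5, 30)) {
    expect_equal(num_grad(lossx, x, i), bw$gx$x[i], tolerance = 1e-5)
  }
})

test_that("whitening decorrelates perfectly correlated channels", {
  ns <- asNamespace("fundusflow")
  net <- list(nodes = list(
    x = ns$nn_node("input", opts = list(name = "x")),
    w = ns$nn_node("whiten", "x")
  ), out = "w")
  set.seed(8)
  base <- matrix(rnorm(64), 8)
  x <- array(0, c(8, 8, 2, 2))
  for (n in 1:2) {
    # strongly correlated channels with a small independent residual
    x[, , 1, n] <- base + rnorm(64, 0, 0.05)
    x[, , 2, n] <- 2 * base + 1 + rnorm(64, 0, 0.05)
  }
  y <- ns$nn_forward(net, list(), list(x = x))$out
  c1 <- as.vector(y[, , 1, ])
  c2 <- as.vector(y[, , 2, ])
  expect_gt(abs(cor(as.vector(x[, , 1, ]), as.vector(x[, , 2, ]))), 0.99)
  expect_lt(abs(cor(c1, c2)), 0.1)
})

test_that("seeded evaluation restores the caller's RNG state", {
  ns <- asNamespace("fundusflow")
  set.seed(42)
  a <- rnorm(1)
  set.seed(42)
  invisible(ns$with_seed(7, rnorm(10)))
  expect_identical(rnorm(1), a)
  expect_identical(ns$with_seed(3, runif(5)), ns$with_seed(3, runif(5)))
  s <- ns$derive_seed(123456L, 99L)
  expect_true(s >= 0 && s < 2^31)
})
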