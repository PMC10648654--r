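# Minimal neural-network engine: static computation graphs over 4-D feature
# arrays (H, W, C, N), with hand-written backward passes and an Adamax
# optimizer.  Every architecture in the package (both denoisers, the GAIN
# imputer, the compression autoencoder, the latent denoiser, MRA-UNet) is a
# graph interpreted by nn_forward()/nn_backward().

# ---- RNG helper -------------------------------------------------------------

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded internals never
#' perturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Derive a child seed from a base seed, kept inside 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 2654435.0 + as.double(k) * 97.0 + 13.0) %%
               2147483647)
}

# ---- im2col convolution primitives -----------------------------------------

.nn_cache <- new.env(parent = emptyenv())

nn_pad <- function(x, p) {
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  out
}

# Linear indices (1-based) into one padded sample (Hp x Wp x C) extracting,
# row-wise per output pixel, the k x k x C receptive field.  Cached per
# geometry; column order is (di fastest, dj, channel) to match R's array
# linearization of the (k, k, Cin, Cout) weight array.
im2col_idx <- function(H, W, C, k) {
  key <- paste0("i2c_", H, "_", W, "_", C, "_", k)
  hit <- .nn_cache[[key]]
  if (!is.null(hit)) return(hit)
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p
  Wp <- W + 2L * p
  base_i <- rep(seq_len(H), times = W)
  base_j <- rep(seq_len(W), each = H)
  off <- expand.grid(di = 0:(k - 1L), dj = 0:(k - 1L), cc = 0:(C - 1L))
  idx <- matrix(0L, nrow = H * W, ncol = k * k * C)
  for (col in seq_len(nrow(off))) {
    idx[, col] <- (base_i + off$di[col]) +
      (base_j + off$dj[col] - 1L) * Hp +
      off$cc[col] * Hp * Wp
  }
  .nn_cache[[key]] <- idx
  idx
}

conv2d_forward <- function(x, W, b) {
  d <- dim(x)
  k <- dim(W)[1]
  Cout <- dim(W)[4]
  p <- (k - 1L) %/% 2L
  xp <- if (p > 0L) nn_pad(x, p) else x
  idx <- im2col_idx(d[1], d[2], d[3], k)
  sz <- prod(dim(xp)[1:3])
  HW <- d[1] * d[2]
  N <- d[4]
  cols <- matrix(0, nrow = HW * N, ncol = ncol(idx))
  for (n in seq_len(N)) {
    cols[(n - 1L) * HW + seq_len(HW), ] <-
      matrix(xp[as.vector(idx) + (n - 1L) * sz], nrow = HW)
  }
  Wm <- matrix(W, nrow = k * k * d[3], ncol = Cout)
  Y <- cols %*% Wm
  Y <- sweep(Y, 2L, b, "+")
  y <- array(0, c(d[1], d[2], Cout, N))
  for (n in seq_len(N)) {
    y[, , , n] <- array(Y[(n - 1L) * HW + seq_len(HW), ], c(d[1], d[2], Cout))
  }
  list(y = y, cache = list(cols = cols, dims = d, k = k, p = p))
}

conv2d_backward <- function(gy, W, cache) {
  d <- cache$dims
  k <- cache$k
  p <- cache$p
  Cout <- dim(W)[4]
  HW <- d[1] * d[2]
  N <- d[4]
  Gm <- matrix(0, nrow = HW * N, ncol = Cout)
  for (n in seq_len(N)) {
    Gm[(n - 1L) * HW + seq_len(HW), ] <- matrix(gy[, , , n], nrow = HW)
  }
  Wm <- matrix(W, nrow = k * k * d[3], ncol = Cout)
  gW <- array(crossprod(cache$cols, Gm), dim(W))
  gb <- colSums(Gm)
  gcols <- Gm %*% t(Wm)
  Hp <- d[1] + 2L * p
  Wp <- d[2] + 2L * p
  idx <- im2col_idx(d[1], d[2], d[3], k)
  szp <- Hp * Wp * d[3]
  gx <- array(0, d)
  iv <- as.vector(idx)
  for (n in seq_len(N)) {
    gpad <- numeric(szp)
    acc <- rowsum(as.vector(gcols[(n - 1L) * HW + seq_len(HW), ]), group = iv,
                  reorder = TRUE)
    gpad[as.integer(rownames(acc))] <- acc[, 1L]
    gp <- array(gpad, c(Hp, Wp, d[3]))
    gx[, , , n] <- gp[p + seq_len(d[1]), p + seq_len(d[2]), , drop = FALSE]
  }
  list(gx = gx, gW = gW, gb = gb)
}

# 2x2/stride-2 transpose convolution: each input pixel emits a 2x2 output
# block, so the whole operation is a per-pixel linear map Cin -> 4*Cout.
convT2_forward <- function(x, W, b) {
  d <- dim(x)
  Cin <- d[3]
  N <- d[4]
  Cout <- dim(W)[4]
  HW <- d[1] * d[2]
  Wm <- matrix(aperm(W, c(3, 1, 2, 4)), nrow = Cin)  # Cin x (2*2*Cout)
  y <- array(0, c(2L * d[1], 2L * d[2], Cout, N))
  ri <- rep(seq_len(d[1]), times = d[2])
  rj <- rep(seq_len(d[2]), each = d[1])
  for (n in seq_len(N)) {
    xm <- matrix(x[, , , n], nrow = HW)
    Ym <- xm %*% Wm  # HW x (di, dj, co)
    col <- 0L
    for (co in seq_len(Cout)) for (dj in 0:1) for (di in 0:1) {
      col <- col + 1L
      # column order of Wm is (di fastest, dj, co)
      cidx <- (co - 1L) * 4L + dj * 2L + di + 1L
      y[cbind(2L * ri - 1L + di, 2L * rj - 1L + dj, co, n)] <-
        Ym[, cidx] + b[co]
    }
  }
  list(y = y, cache = list(dims = d))
}

convT2_backward <- function(gy, x, W) {
  d <- dim(x)
  Cin <- d[3]
  N <- d[4]
  Cout <- dim(W)[4]
  HW <- d[1] * d[2]
  Wm <- matrix(aperm(W, c(3, 1, 2, 4)), nrow = Cin)
  gWm <- matrix(0, nrow = Cin, ncol = 4L * Cout)
  gb <- numeric(Cout)
  gx <- array(0, d)
  ri <- rep(seq_len(d[1]), times = d[2])
  rj <- rep(seq_len(d[2]), each = d[1])
  for (n in seq_len(N)) {
    Gm <- matrix(0, nrow = HW, ncol = 4L * Cout)
    for (co in seq_len(Cout)) for (dj in 0:1) for (di in 0:1) {
      cidx <- (co - 1L) * 4L + dj * 2L + di + 1L
      Gm[, cidx] <- gy[cbind(2L * ri - 1L + di, 2L * rj - 1L + dj, co, n)]
    }
    xm <- matrix(x[, , , n], nrow = HW)
    gWm <- gWm + crossprod(xm, Gm)
    gb <- gb + vapply(seq_len(Cout),
                      function(co) sum(Gm[, (co - 1L) * 4L + 1:4]), numeric(1))
    gx[, , , n] <- array(Gm %*% t(Wm), c(d[1], d[2], Cin))
  }
  gW <- aperm(array(gWm, c(Cin, 2L, 2L, Cout)), c(2, 3, 1, 4))
  list(gx = gx, gW = gW, gb = gb)
}

maxpool2_forward <- function(x) {
  d <- dim(x)
  io <- seq(1L, d[1], by = 2L)
  jo <- seq(1L, d[2], by = 2L)
  a <- x[io, jo, , , drop = FALSE]
  b <- x[io + 1L, jo, , , drop = FALSE]
  cc <- x[io, jo + 1L, , , drop = FALSE]
  dd <- x[io + 1L, jo + 1L, , , drop = FALSE]
  m1 <- pmax(a, b)
  m2 <- pmax(cc, dd)
  y <- pmax(m1, m2)
  code <- array(1L, dim(a))
  code[b > a] <- 2L
  code[m2 > m1] <- 3L
  code[(m2 > m1) & (dd > cc)] <- 4L
  list(y = y, cache = list(code = code, dims = d))
}

maxpool2_backward <- function(gy, cache) {
  d <- cache$dims
  code <- cache$code
  gx <- array(0, d)
  io <- seq(1L, d[1], by = 2L)
  jo <- seq(1L, d[2], by = 2L)
  g1 <- gy; g1[code != 1L] <- 0
  g2 <- gy; g2[code != 2L] <- 0
  g3 <- gy; g3[code != 3L] <- 0
  g4 <- gy; g4[code != 4L] <- 0
  gx[io, jo, , ] <- g1
  gx[io + 1L, jo, , ] <- g2
  gx[io, jo + 1L, , ] <- g3
  gx[io + 1L, jo + 1L, , ] <- g4
  gx
}

upsample2_forward <- function(x) {
  d <- dim(x)
  ri <- rep(seq_len(d[1]), each = 2L)
  rj <- rep(seq_len(d[2]), each = 2L)
  x[ri, rj, , , drop = FALSE]
}

upsample2_backward <- function(gy, dims) {
  io <- seq(1L, 2L * dims[1], by = 2L)
  jo <- seq(1L, 2L * dims[2], by = 2L)
  gy[io, jo, , , drop = FALSE] + gy[io + 1L, jo, , , drop = FALSE] +
    gy[io, jo + 1L, , , drop = FALSE] + gy[io + 1L, jo + 1L, , , drop = FALSE]
}

# ---- graph nodes ------------------------------------------------------------

# A net is list(nodes = <named list>, out = <node name>).  Each node:
#   list(op =, inputs = c(node names), opts = list(), has parameters iff op
#   in conv/convT/dense/bn*).  Parameter names: <node>.W, <node>.b,
#   <node>.gamma, <node>.beta.
nn_node <- function(op, inputs = character(), opts = list()) {
  list(op = op, inputs = inputs, opts = opts)
}

# Initialize parameters for every parameterized node.  `scale` multiplies the
# He/Glorot std; nodes may override via opts$init_scale (e.g. near-identity
# output heads).
nn_init <- function(net, seed) {
  with_seed(seed, {
    params <- list()
    for (nm in names(net$nodes)) {
      nd <- net$nodes[[nm]]
      sc <- if (!is.null(nd$opts$init_scale)) nd$opts$init_scale else 1
      if (nd$op == "conv") {
        k <- nd$opts$k
        cin <- nd$opts$cin
        cout <- nd$opts$cout
        std <- sc * sqrt(2 / (k * k * cin))
        params[[paste0(nm, ".W")]] <-
          array(rnorm(k * k * cin * cout, 0, std), c(k, k, cin, cout))
        params[[paste0(nm, ".b")]] <- numeric(cout)
      } else if (nd$op == "convT") {
        cin <- nd$opts$cin
        cout <- nd$opts$cout
        std <- sc * sqrt(2 / (4 * cin))
        params[[paste0(nm, ".W")]] <-
          array(rnorm(4 * cin * cout, 0, std), c(2, 2, cin, cout))
        params[[paste0(nm, ".b")]] <- numeric(cout)
      } else if (nd$op == "dense") {
        din <- nd$opts$din
        dout <- nd$opts$dout
        std <- sc * sqrt(2 / din)
        params[[paste0(nm, ".W")]] <- matrix(rnorm(din * dout, 0, std), din, dout)
        params[[paste0(nm, ".b")]] <- numeric(dout)
      } else if (nd$op %in% c("bnc", "bnd")) {
        nf <- nd$opts$nf
        params[[paste0(nm, ".gamma")]] <- rep(1, nf)
        params[[paste0(nm, ".beta")]] <- numeric(nf)
      }
    }
    params
  })
}

.bn_eps <- 1e-5

# Forward pass.  xs: named list of input arrays keyed by input-node name.
nn_forward <- function(net, params, xs) {
  vals <- list()
  caches <- list()
  for (nm in names(net$nodes)) {
    nd <- net$nodes[[nm]]
    ins <- lapply(nd$inputs, function(i) vals[[i]])
    v <- NULL
    ch <- NULL
    if (nd$op == "input") {
      v <- xs[[nd$opts$name]]
      if (is.null(v)) stop("missing input '", nd$opts$name, "'")
    } else if (nd$op == "conv") {
      r <- conv2d_forward(ins[[1]], params[[paste0(nm, ".W")]],
                          params[[paste0(nm, ".b")]])
      v <- r$y; ch <- r$cache
    } else if (nd$op == "convT") {
      r <- convT2_forward(ins[[1]], params[[paste0(nm, ".W")]],
                          params[[paste0(nm, ".b")]])
      v <- r$y; ch <- list(x = ins[[1]])
    } else if (nd$op == "pool2") {
      r <- maxpool2_forward(ins[[1]])
      v <- r$y; ch <- r$cache
    } else if (nd$op == "up2") {
      v <- upsample2_forward(ins[[1]])
      ch <- list(dims = dim(ins[[1]]))
    } else if (nd$op == "lrelu") {
      s <- nd$opts$slope
      m <- ins[[1]] >= 0
      v <- ins[[1]] * ifelse(m, 1, s)
      ch <- list(m = m, s = s)
    } else if (nd$op == "relu") {
      m <- ins[[1]] >= 0
      v <- ins[[1]] * m
      ch <- list(m = m)
    } else if (nd$op == "sigmoid") {
      v <- 1 / (1 + exp(-ins[[1]]))
      ch <- list(y = v)
    } else if (nd$op == "add") {
      v <- Reduce(`+`, ins)
    } else if (nd$op == "concat") {
      dims <- lapply(ins, dim)
      ctot <- sum(vapply(dims, function(d) d[3], numeric(1)))
      d1 <- dims[[1]]
      v <- array(0, c(d1[1], d1[2], ctot, d1[4]))
      at <- 0L
      for (x in ins) {
        cx <- dim(x)[3]
        v[, , at + seq_len(cx), ] <- x
        at <- at + cx
      }
      ch <- list(chans = vapply(dims, function(d) d[3], numeric(1)))
    } else if (nd$op == "flatten") {
      d <- dim(ins[[1]])
      v <- t(matrix(ins[[1]], nrow = prod(d[1:3]), ncol = d[4]))
      ch <- list(dims = d)
    } else if (nd$op == "dense") {
      v <- sweep(ins[[1]] %*% params[[paste0(nm, ".W")]], 2L,
                 params[[paste0(nm, ".b")]], "+")
      ch <- list(x = ins[[1]])
    } else if (nd$op == "bnd") {
      x <- ins[[1]]
      mu <- colMeans(x)
      xc <- sweep(x, 2L, mu)
      va <- colMeans(xc^2)
      sd_ <- sqrt(va + .bn_eps)
      xh <- sweep(xc, 2L, sd_, "/")
      g <- params[[paste0(nm, ".gamma")]]
      v <- sweep(sweep(xh, 2L, g, "*"), 2L, params[[paste0(nm, ".beta")]], "+")
      ch <- list(xh = xh, sd = sd_, n = nrow(x))
    } else if (nd$op == "bnc") {
      x <- ins[[1]]
      d <- dim(x)
      xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
      mu <- colMeans(xm)
      xc <- sweep(xm, 2L, mu)
      va <- colMeans(xc^2)
      sd_ <- sqrt(va + .bn_eps)
      xh <- sweep(xc, 2L, sd_, "/")
      g <- params[[paste0(nm, ".gamma")]]
      ym <- sweep(sweep(xh, 2L, g, "*"), 2L, params[[paste0(nm, ".beta")]], "+")
      v <- aperm(array(ym, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
      ch <- list(xh = xh, sd = sd_, n = nrow(xm), dims = d)
    } else if (nd$op == "reshape") {
      dm <- nd$opts$dims
      x <- ins[[1]]
      v <- array(t(x), c(dm, nrow(x)))
      ch <- list(n = nrow(x))
    } else if (nd$op == "chanpool") {
      x <- ins[[1]]
      d <- dim(x)
      mn <- array(0, c(d[1], d[2], 1L, d[4]))
      mx <- array(-Inf, c(d[1], d[2], 1L, d[4]))
      arg <- array(1L, c(d[1], d[2], 1L, d[4]))
      for (cidx in seq_len(d[3])) {
        sl <- x[, , cidx, , drop = FALSE]
        mn <- mn + sl
        upd <- sl > mx
        mx[upd] <- sl[upd]
        arg[upd] <- cidx
      }
      mn <- mn / d[3]
      v <- array(0, c(d[1], d[2], 2L, d[4]))
      v[, , 1L, ] <- mn
      v[, , 2L, ] <- mx
      ch <- list(arg = arg, dims = d)
    } else if (nd$op == "gate") {
      f <- ins[[1]]
      a <- ins[[2]]
      d <- dim(f)
      ab <- array(a[, , rep(1L, d[3]), , drop = FALSE], d)
      v <- f + f * ab
      ch <- list(f = f, ab = ab)
    } else if (nd$op == "mf") {
      v <- mf_reconstruct_map(ins[[1]], rank = nd$opts$rank,
                              iterations = nd$opts$iterations,
                              seed = nd$opts$seed)
      # straight-through backward
    } else if (nd$op == "whiten") {
      x <- ins[[1]]
      d <- dim(x)
      xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
      mu <- colMeans(xm)
      xc <- sweep(xm, 2L, mu)
      S <- crossprod(xc) / nrow(xc) + diag(1e-4, d[3])
      e <- eigen(S, symmetric = TRUE)
      Wz <- e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-8)),
                               length(e$values)) %*% t(e$vectors)
      ym <- xc %*% Wz
      v <- aperm(array(ym, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
      ch <- list(Wz = Wz, dims = d)
    } else {
      stop("unknown op: ", nd$op)
    }
    vals[[nm]] <- v
    caches[[nm]] <- ch
  }
  list(out = vals[[net$out]], vals = vals, caches = caches)
}

# Backward pass from gradient at the output node.  Returns list(gx = named
# list of gradients at input nodes, grads = named list matching params).
nn_backward <- function(net, params, fw, gout) {
  gvals <- list()
  gvals[[net$out]] <- gout
  grads <- list()
  gx <- list()
  for (nm in rev(names(net$nodes))) {
    g <- gvals[[nm]]
    if (is.null(g)) next
    nd <- net$nodes[[nm]]
    ch <- fw$caches[[nm]]
    push <- function(to, val) {
      gvals[[to]] <<- if (is.null(gvals[[to]])) val else gvals[[to]] + val
    }
    if (nd$op == "input") {
      gx[[nd$opts$name]] <- g
    } else if (nd$op == "conv") {
      W <- params[[paste0(nm, ".W")]]
      r <- conv2d_backward(g, W, ch)
      grads[[paste0(nm, ".W")]] <- r$gW
      grads[[paste0(nm, ".b")]] <- r$gb
      push(nd$inputs[1], r$gx)
    } else if (nd$op == "convT") {
      W <- params[[paste0(nm, ".W")]]
      r <- convT2_backward(g, ch$x, W)
      grads[[paste0(nm, ".W")]] <- r$gW
      grads[[paste0(nm, ".b")]] <- r$gb
      push(nd$inputs[1], r$gx)
    } else if (nd$op == "pool2") {
      push(nd$inputs[1], maxpool2_backward(g, ch))
    } else if (nd$op == "up2") {
      push(nd$inputs[1], upsample2_backward(g, ch$dims))
    } else if (nd$op == "lrelu") {
      push(nd$inputs[1], g * ifelse(ch$m, 1, ch$s))
    } else if (nd$op == "relu") {
      push(nd$inputs[1], g * ch$m)
    } else if (nd$op == "sigmoid") {
      push(nd$inputs[1], g * ch$y * (1 - ch$y))
    } else if (nd$op == "add") {
      for (i in nd$inputs) push(i, g)
    } else if (nd$op == "concat") {
      at <- 0L
      for (ii in seq_along(nd$inputs)) {
        cx <- ch$chans[ii]
        push(nd$inputs[ii], g[, , at + seq_len(cx), , drop = FALSE])
        at <- at + cx
      }
    } else if (nd$op == "flatten") {
      push(nd$inputs[1], array(t(g), ch$dims))
    } else if (nd$op == "dense") {
      W <- params[[paste0(nm, ".W")]]
      grads[[paste0(nm, ".W")]] <- crossprod(ch$x, g)
      grads[[paste0(nm, ".b")]] <- colSums(g)
      push(nd$inputs[1], g %*% t(W))
    } else if (nd$op == "bnd" || nd$op == "bnc") {
      gmat <- if (nd$op == "bnd") g else {
        d <- ch$dims
        matrix(aperm(g, c(1, 2, 4, 3)), ncol = d[3])
      }
      gamma <- params[[paste0(nm, ".gamma")]]
      grads[[paste0(nm, ".gamma")]] <- colSums(gmat * ch$xh)
      grads[[paste0(nm, ".beta")]] <- colSums(gmat)
      n <- ch$n
      gh <- sweep(gmat, 2L, gamma, "*")
      t1 <- sweep(gh, 2L, colMeans(gh))
      t2 <- sweep(ch$xh, 2L, colMeans(gh * ch$xh), "*")
      gm <- sweep(t1 - t2, 2L, ch$sd, "/")
      if (nd$op == "bnd") {
        push(nd$inputs[1], gm)
      } else {
        d <- ch$dims
        push(nd$inputs[1],
             aperm(array(gm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3)))
      }
    } else if (nd$op == "reshape") {
      push(nd$inputs[1], t(matrix(g, ncol = ch$n)))
    } else if (nd$op == "chanpool") {
      d <- ch$dims
      gi <- array(0, d)
      gmn <- g[, , 1L, , drop = FALSE] / d[3]
      for (cidx in seq_len(d[3])) {
        gi[, , cidx, ] <- gmn
      }
      gmx <- g[, , 2L, , drop = FALSE]
      for (cidx in seq_len(d[3])) {
        sel <- ch$arg == cidx
        tmp <- gi[, , cidx, , drop = FALSE]
        tmp[sel] <- tmp[sel] + gmx[sel]
        gi[, , cidx, ] <- tmp
      }
      push(nd$inputs[1], gi)
    } else if (nd$op == "gate") {
      push(nd$inputs[1], g * (1 + ch$ab))
      ga <- g * ch$f
      d <- dim(ch$f)
      ga1 <- array(0, c(d[1], d[2], 1L, d[4]))
      for (cidx in seq_len(d[3])) ga1 <- ga1 + ga[, , cidx, , drop = FALSE]
      push(nd$inputs[2], ga1)
    } else if (nd$op == "mf") {
      push(nd$inputs[1], g)  # straight-through
    } else if (nd$op == "whiten") {
      d <- ch$dims
      gm <- matrix(aperm(g, c(1, 2, 4, 3)), ncol = d[3])
      gxm <- gm %*% t(ch$Wz)  # whitening matrix treated as constant
      push(nd$inputs[1],
           aperm(array(gxm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3)))
    }
  }
  list(gx = gx, grads = grads)
}

n_params <- function(params) sum(vapply(params, length, numeric(1)))

# ---- Adamax -----------------------------------------------------------------

adamax_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       u = lapply(params, function(p) p * 0),
       t = 0L)
}

adamax_step <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc <- 1 - beta1^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$u[[nm]] <- pmax(beta2 * state$u[[nm]], abs(g))
    params[[nm]] <- params[[nm]] -
      (lr / bc) * state$m[[nm]] / (state$u[[nm]] + eps)
  }
  list(params = params, state = state)
}

# Stack a list of H x W matrices into an (H, W, 1, N) batch.
as_batch <- function(imgs) {
  d <- dim(imgs[[1]])
  x <- array(0, c(d[1], d[2], 1L, length(imgs)))
  for (i in seq_along(imgs)) x[, , 1L, i] <- imgs[[i]]
  x
}

batch_to_list <- function(x) {
  lapply(seq_len(dim(x)[4]), function(i) x[, , 1L, i])
}
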