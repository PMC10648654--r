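# Nonnegative matrix factorization by multiplicative updates: the numerical
# core of the MD denoising block, which factors the flattened bottleneck map
# into two nonnegative submatrices and reconstructs it as a structured,
# low-rank feature.

#' Construct a nonnegative factor pair
#'
#' @param w Nonnegative n x r matrix.
#' @param h Nonnegative r x m matrix.
#' @return A `factor_pair` list.
#' @export
factor_pair <- function(w, h) {
  if (any(w < 0) || any(h < 0)) stop("factors must be nonnegative")
  if (ncol(w) != nrow(h)) stop("inner dimensions of w and h must agree")
  structure(list(w = w, h = h), class = "factor_pair")
}

#' Seeded random initialization for NMF
#'
#' @param v Nonnegative matrix to factor.
#' @param rank Inner dimension r.
#' @param seed Integer seed.
#' @return A `factor_pair`.
#' @export
mf_init <- function(v, rank, seed = 1L) {
  with_seed(seed, {
    sc <- sqrt(mean(v) / rank + 1e-12)
    factor_pair(matrix(stats::runif(nrow(v) * rank, 0.2, 1) * sc, nrow(v)),
                matrix(stats::runif(rank * ncol(v), 0.2, 1) * sc, rank))
  })
}

#' Frobenius NMF objective
#'
#' @param v Target matrix.
#' @param factors A `factor_pair`.
#' @return `||v - w h||_F^2`.
#' @export
mf_objective <- function(v, factors) {
  sum((v - factors$w %*% factors$h)^2)
}

#' Multiplicative NMF updates
#'
#' Applies the standard multiplicative update rules for the Frobenius
#' objective `||V - WH||^2`.  Each update is individually non-increasing in
#' the objective; entries are floored at 1e-12 to preserve strict
#' nonnegativity.
#'
#' @param v Nonnegative matrix.
#' @param factors A `factor_pair` with compatible shapes.
#' @param iterations Number of (H, W) update sweeps.
#' @return The updated `factor_pair`.
#' @export
mf_update <- function(v, factors, iterations = 30L) {
  if (any(v < 0)) stop("v must be nonnegative")
  w <- factors$w
  h <- factors$h
  eps <- 1e-12
  for (i in seq_len(iterations)) {
    h <- pmax(h * (crossprod(w, v)) / (crossprod(w, w %*% h) + eps), eps)
    w <- pmax(w * (v %*% t(h)) / (w %*% (h %*% t(h)) + eps), eps)
  }
  factor_pair(w, h)
}

# Low-rank NMF reconstruction of a (H, W, C, N) feature map, flattened as
# channels x pixels per sample.  Negative values are handled by a per-sample
# min shift.  Used inside the MD block; backward is straight-through.
mf_reconstruct_map <- function(x, rank, iterations, seed = 1L) {
  d <- dim(x)
  out <- x
  for (n in seq_len(d[4])) {
    v <- t(matrix(x[, , , n], nrow = d[1] * d[2], ncol = d[3]))  # C x HW
    lo <- min(v)
    v0 <- v - lo
    r <- min(rank, nrow(v0), ncol(v0))
    if (max(v0) < 1e-10) {
      rec <- v0 * 0
    } else {
      f <- mf_update(v0, mf_init(v0, r, derive_seed(seed, n)), iterations)
      rec <- f$w %*% f$h
    }
    out[, , , n] <- array(t(rec + lo), c(d[1], d[2], d[3]))
  }
  out
}
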