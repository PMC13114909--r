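# Differentiable layer primitives.
#
# Every *_fwd returns list(y = output, cache = what backward needs); every
# *_bwd consumes the upstream gradient plus that cache and returns dx along
# with parameter gradients. Two data layouts are used:
#   - "col" layout: m x p matrices, features in columns (dense heads);
#   - "row" layout: C x (n*T) matrices, channels in rows with column index
#     (t-1)*n + i (sample fastest), used by the convolutional pipeline.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

## ---- fully connected --------------------------------------------------------

fc_fwd <- function(x, W, b) {
  y <- x %*% W          # fresh allocation; bias added in place
  add_bias_inplace(y, b)
  list(y = y, cache = list(x = x, W = W))
}

fc_bwd <- function(dy, cache) {
  list(dx = dy %*% t(cache$W),
       dW = crossprod(cache$x, dy),
       db = colSums(dy))
}

## ---- batch normalization ----------------------------------------------------

# column layout: statistics per column over the batch dimension
bnc_fwd <- function(x, g, b, rm, rv, training) {
  if (training) {
    mu <- colMeans(x)
    v <- colMeans(sweep(x, 2L, mu)^2)
    rm <- (1 - BN_MOMENTUM) * rm + BN_MOMENTUM * mu
    rv <- (1 - BN_MOMENTUM) * rv + BN_MOMENTUM * v
  } else {
    mu <- rm
    v <- rv
  }
  invstd <- 1 / sqrt(v + BN_EPS)
  xhat <- sweep(sweep(x, 2L, mu), 2L, invstd, "*")
  y <- sweep(sweep(xhat, 2L, g, "*"), 2L, b, "+")
  list(y = y, cache = list(xhat = xhat, invstd = invstd, g = g,
                           training = training),
       rm = rm, rv = rv)
}

bnc_bwd <- function(dy, cache) {
  dg <- colSums(dy * cache$xhat)
  db <- colSums(dy)
  dxhat <- sweep(dy, 2L, cache$g, "*")
  if (cache$training) {
    m <- nrow(dy)
    s1 <- colMeans(dxhat)
    s2 <- colMeans(dxhat * cache$xhat)
    dx <- sweep(dxhat - rep(s1, each = m) - cache$xhat * rep(s2, each = m),
                2L, cache$invstd, "*")
  } else {
    dx <- sweep(dxhat, 2L, cache$invstd, "*")
  }
  list(dx = dx, dg = dg, db = db)
}

# row layout: statistics per row over all (sample, time) columns
bnr_fwd <- function(x, g, b, rm, rv, training) {
  if (training) {
    mu <- rowMeans(x)
    v <- rowMeans((x - mu)^2)
    rm <- (1 - BN_MOMENTUM) * rm + BN_MOMENTUM * mu
    rv <- (1 - BN_MOMENTUM) * rv + BN_MOMENTUM * v
  } else {
    mu <- rm
    v <- rv
  }
  invstd <- 1 / sqrt(v + BN_EPS)
  xhat <- (x - mu) * invstd
  y <- xhat * g + b
  list(y = y, cache = list(xhat = xhat, invstd = invstd, g = g,
                           training = training),
       rm = rm, rv = rv)
}

bnr_bwd <- function(dy, cache) {
  dg <- rowSums(dy * cache$xhat)
  db <- rowSums(dy)
  dxhat <- dy * cache$g
  if (cache$training) {
    s1 <- rowMeans(dxhat)
    s2 <- rowMeans(dxhat * cache$xhat)
    dx <- (dxhat - s1 - cache$xhat * s2) * cache$invstd
  } else {
    dx <- dxhat * cache$invstd
  }
  list(dx = dx, dg = dg, db = db)
}

## ---- pointwise --------------------------------------------------------------

relu_fwd <- function(x) {
  m <- x > 0
  list(y = x * m, cache = m)
}
relu_bwd <- function(dy, cache) dy * cache

# inverted dropout: scales at train time so inference is the identity
dropout_fwd <- function(x, p, training) {
  if (!training || p <= 0) {
    return(list(y = x, cache = NULL))
  }
  keep <- 1 - p
  mask <- (matrix(runif(length(x)), nrow(x)) < keep) / keep
  list(y = x * mask, cache = mask)
}

dropout_bwd <- function(dy, cache) {
  if (is.null(cache)) dy else dy * cache
}

## ---- 1-D convolution over time (row layout) ---------------------------------

# x: C_in x (n*T); W: C_out x (C_in*k); stride 1, zero padding `pad`.
conv1d_fwd <- function(x, W, b, n, T, k, pad) {
  c_in <- nrow(x)
  xa <- array(x, c(c_in, n, T))
  xp <- array(0, c(c_in, n, T + 2L * pad))
  xp[, , pad + seq_len(T)] <- xa
  Xc <- matrix(0, c_in * k, n * T)
  for (o in seq_len(k)) {
    Xc[(o - 1L) * c_in + seq_len(c_in), ] <-
      matrix(xp[, , o:(o + T - 1L)], c_in, n * T)
  }
  y <- W %*% Xc + b
  list(y = y, cache = list(Xc = Xc, W = W, n = n, T = T, k = k, pad = pad,
                           c_in = c_in))
}

conv1d_bwd <- function(dy, cache) {
  W <- cache$W
  n <- cache$n
  T <- cache$T
  k <- cache$k
  pad <- cache$pad
  c_in <- cache$c_in
  dW <- tcrossprod(dy, cache$Xc)
  db <- rowSums(dy)
  dXc <- crossprod(W, dy)
  dxp <- array(0, c(c_in, n, T + 2L * pad))
  for (o in seq_len(k)) {
    dxp[, , o:(o + T - 1L)] <- dxp[, , o:(o + T - 1L)] +
      array(dXc[(o - 1L) * c_in + seq_len(c_in), ], c(c_in, n, T))
  }
  dx <- matrix(dxp[, , pad + seq_len(T)], c_in, n * T)
  list(dx = dx, dW = dW, db = db)
}

# max pooling over time, kernel 2 stride 2 (row layout); ties keep the first
maxpool2_fwd <- function(x, n, T) {
  C <- nrow(x)
  xa <- array(x, c(C, n, T))
  a <- xa[, , seq(1L, T, 2L), drop = FALSE]
  b <- xa[, , seq(2L, T, 2L), drop = FALSE]
  mask <- a >= b
  y <- matrix(pmax(a, b), C, n * T / 2L)
  list(y = y, cache = list(mask = mask, n = n, T = T, C = C))
}

maxpool2_bwd <- function(dy, cache) {
  C <- cache$C
  n <- cache$n
  T <- cache$T
  dya <- array(dy, c(C, n, T / 2L))
  dxa <- array(0, c(C, n, T))
  dxa[, , seq(1L, T, 2L)] <- dya * cache$mask
  dxa[, , seq(2L, T, 2L)] <- dya * !cache$mask
  matrix(dxa, C, n * T)
}

# adaptive average pool to length 1: (C, n*T) row layout -> (n, C)
avgpool_fwd <- function(x, n, T) {
  C <- nrow(x)
  y <- t(rowSums(array(x, c(C, n, T)), dims = 2L)) / T
  list(y = y, cache = list(n = n, T = T, C = C))
}

avgpool_bwd <- function(dy, cache) {
  # each time slice receives dy / T
  matrix(array(rep(as.vector(t(dy)) / cache$T, cache$T),
               c(cache$C, cache$n, cache$T)),
         cache$C, cache$n * cache$T)
}

## ---- layer normalization (per row over features) ----------------------------

ln_fwd <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  invstd <- 1 / sqrt(rowMeans(xc^2) + BN_EPS)
  xhat <- xc * invstd
  y <- sweep(xhat, 2L, g, "*")
  y <- sweep(y, 2L, b, "+")
  list(y = y, cache = list(xhat = xhat, invstd = invstd, g = g))
}

ln_bwd <- function(dy, cache) {
  dg <- colSums(dy * cache$xhat)
  db <- colSums(dy)
  dxhat <- sweep(dy, 2L, cache$g, "*")
  s1 <- rowMeans(dxhat)
  s2 <- rowMeans(dxhat * cache$xhat)
  dx <- (dxhat - s1 - cache$xhat * s2) * cache$invstd
  list(dx = dx, dg = dg, db = db)
}
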