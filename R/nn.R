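# Minimal CPU convolution engine used by the cGAN core. Tensors are 3-D
# arrays (height, width, channels); convolutions are implemented as im2col
# followed by a matrix product, so the BLAS does the heavy lifting.
# Weight layout: a (k*k*Cin) x Cout matrix whose row for kernel offset
# (di, dj) (1-based, di fastest) and input channel c is
# ((dj-1)*k + di - 1)*Cin + c.

# Geometry-dependent index maps are memoized: the gather map sends each
# (output position, kernel offset, channel) to its flat index in the padded
# input, so im2col is one vectorized subscript and the backward scatter is
# one sparse matrix-vector product.
.conv_cache <- new.env(parent = emptyenv())

conv_geom <- function(H, W, C, k, stride, pad) {
  key <- paste(H, W, C, k, stride, pad, sep = "x")
  g <- .conv_cache[[key]]
  if (!is.null(g)) return(g)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  outH <- (Hp - k) %/% stride + 1L
  outW <- (Wp - k) %/% stride + 1L
  M <- matrix(0L, outH * outW, k * k * C)
  o <- 0L
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    ri <- seq.int(di, by = stride, length.out = outH)
    ci <- seq.int(dj, by = stride, length.out = outW)
    base <- as.vector(outer(ri, (ci - 1L) * Hp, "+"))
    M[, o * C + seq_len(C)] <- outer(base, (seq_len(C) - 1L) * Hp * Wp, "+")
    o <- o + 1L
  }
  Mvec <- as.vector(M)
  # sparse scatter operator: accumulates column-space gradients back onto
  # the padded input grid in one sparse matrix-vector product
  S <- Matrix::sparseMatrix(i = Mvec, j = seq_along(Mvec), x = 1,
                            dims = c(Hp * Wp * C, length(Mvec)))
  g <- list(M = M, S = S, Hp = Hp, Wp = Wp, outH = outH, outW = outW)
  .conv_cache[[key]] <- g
  g
}

im2col <- function(x, k, stride, pad) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  g <- conv_geom(H, W, C, k, stride, pad)
  if (pad > 0) {
    xp <- array(0, c(g$Hp, g$Wp, C))
    xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  } else xp <- x
  cols <- xp[g$M]
  dim(cols) <- dim(g$M)
  list(cols = cols, outH = g$outH, outW = g$outW, xdim = d,
       k = k, stride = stride, pad = pad, geom = g)
}

conv_fwd <- function(x, W, b, k, stride, pad) {
  ic <- im2col(x, k, stride, pad)
  y <- ic$cols %*% W
  y <- y + matrix(b, nrow(y), length(b), byrow = TRUE)
  dim(y) <- c(ic$outH, ic$outW, length(b))
  list(y = y, cache = ic)
}

conv_bwd <- function(gy, cache, W) {
  cout <- dim(gy)[3]
  dim(gy) <- c(cache$outH * cache$outW, cout)
  gW <- crossprod(cache$cols, gy)
  gb <- colSums(gy)
  gcols <- tcrossprod(gy, W)
  d <- cache$xdim; pad <- cache$pad; C <- d[3]
  g <- cache$geom
  gxp <- as.numeric(g$S %*% as.vector(gcols))
  dim(gxp) <- c(g$Hp, g$Wp, C)
  gx <- if (pad > 0) gxp[pad + seq_len(d[1]), pad + seq_len(d[2]), , drop = FALSE]
        else gxp
  list(gW = gW, gb = gb, gx = gx)
}

upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
}

upsample2_bwd <- function(gy) {
  d <- dim(gy)
  oi <- seq.int(1L, d[1], 2L); ei <- oi + 1L
  oj <- seq.int(1L, d[2], 2L); ej <- oj + 1L
  gy[oi, oj, , drop = FALSE] + gy[ei, oj, , drop = FALSE] +
    gy[oi, ej, , drop = FALSE] + gy[ei, ej, , drop = FALSE]
}

ccat <- function(a, b) {
  d <- dim(a)
  array(c(a, b), c(d[1], d[2], d[3] + dim(b)[3]))
}

# Instance normalization: per-channel standardization over the spatial
# plane with learnable affine (gamma, beta). This is what batch-size-1
# batch normalization degenerates to, i.e. the pix2pix training regime.
inorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x); n <- d[1] * d[2]; C <- d[3]
  m <- x; dim(m) <- c(n, C)
  mu <- colMeans(m)
  xc <- m - matrix(mu, n, C, byrow = TRUE)
  s <- sqrt(colMeans(xc * xc) + eps)
  xhat <- xc / matrix(s, n, C, byrow = TRUE)
  y <- xhat * matrix(gamma, n, C, byrow = TRUE) +
    matrix(beta, n, C, byrow = TRUE)
  dim(y) <- d
  list(y = y, xhat = xhat, s = s, d = d)
}

inorm_bwd <- function(gy, cache, gamma) {
  d <- cache$d; n <- d[1] * d[2]; C <- d[3]
  gm <- gy; dim(gm) <- c(n, C)
  xhat <- cache$xhat
  gg <- colSums(gm * xhat)
  gb <- colSums(gm)
  coef <- matrix(gamma / cache$s, n, C, byrow = TRUE)
  gx <- coef * (gm - matrix(gb / n, n, C, byrow = TRUE) -
                xhat * matrix(gg / n, n, C, byrow = TRUE))
  dim(gx) <- d
  list(gx = gx, gg = gg, gb = gb)
}

lrelu <- function(x, slope = 0.2) {
  neg <- x < 0
  x[neg] <- slope * x[neg]
  list(y = x, neg = neg)
}

lrelu_bwd <- function(gy, neg, slope = 0.2) {
  gy[neg] <- slope * gy[neg]
  gy
}

hardtanh <- function(x) {
  list(y = clip(x, -1, 1), mask = x >= -1 & x <= 1)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softplus <- function(x) {
  out <- x
  pos <- x > 0
  out[pos] <- x[pos] + log1p(exp(-x[pos]))
  out[!pos] <- log1p(exp(x[!pos]))
  out
}

# Adam optimizer over a flat named list of parameter arrays.
adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0), v = lapply(par, function(p) p * 0),
       t = 0L)
}

adam_step <- function(par, grads, state, lr, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (nm in names(par)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    par[[nm]] <- par[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(par = par, state = state)
}
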