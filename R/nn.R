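# Layer primitives of the training stack. Activations are double arrays of
# dim (H, W, C, N); every forward returns the output plus the cache its
# backward needs. Convolution/pooling kernels live in src/convops.cpp.

SELU_LAMBDA <- 1.0507009873554805
SELU_ALPHA <- 1.6732632423543772

seluForward <- function(x) list(y = seluFwd(x), cache = x)

seluBackward <- function(cache, dy) seluBwd(cache, dy)

# group normalisation over (H, W, C/G) blocks, per sample
gnForward <- function(x, gamma, beta, G, eps = 1e-5) {
  f <- gnFwd(x, gamma, beta, as.integer(G), eps)
  list(y = f$y, cache = list(xhat = f$xhat, rstd = f$rstd, gamma = gamma,
                             G = G))
}

gnBackward <- function(cache, dy) {
  b <- gnBwd(cache$xhat, cache$rstd, cache$gamma, dy, as.integer(cache$G))
  list(dx = b$dx, dgamma = b$dgamma, dbeta = b$dbeta)
}

# pixelwise 2-class softmax collapsed to the foreground probability
softmax2Forward <- function(logits) {
  d <- dim(logits)
  z0 <- logits[, , 1, , drop = FALSE]
  z1 <- logits[, , 2, , drop = FALSE]
  p <- 1 / (1 + exp(z0 - z1))
  dim(p) <- d[c(1, 2, 4)]
  list(p = p, cache = p)
}

softmax2Backward <- function(cache, dp) {
  p <- cache
  dz1 <- dp * p * (1 - p)
  d <- dim(p)
  out <- array(0, c(d[1], d[2], 2, d[3]))
  out[, , 1, ] <- -dz1
  out[, , 2, ] <- dz1
  out
}

# 1x1 convolution (channel-mixing head)
conv1x1Forward <- function(x, w, b) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  Cout <- ncol(w)
  y <- array(0, c(H, W, Cout, N))
  xm <- x; dim(xm) <- c(H * W, C, N)
  for (n in seq_len(N))
    y[, , , n] <- array(xm[, , n] %*% w, c(H, W, Cout)) +
      rep(b, each = H * W)
  list(y = y, cache = list(x = x))
}

conv1x1Backward <- function(cache, w, dy) {
  x <- cache$x
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  Cout <- ncol(w)
  xm <- x; dim(xm) <- c(H * W, C, N)
  dym <- dy; dim(dym) <- c(H * W, Cout, N)
  dx <- array(0, d)
  dw <- matrix(0, C, Cout)
  db <- numeric(Cout)
  for (n in seq_len(N)) {
    dx[, , , n] <- array(dym[, , n] %*% t(w), c(H, W, C))
    dw <- dw + t(xm[, , n]) %*% dym[, , n]
    db <- db + colSums(dym[, , n])
  }
  list(dx = dx, dw = dw, db = db)
}

concatC <- function(a, b) concatChannels(a, b)

splitC <- function(x, c1) splitChannels(x, as.integer(c1))

# --- parameter trees ---------------------------------------------------------

treeMap <- function(f, x, ...) {
  others <- list(...)
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (i in seq_along(x))
      out[[i]] <- do.call(treeMap, c(list(f, x[[i]]),
                                     lapply(others, `[[`, i)))
    out
  } else {
    do.call(f, c(list(x), others))
  }
}

treeZero <- function(x) treeMap(function(v) v * 0, x)

adamInit <- function(params) {
  list(m = treeZero(params), v = treeZero(params), t = 0)
}

adamStep <- function(params, grads, state, lr, decays) {
  b1 <- decays[1]; b2 <- decays[2]
  state$t <- state$t + 1
  state$m <- treeMap(function(m, g) b1 * m + (1 - b1) * g, state$m, grads)
  state$v <- treeMap(function(v, g) b2 * v + (1 - b2) * g^2, state$v, grads)
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  params <- treeMap(function(p, m, v)
    p - lr * (m / c1) / (sqrt(v / c2) + 1e-8),
    params, state$m, state$v)
  list(params = params, state = state)
}

# --- convolution dispatch ----------------------------------------------------
# The compiled kernels run single-precision GEMM. For numerical verification
# (tiny fixtures, finite-difference oracles) a pure-R double-precision
# reference path can be enabled with options(iplfseg.referenceConv = TRUE).

convRefCol <- function(x, n, H, W, C) {
  xp <- array(0, c(H + 2, W + 2, C))
  xp[2:(H + 1), 2:(W + 1), ] <- x[, , , n]
  col <- matrix(0, H * W, 9 * C)
  for (c in seq_len(C)) for (kx in -1:1) for (ky in -1:1) {
    r <- (c - 1) * 9 + (kx + 1) * 3 + (ky + 1) + 1
    col[, r] <- as.vector(xp[(2 + ky):(H + 1 + ky), (2 + kx):(W + 1 + kx), c])
  }
  col
}

convRefForward <- function(x, wm, b) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  Cout <- ncol(wm)
  y <- array(0, c(H, W, Cout, N))
  for (n in seq_len(N))
    y[, , , n] <- array(convRefCol(x, n, H, W, C) %*% wm, c(H, W, Cout)) +
      rep(b, each = H * W)
  y
}

convRefBackward <- function(x, wm, dy) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  Cout <- ncol(wm)
  dw <- matrix(0, 9 * C, Cout); db <- numeric(Cout)
  dx <- array(0, d)
  for (n in seq_len(N)) {
    col <- convRefCol(x, n, H, W, C)
    dyn <- matrix(dy[, , , n], H * W, Cout)
    dw <- dw + t(col) %*% dyn
    db <- db + colSums(dyn)
    dcol <- dyn %*% t(wm)
    dxp <- array(0, c(H + 2, W + 2, C))
    for (c in seq_len(C)) for (kx in -1:1) for (ky in -1:1) {
      r <- (c - 1) * 9 + (kx + 1) * 3 + (ky + 1) + 1
      dxp[(2 + ky):(H + 1 + ky), (2 + kx):(W + 1 + kx), c] <-
        dxp[(2 + ky):(H + 1 + ky), (2 + kx):(W + 1 + kx), c] +
        matrix(dcol[, r], H, W)
    }
    dx[, , , n] <- dxp[2:(H + 1), 2:(W + 1), ]
  }
  list(dx = dx, dw = dw, db = db)
}

# returns list(y, ctx); ctx carries the im2col matrix for the backward pass
convF <- function(x, w, b) {
  if (isTRUE(getOption("iplfseg.referenceConv")))
    list(y = convRefForward(x, w, b), ctx = NULL)
  else {
    f <- conv3x3ForwardC(x, w, b)
    list(y = f$y, ctx = f$col)
  }
}

convB <- function(ctx, x, w, dy) {
  if (is.null(ctx)) convRefBackward(x, w, dy)
  else conv3x3BackwardC(ctx, w, dy, dim(x))
}

# convolution block: two (3x3 conv -> group norm -> SeLU) stages
blockInit <- function(cin, cout, groups) {
  sd1 <- sqrt(1 / (9 * cin)); sd2 <- sqrt(1 / (9 * cout))
  list(w1 = matrix(rnorm(9 * cin * cout, sd = sd1), 9 * cin, cout),
       b1 = numeric(cout),
       g1 = rep(1, cout), be1 = numeric(cout),
       w2 = matrix(rnorm(9 * cout * cout, sd = sd2), 9 * cout, cout),
       b2 = numeric(cout),
       g2 = rep(1, cout), be2 = numeric(cout))
}

blockForward <- function(bp, x, G) {
  c1 <- convF(x, bp$w1, bp$b1)
  n1 <- gnForward(c1$y, bp$g1, bp$be1, G)
  a1 <- seluForward(n1$y)
  c2 <- convF(a1$y, bp$w2, bp$b2)
  n2 <- gnForward(c2$y, bp$g2, bp$be2, G)
  a2 <- seluForward(n2$y)
  list(y = a2$y, cache = list(x = x, a1 = a1$y, s1 = a1$cache,
                              s2 = a2$cache, n1 = n1$cache, n2 = n2$cache,
                              ctx1 = c1$ctx, ctx2 = c2$ctx))
}

blockBackward <- function(bp, cache, dy) {
  d2 <- seluBackward(cache$s2, dy)
  g2 <- gnBackward(cache$n2, d2)
  cb2 <- convB(cache$ctx2, cache$a1, bp$w2, g2$dx)
  d1 <- seluBackward(cache$s1, cb2$dx)
  g1 <- gnBackward(cache$n1, d1)
  cb1 <- convB(cache$ctx1, cache$x, bp$w1, g1$dx)
  list(dx = cb1$dx,
       grads = list(w1 = cb1$dw, b1 = cb1$db, g1 = g1$dgamma,
                    be1 = g1$dbeta, w2 = cb2$dw, b2 = cb2$db,
                    g2 = g2$dgamma, be2 = g2$dbeta))
}
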