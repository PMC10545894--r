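# Minimal neural-network primitives with manual backpropagation.
#
# Feature maps are stored as arrays [H, W, C, N]; convolutions run per
# sample via im2col + BLAS matrix products. All layers expose a
# forward(params, x) -> list(out, cache) / backward(params, cache, dout)
# pair; gradients mirror the parameter structure. Gradient correctness is
# established by finite-difference tests.

.convGeom <- function(inH, inW, kh, kw, stride, pad) {
  outH <- (inH + 2L * pad - kh) %/% stride + 1L
  outW <- (inW + 2L * pad - kw) %/% stride + 1L
  list(outH = outH, outW = outW)
}

# linear indices into the zero-padded [Hp, Wp, C] array for im2col;
# rows ordered (ky, kx, c), columns ordered (oy, ox)
.im2colIndex <- function(inH, inW, C, kh, kw, stride, pad) {
  Hp <- inH + 2L * pad
  Wp <- inW + 2L * pad
  g <- .convGeom(inH, inW, kh, kw, stride, pad)
  ky <- rep(seq_len(kh) - 1L, times = kw * C)
  kx <- rep(rep(seq_len(kw) - 1L, each = kh), times = C)
  cc <- rep(seq_len(C) - 1L, each = kh * kw)
  rowOff <- ky + kx * Hp + cc * (Hp * Wp)
  oy <- rep(seq_len(g$outH) - 1L, times = g$outW)
  ox <- rep(seq_len(g$outW) - 1L, each = g$outH)
  colOff <- oy * stride + ox * stride * Hp
  idx <- outer(rowOff, colOff, "+") + 1L
  list(idx = idx, Hp = Hp, Wp = Wp, outH = g$outH, outW = g$outW)
}

.pad3 <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, dim = c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  xp
}

# x: [H, W, C, N]; W matrix (cout x kh*kw*cin); returns [outH, outW, cout, N]
# whole batch gathered into one K x (L*N) matrix -> a single BLAS product
.convForward <- function(lay, x, keepCache = TRUE) {
  d <- dim(x)
  N <- d[4]
  ii <- .im2colIndex(d[1], d[2], d[3], lay$kh, lay$kw, lay$stride, lay$pad)
  K <- nrow(ii$idx); L <- ncol(ii$idx)
  cols <- matrix(0, K, L * N)
  if (lay$pad == 0L) {
    for (n in seq_len(N))
      cols[, (n - 1L) * L + seq_len(L)] <- x[, , , n][ii$idx]
  } else {
    for (n in seq_len(N)) {
      xp <- .pad3(array(x[, , , n], dim = d[1:3]), lay$pad)
      cols[, (n - 1L) * L + seq_len(L)] <- xp[ii$idx]
    }
  }
  y <- lay$W %*% cols + lay$b                      # cout x (L*N)
  out <- aperm(array(y, dim = c(lay$cout, L, N)), c(2, 1, 3))
  out <- array(out, dim = c(ii$outH, ii$outW, lay$cout, N))
  list(out = out,
       cache = list(cols = if (keepCache) cols else NULL, ii = ii,
                    inDim = d))
}

.convBackward <- function(lay, cache, dout) {
  ii <- cache$ii
  d <- cache$inDim
  N <- d[4]
  K <- nrow(ii$idx); L <- ncol(ii$idx)
  # dout [outH, outW, cout, N] -> cout x (L*N)
  dy <- matrix(aperm(array(dout, dim = c(L, lay$cout, N)), c(2, 1, 3)),
               lay$cout, L * N)
  dW <- tcrossprod(dy, cache$cols)
  db <- rowSums(dy)
  dcols <- crossprod(lay$W, dy)                    # K x (L*N)
  # scatter-accumulate: for a fixed kernel offset the L target indices are
  # distinct, so each row is a plain vectorized assignment
  Hp <- ii$Hp; Wp <- ii$Wp
  dxp <- matrix(0, Hp * Wp * d[3], N)
  dim(dcols) <- c(K, L, N)
  for (k in seq_len(K)) {
    tgt <- ii$idx[k, ]
    dxp[tgt, ] <- dxp[tgt, ] + dcols[k, , ]
  }
  dxp <- array(dxp, dim = c(Hp, Wp, d[3], N))
  dx <- if (lay$pad == 0L) dxp else
    dxp[lay$pad + seq_len(d[1]), lay$pad + seq_len(d[2]), , , drop = FALSE]
  list(dx = dx, grads = list(W = dW, b = db))
}

.bnEps <- 1e-5

# per-channel batch normalization over (H, W, N); exact = TRUE overwrites
# the running statistics with this batch's (post-training re-estimation)
.bnForward <- function(lay, x, train, exact = FALSE) {
  d <- dim(x)
  m <- prod(d[c(1, 2, 4)])
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), m, d[3])
  if (train) {
    mu <- colMeans(xm)
    va <- colMeans(xm^2) - mu^2
  } else {
    mu <- lay$rmean
    va <- lay$rvar
  }
  invstd <- 1 / sqrt(va + .bnEps)
  xhat <- sweep(sweep(xm, 2, mu), 2, invstd, "*")
  ym <- sweep(sweep(xhat, 2, lay$gamma, "*"), 2, lay$beta, "+")
  y <- aperm(array(ym, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
  newStats <- if (train && exact) {
    list(rmean = mu, rvar = va)
  } else if (train) {
    mom <- 0.9
    list(rmean = mom * lay$rmean + (1 - mom) * mu,
         rvar = mom * lay$rvar + (1 - mom) * va)
  } else NULL
  list(out = y, cache = list(xhat = xhat, invstd = invstd, d = d, m = m),
       newStats = newStats)
}

.bnBackward <- function(lay, cache, dout) {
  d <- cache$d
  dym <- matrix(aperm(dout, c(1, 2, 4, 3)), cache$m, d[3])
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, lay$gamma, "*")
  t1 <- sweep(dxhat, 2, colMeans(dxhat))
  t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*")
  dxm <- sweep(t1 - t2, 2, cache$invstd, "*")
  dx <- aperm(array(dxm, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

.reluForward <- function(x) list(out = pmax(x, 0), cache = x > 0)
.reluBackward <- function(cache, dout) dout * cache

# elu(x) + 1: the strictly positive attention kernel feature map
.phi <- function(x) ifelse(x > 0, x + 1, exp(x))
.phiPrime <- function(x) ifelse(x > 0, 1, exp(x))

# row-wise layer normalization over the feature dimension
.lnForward <- function(lay, x) {
  dfeat <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc^2)
  invstd <- 1 / sqrt(va + .bnEps)
  xhat <- xc * invstd
  y <- sweep(sweep(xhat, 2, lay$gamma, "*"), 2, lay$beta, "+")
  list(out = y, cache = list(xhat = xhat, invstd = invstd, dfeat = dfeat))
}

.lnBackward <- function(lay, cache, dout) {
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2, lay$gamma, "*")
  t1 <- dxhat - rowMeans(dxhat)
  t2 <- cache$xhat * rowMeans(dxhat * cache$xhat)
  dx <- (t1 - t2) * cache$invstd
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

# one pre-norm linear-attention transformer layer on tokens X (T x d)
.attnForward <- function(lay, X) {
  ln <- .lnForward(lay$ln, X)
  Xn <- ln$out
  Q <- Xn %*% lay$Wq
  K <- Xn %*% lay$Wk
  V <- Xn %*% lay$Wv
  A <- .phi(Q)
  Bm <- .phi(K)
  S <- crossprod(Bm, V)        # d x d
  z <- colSums(Bm)             # d
  num <- A %*% S               # T x d
  den <- as.vector(A %*% z)    # T
  O <- num / den
  Y <- O %*% lay$Wo
  list(out = X + Y,
       cache = list(ln = ln, Xn = Xn, Q = Q, K = K, V = V, A = A, Bm = Bm,
                    S = S, z = z, num = num, den = den, O = O))
}

.attnBackward <- function(lay, cache, dout) {
  ch <- cache
  dY <- dout
  dWo <- crossprod(ch$O, dY)
  dO <- dY %*% t(lay$Wo)
  dnum <- dO / ch$den
  dden <- -rowSums(dO * ch$O) / ch$den
  dA <- dnum %*% t(ch$S) + outer(dden, ch$z)
  dS <- crossprod(ch$A, dnum)
  dz <- as.vector(crossprod(ch$A, dden))
  dBm <- ch$V %*% t(dS) + matrix(dz, nrow(ch$Bm), length(dz), byrow = TRUE)
  dV <- ch$Bm %*% dS
  dQ <- dA * .phiPrime(ch$Q)
  dK <- dBm * .phiPrime(ch$K)
  dWq <- crossprod(ch$Xn, dQ)
  dWk <- crossprod(ch$Xn, dK)
  dWv <- crossprod(ch$Xn, dV)
  dXn <- dQ %*% t(lay$Wq) + dK %*% t(lay$Wk) + dV %*% t(lay$Wv)
  lnb <- .lnBackward(lay$ln, ch$ln$cache, dXn)
  list(dx = dout + lnb$dx,
       grads = list(ln = lnb$grads, Wq = dWq, Wk = dWk, Wv = dWv, Wo = dWo))
}

# He-style initializers
.initConv <- function(kh, kw, cin, cout, stride, pad) {
  fanIn <- kh * kw * cin
  list(W = matrix(rnorm(cout * fanIn, sd = sqrt(2 / fanIn)), cout, fanIn),
       b = numeric(cout),
       kh = kh, kw = kw, cin = cin, cout = cout, stride = stride, pad = pad)
}

.initBn <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c),
       rmean = numeric(c), rvar = rep(1, c))
}

.initLinear <- function(din, dout) {
  list(W = matrix(rnorm(din * dout, sd = sqrt(2 / din)), din, dout),
       b = numeric(dout))
}

.initAttn <- function(d) {
  s <- sqrt(1 / d)
  list(ln = list(gamma = rep(1, d), beta = numeric(d)),
       Wq = matrix(rnorm(d * d, sd = s), d, d),
       Wk = matrix(rnorm(d * d, sd = s), d, d),
       Wv = matrix(rnorm(d * d, sd = s), d, d),
       Wo = matrix(rnorm(d * d, sd = s), d, d))
}

# recursive tree utilities over nested lists of numeric arrays;
# names in `skip` (batch-norm running stats) are ignored
.treeNames <- c("rmean", "rvar", "kh", "kw", "cin", "cout", "stride", "pad")

.treeZero <- function(p) {
  if (is.list(p)) {
    out <- lapply(p, .treeZero)
    out[names(p) %in% .treeNames] <- NULL
    return(out)
  }
  p * 0
}

.treeAdd <- function(a, b) {
  if (is.null(b)) return(a)
  if (is.list(a)) {
    for (nm in names(b)) a[[nm]] <- .treeAdd(a[[nm]], b[[nm]])
    return(a)
  }
  a + b
}

# Adam step; returns list(params, m, v)
.adamStep <- function(p, g, m, v, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  if (is.list(p)) {
    for (nm in names(p)) {
      if (nm %in% .treeNames) next
      if (is.null(g[[nm]])) next
      r <- .adamStep(p[[nm]], g[[nm]], m[[nm]], v[[nm]], lr, t, beta1, beta2,
                     eps)
      p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
    }
    return(list(p = p, m = m, v = v))
  }
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g^2
  mhat <- m / (1 - beta1^t)
  vhat <- v / (1 - beta2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}
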