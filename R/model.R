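#' Construct an MsiFormer architecture configuration
#'
#' Defaults give the published germination-prediction network: 256 x 256 x 22
#' input; stage 0 is a stem of two 3 x 3 stride-2 convolutions to 64
#' channels (overall stride 4); stages 1-4 are residual bottleneck stages of
#' widths 256, 512, 1024, 2048 with strides 1, 2, 2, 2; five linear-attention
#' transformer layers on the resulting 8 x 8 x 2048 map; a full-extent
#' convolution head to 1 x 1 x 2048; and a fully connected softmax classifier
#' over 2 classes.
#'
#' @param inChannels input channel count (22 = 19 bands + RGB; 3 for an
#'   RGB-only ablation).
#' @param inputSize square input side (must be divisible by the product of
#'   `stageStrides`).
#' @param stageChannels per-stage output widths (ascending).
#' @param stageStrides per-stage spatial strides (a stride of 4 realises the
#'   stem's two stride-2 convolutions).
#' @param attentionLayers number of linear-attention layers.
#' @param nClasses output classes.
#' @param blocksPerStage residual bottleneck blocks per stage.
#' @return a [MsiFormerConfig-class].
#' @export
msiFormerConfig <- function(inChannels = 22, inputSize = 256,
                            stageChannels = c(64, 256, 512, 1024, 2048),
                            stageStrides = c(4, 1, 2, 2, 2),
                            attentionLayers = 5, nClasses = 2,
                            blocksPerStage = 1) {
  new("MsiFormerConfig",
      inChannels = as.integer(inChannels), inputSize = as.integer(inputSize),
      stageChannels = as.integer(stageChannels),
      stageStrides = as.integer(stageStrides),
      attentionLayers = as.integer(attentionLayers),
      nClasses = as.integer(nClasses),
      featureDim = as.integer(tail(stageChannels, 1L)),
      blocksPerStage = as.integer(blocksPerStage))
}

#' Per-stage output shape trajectory
#'
#' Deterministic spatial/channel trajectory of a configuration: the input,
#' each convolutional stage, the (shape-preserving) attention block and the
#' full-extent convolution head. With defaults this reproduces the published
#' stage table: (64,64,64), (64,64,256), (32,32,512), (16,16,1024),
#' (8,8,2048), attention at (8,8,2048) and output (1,1,2048).
#'
#' @param config a [MsiFormerConfig-class].
#' @return data.frame with columns stage, h, w, c.
#' @export
stageShapes <- function(config) {
  validObject(config)
  s <- config@inputSize
  rows <- data.frame(stage = "input", h = s, w = s, c = config@inChannels)
  for (i in seq_along(config@stageChannels)) {
    if (s %% config@stageStrides[i] != 0)
      stop(sprintf("size %d not divisible by stride %d at stage %d",
                   s, config@stageStrides[i], i - 1L), call. = FALSE)
    s <- s %/% config@stageStrides[i]
    rows <- rbind(rows, data.frame(stage = sprintf("stage%d", i - 1L),
                                   h = s, w = s,
                                   c = config@stageChannels[i]))
  }
  rows <- rbind(rows,
                data.frame(stage = "attention", h = s, w = s,
                           c = config@featureDim),
                data.frame(stage = "output", h = 1L, w = 1L,
                           c = config@featureDim))
  rows
}

#' Linear (kernel) attention
#'
#' Attention with the positive kernel feature map `phi(x) = elu(x) + 1`
#' replacing the softmax: row i of the output is
#' `phi(q_i)^T (sum_j phi(k_j) v_j^T) / (phi(q_i)^T sum_j phi(k_j))`,
#' computed in the factored O(N d^2) form (associativity of the kernel
#' factorisation), never via the N x N similarity matrix. Because phi is
#' strictly positive the attention weights are a convex combination, so each
#' output coordinate lies within the range of the corresponding V column.
#'
#' @param Q,K numeric matrices N x d.
#' @param V numeric matrix N x dv.
#' @return numeric matrix N x dv.
#' @export
linearAttention <- function(Q, K, V) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (!all(is.finite(Q), is.finite(K), is.finite(V)))
    stop("non-finite attention input", call. = FALSE)
  if (nrow(Q) < 1L || ncol(Q) != ncol(K) || nrow(K) != nrow(V))
    stop("inconsistent Q/K/V shapes", call. = FALSE)
  A <- .phi(Q)
  B <- .phi(K)
  S <- crossprod(B, V)        # d x dv
  z <- colSums(B)             # d
  (A %*% S) / as.vector(A %*% z)
}

#' Binary cross-entropy loss
#'
#' Nonnegative mean cross-entropy `-mean(y log p + (1-y) log(1-p))` over
#' predicted positive-class probabilities, with probabilities clamped to
#' `[1e-12, 1 - 1e-12]`. Zero exactly when predictions match labels.
#'
#' @param p predicted positive-class probabilities in \[0, 1\].
#' @param y binary labels (0/1).
#' @return scalar loss.
#' @export
crossEntropy <- function(p, y) {
  if (length(p) != length(y))
    stop(sprintf("length mismatch: %d probabilities vs %d labels",
                 length(p), length(y)), call. = FALSE)
  if (any(p < 0 | p > 1)) stop("probabilities must be in [0, 1]",
                               call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("labels must be binary", call. = FALSE)
  eps <- 1e-12
  p <- clamp(p, eps, 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# layer plan derived from a config (static geometry)
.mfPlan <- function(config) {
  sh <- stageShapes(config)
  nStage <- length(config@stageChannels)
  stemStride <- config@stageStrides[1]
  stem <- if (stemStride == 4L) c(2L, 2L) else stemStride
  finalSide <- sh$h[nStage + 1L]
  list(stem = stem, nStage = nStage, shapes = sh,
       finalSide = finalSide, tokens = finalSide^2,
       d = config@featureDim,
       headIn = finalSide^2 * config@featureDim)
}

#' Initialise an MsiFormer model with random weights
#'
#' He-style Gaussian initialisation; deterministic for a fixed `rngSeed`.
#'
#' @param config a [MsiFormerConfig-class].
#' @param rngSeed integer seed for weight initialisation.
#' @return an untrained [MsiFormerModel-class].
#' @export
initMsiFormer <- function(config, rngSeed = 1L) {
  validObject(config)
  set.seed(as.integer(rngSeed))
  plan <- .mfPlan(config)
  ch <- config@stageChannels
  p <- list()
  # stem
  cin <- config@inChannels
  stem <- list()
  for (s in plan$stem) {
    stem[[length(stem) + 1L]] <- list(conv = .initConv(3L, 3L, cin, ch[1],
                                                       s, 1L),
                                      bn = .initBn(ch[1]))
    cin <- ch[1]
  }
  p$stem <- stem
  # residual bottleneck stages
  stages <- list()
  prev <- ch[1]
  for (i in seq_len(plan$nStage)[-1]) {
    blocks <- list()
    for (j in seq_len(config@blocksPerStage)) {
      stride <- if (j == 1L) config@stageStrides[i] else 1L
      cout <- ch[i]
      cmid <- max(1L, cout %/% 4L)
      blk <- list(
        c1 = .initConv(1L, 1L, prev, cmid, 1L, 0L), bn1 = .initBn(cmid),
        c2 = .initConv(3L, 3L, cmid, cmid, stride, 1L), bn2 = .initBn(cmid),
        c3 = .initConv(1L, 1L, cmid, cout, 1L, 0L), bn3 = .initBn(cout)
      )
      if (stride != 1L || prev != cout) {
        blk$proj <- .initConv(1L, 1L, prev, cout, stride, 0L)
        blk$bnp <- .initBn(cout)
      }
      blocks[[j]] <- blk
      prev <- cout
    }
    stages[[length(stages) + 1L]] <- blocks
  }
  p$stages <- stages
  p$attn <- lapply(seq_len(config@attentionLayers),
                   function(i) .initAttn(plan$d))
  p$head <- .initLinear(plan$headIn, config@featureDim)
  p$fc <- .initLinear(config@featureDim, config@nClasses)
  new("MsiFormerModel", config = config, params = p, trained = FALSE,
      trainingLog = data.frame(epoch = integer(0), loss = numeric(0)))
}

.blockForward <- function(blk, x, train, keepCache, exact = FALSE) {
  cv1 <- .convForward(blk$c1, x, keepCache)
  bn1 <- .bnForward(blk$bn1, cv1$out, train, exact)
  r1 <- .reluForward(bn1$out)
  cv2 <- .convForward(blk$c2, r1$out, keepCache)
  bn2 <- .bnForward(blk$bn2, cv2$out, train, exact)
  r2 <- .reluForward(bn2$out)
  cv3 <- .convForward(blk$c3, r2$out, keepCache)
  bn3 <- .bnForward(blk$bn3, cv3$out, train, exact)
  if (!is.null(blk$proj)) {
    cvp <- .convForward(blk$proj, x, keepCache)
    bnp <- .bnForward(blk$bnp, cvp$out, train, exact)
    sc <- bnp$out
  } else {
    cvp <- NULL; bnp <- NULL; sc <- x
  }
  pre <- bn3$out + sc
  r3 <- .reluForward(pre)
  list(out = r3$out,
       cache = list(cv1 = cv1, bn1 = bn1, r1 = r1, cv2 = cv2, bn2 = bn2,
                    r2 = r2, cv3 = cv3, bn3 = bn3, cvp = cvp, bnp = bnp,
                    r3 = r3, hasProj = !is.null(blk$proj)),
       newStats = list(bn1 = bn1$newStats, bn2 = bn2$newStats,
                       bn3 = bn3$newStats,
                       bnp = if (!is.null(bnp)) bnp$newStats else NULL))
}

.blockBackward <- function(blk, cache, dout) {
  g <- list()
  dpre <- .reluBackward(cache$r3$cache, dout)
  b3 <- .bnBackward(blk$bn3, cache$bn3$cache, dpre)
  g$bn3 <- b3$grads
  c3 <- .convBackward(blk$c3, cache$cv3$cache, b3$dx)
  g$c3 <- c3$grads
  dr2 <- .reluBackward(cache$r2$cache, c3$dx)
  b2 <- .bnBackward(blk$bn2, cache$bn2$cache, dr2)
  g$bn2 <- b2$grads
  c2 <- .convBackward(blk$c2, cache$cv2$cache, b2$dx)
  g$c2 <- c2$grads
  dr1 <- .reluBackward(cache$r1$cache, c2$dx)
  b1 <- .bnBackward(blk$bn1, cache$bn1$cache, dr1)
  g$bn1 <- b1$grads
  c1 <- .convBackward(blk$c1, cache$cv1$cache, b1$dx)
  g$c1 <- c1$grads
  dx <- c1$dx
  if (cache$hasProj) {
    bp <- .bnBackward(blk$bnp, cache$bnp$cache, dpre)
    g$bnp <- bp$grads
    cp <- .convBackward(blk$proj, cache$cvp$cache, bp$dx)
    g$proj <- cp$grads
    dx <- dx + cp$dx
  } else {
    dx <- dx + dpre
  }
  list(dx = dx, grads = g)
}

# full network forward; x is [H, W, C, N]
.mfForward <- function(params, config, x, train = FALSE, keepCache = FALSE,
                       bnExact = FALSE) {
  plan <- .mfPlan(config)
  N <- dim(x)[4]
  caches <- list(stem = list(), stages = list(), attn = NULL, head = NULL)
  # stem
  for (si in seq_along(params$stem)) {
    lay <- params$stem[[si]]
    cv <- .convForward(lay$conv, x, keepCache)
    bn <- .bnForward(lay$bn, cv$out, train, bnExact)
    rl <- .reluForward(bn$out)
    x <- rl$out
    caches$stem[[si]] <- list(cv = cv, bn = bn, rl = rl)
    if (train && !is.null(bn$newStats)) {
      params$stem[[si]]$bn$rmean <- bn$newStats$rmean
      params$stem[[si]]$bn$rvar <- bn$newStats$rvar
    }
  }
  # residual stages
  for (i in seq_along(params$stages)) {
    caches$stages[[i]] <- list()
    for (j in seq_along(params$stages[[i]])) {
      bf <- .blockForward(params$stages[[i]][[j]], x, train, keepCache,
                          bnExact)
      x <- bf$out
      caches$stages[[i]][[j]] <- bf$cache
      if (train) {
        for (nm in c("bn1", "bn2", "bn3", "bnp")) {
          ns <- bf$newStats[[nm]]
          if (!is.null(ns)) {
            params$stages[[i]][[j]][[nm]]$rmean <- ns$rmean
            params$stages[[i]][[j]][[nm]]$rvar <- ns$rvar
          }
        }
      }
    }
  }
  featureMap <- x   # [f, f, d, N]
  # attention on spatial tokens, per sample
  Tn <- plan$tokens; d <- plan$d
  attnCaches <- if (keepCache)
    lapply(seq_along(params$attn), function(i) vector("list", N)) else NULL
  tokensOut <- array(0, dim = c(Tn, d, N))
  for (n in seq_len(N)) {
    X <- matrix(x[, , , n], Tn, d)
    for (li in seq_along(params$attn)) {
      af <- .attnForward(params$attn[[li]], X)
      X <- af$out
      if (keepCache) attnCaches[[li]][[n]] <- af$cache
    }
    tokensOut[, , n] <- X
  }
  caches$attn <- attnCaches
  # head: full-extent convolution == linear map over the flattened map
  flat <- matrix(tokensOut, Tn * d, N)   # (tokens*d) x N
  h1 <- t(flat) %*% params$head$W        # N x featureDim
  h1 <- sweep(h1, 2, params$head$b, "+")
  rh <- .reluForward(h1)
  logits <- sweep(rh$out %*% params$fc$W, 2, params$fc$b, "+")
  # softmax rows
  mx <- apply(logits, 1, max)
  e <- exp(logits - mx)
  probs <- e / rowSums(e)
  caches$head <- list(flat = flat, rh = rh, h1 = h1)
  caches$tokensOut <- tokensOut
  caches$featureMapDim <- dim(featureMap)
  list(probs = probs, logits = logits, caches = caches, params = params,
       featureMap = featureMap)
}

# backward from dlogits (N x nClasses); returns gradient tree
.mfBackward <- function(params, config, caches, dlogits) {
  plan <- .mfPlan(config)
  N <- nrow(dlogits)
  g <- list()
  rh <- caches$head$rh
  g$fc <- list(W = crossprod(rh$out, dlogits), b = colSums(dlogits))
  dh1 <- .reluBackward(rh$cache, dlogits %*% t(params$fc$W))
  g$head <- list(W = caches$head$flat %*% dh1, b = colSums(dh1))
  dflat <- params$head$W %*% t(dh1)      # (tokens*d) x N
  Tn <- plan$tokens; d <- plan$d
  dTokens <- array(dflat, dim = c(Tn, d, N))
  g$attn <- lapply(params$attn, .treeZero)
  fmDim <- caches$featureMapDim
  dx <- array(0, dim = fmDim)
  for (n in seq_len(N)) {
    dX <- matrix(dTokens[, , n], Tn, d)
    for (li in rev(seq_along(params$attn))) {
      ab <- .attnBackward(params$attn[[li]], caches$attn[[li]][[n]], dX)
      dX <- ab$dx
      g$attn[[li]] <- .treeAdd(g$attn[[li]], ab$grads)
    }
    dx[, , , n] <- array(dX, dim = fmDim[1:3])
  }
  g$stages <- vector("list", length(params$stages))
  for (i in rev(seq_along(params$stages))) {
    g$stages[[i]] <- vector("list", length(params$stages[[i]]))
    for (j in rev(seq_along(params$stages[[i]]))) {
      bb <- .blockBackward(params$stages[[i]][[j]], caches$stages[[i]][[j]],
                           dx)
      dx <- bb$dx
      g$stages[[i]][[j]] <- bb$grads
    }
  }
  g$stem <- vector("list", length(params$stem))
  for (si in rev(seq_along(params$stem))) {
    ch <- caches$stem[[si]]
    drl <- .reluBackward(ch$rl$cache, dx)
    bb <- .bnBackward(params$stem[[si]]$bn, ch$bn$cache, drl)
    cb <- .convBackward(params$stem[[si]]$conv, ch$cv$cache, bb$dx)
    g$stem[[si]] <- list(conv = cb$grads, bn = bb$grads)
    dx <- cb$dx
  }
  g
}

#' Forward pass of an MsiFormer model
#'
#' Runs the full pipeline (convolutional stages, linear-attention layers,
#' full-extent convolution head, fully connected layer, softmax) in
#' evaluation mode (batch-norm running statistics; deterministic).
#'
#' @param model an [MsiFormerModel-class].
#' @param x numeric array N x S x S x C (batch first) or S x S x C for a
#'   single crop.
#' @return matrix N x nClasses of class probabilities (rows sum to 1);
#'   column order is (non-germinated, germinated).
#' @export
msiFormerForward <- function(model, x) {
  stopifnot(is(model, "MsiFormerModel"))
  cfg <- model@config
  if (length(dim(x)) == 3L) x <- array(x, dim = c(1L, dim(x)))
  d <- dim(x)
  if (d[2] != cfg@inputSize || d[3] != cfg@inputSize ||
      d[4] != cfg@inChannels)
    stop(sprintf("input is %d x %d x %d but config expects %d x %d x %d",
                 d[2], d[3], d[4], cfg@inputSize, cfg@inputSize,
                 cfg@inChannels), call. = FALSE)
  xb <- aperm(x, c(2, 3, 4, 1))
  fw <- .mfForward(model@params, cfg, xb, train = FALSE, keepCache = FALSE)
  if (cfg@nClasses == 2L)
    colnames(fw$probs) <- c("non_germinated", "germinated")
  fw$probs
}
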