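test_that("default architecture reproduces the published shape trajectory", {
  sh <- stageShapes(msiFormerConfig())
  expect_equal(sh[sh$stage == "input", c("h", "w", "c")],
               data.frame(h = 256, w = 256, c = 22),
               ignore_attr = TRUE)
  stages <- sh[grepl("^stage", sh$stage), ]
  expect_equal(stages$h, c(64, 64, 32, 16, 8))
  expect_equal(stages$c, c(64, 256, 512, 1024, 2048))
  expect_equal(sh[sh$stage == "attention", c("h", "w", "c")],
               data.frame(h = 8, w = 8, c = 2048), ignore_attr = TRUE)
  expect_equal(sh[sh$stage == "output", c("h", "w", "c")],
               data.frame(h = 1, w = 1, c = 2048), ignore_attr = TRUE)
  expect_error(stageShapes(msiFormerConfig(inputSize = 250)), "divisible")
})

test_that("linear attention matches its definition and the naive oracle", {
  # single token: output equals v exactly
  v <- matrix(c(2, -1, 3), 1)
  expect_equal(linearAttention(matrix(rnorm(3), 1), matrix(rnorm(3), 1), v),
               v)
  # constant value rows pass through (weights normalize to 1)
  Q <- matrix(rnorm(40), 8); K <- matrix(rnorm(40), 8)
  Vc <- matrix(rep(c(1, 2, 3, 4, 5), each = 8), 8)
  expect_equal(linearAttention(Q, K, Vc), Vc)
  # factored form equals the naive O(N^2) oracle
  set.seed(101)
  for (i in 1:25) {
    N <- sample(1:64, 1); d <- sample(1:32, 1)
    Q <- matrix(rnorm(N * d), N); K <- matrix(rnorm(N * d), N)
    V <- matrix(rnorm(N * d), N)
    expect_lt(max(abs(linearAttention(Q, K, V) -
                        naiveLinearAttention(Q, K, V))), 1e-6)
  }
  # convexity: outputs lie within the column ranges of V
  out <- linearAttention(Q, K, V)
  expect_true(all(sweep(out, 2, apply(V, 2, max)) <= 1e-12))
  expect_true(all(sweep(out, 2, apply(V, 2, min)) >= -1e-12))
  expect_error(linearAttention(matrix(NaN, 1, 1), matrix(1), matrix(1)),
               "non-finite")
})

test_that("cross-entropy matches hand-computed values", {
  expect_equal(crossEntropy(1.0, 1), 0)
  expect_equal(crossEntropy(0.5, 1), log(2))
  expect_equal(crossEntropy(c(0.9, 0.2), c(1, 0)),
               mean(c(-log(0.9), -log(0.8))))
  expect_error(crossEntropy(c(0.5, 0.5), 1), "length mismatch")
  expect_error(crossEntropy(1.5, 1), "\\[0, 1\\]")
  # clamping keeps the loss finite at certainty errors
  expect_true(is.finite(crossEntropy(0, 1)))
})

test_that("forward pass produces valid, deterministic probabilities", {
  cfg <- tinyConfig(inputSize = 32)
  m <- initMsiFormer(cfg, rngSeed = 7)
  x <- array(runif(3 * 32 * 32 * 22), dim = c(3, 32, 32, 22))
  p <- msiFormerForward(m, x)
  expect_identical(dim(p), c(3L, 2L))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  expect_true(all(p >= 0))
  # duplicated inputs give identical outputs (eval mode is deterministic)
  xd <- x[c(1, 1, 2), , , ]
  pd <- msiFormerForward(m, xd)
  expect_equal(pd[1, ], pd[2, ])
  # the feature map entering the head matches the stage trajectory
  sh <- stageShapes(cfg)
  fin <- sh[sh$stage == "attention", ]
  fw <- msivigor:::.mfForward(m@params, cfg, aperm(x, c(2, 3, 4, 1)))
  expect_identical(dim(fw$featureMap)[1:3],
                   c(fin$h, fin$w, fin$c))
  expect_error(msiFormerForward(m, array(0, dim = c(1, 16, 16, 22))),
               "config expects")
})

test_that("an RGB-only ablation configuration runs", {
  cfg <- tinyConfig(inChannels = 3, inputSize = 32)
  m <- initMsiFormer(cfg, rngSeed = 1)
  p <- msiFormerForward(m, array(runif(32 * 32 * 3), dim = c(32, 32, 3)))
  expect_equal(sum(p), 1, tolerance = 1e-6)
})

test_that("analytic gradients agree with finite differences", {
  cfg <- msiFormerConfig(inChannels = 2, inputSize = 16,
                         stageChannels = c(4, 8), stageStrides = c(2, 2),
                         attentionLayers = 1)
  m <- initMsiFormer(cfg, rngSeed = 3)
  set.seed(5)
  xb <- array(runif(16 * 16 * 2 * 2), dim = c(16, 16, 2, 2))
  y <- c(1L, 0L)
  lossOf <- function(params) {
    fw <- msivigor:::.mfForward(params, cfg, xb, train = TRUE)
    crossEntropy(fw$probs[, 2], y)
  }
  fw <- msivigor:::.mfForward(m@params, cfg, xb, train = TRUE,
                              keepCache = TRUE)
  onehot <- matrix(0, 2, 2); onehot[cbind(1:2, y + 1L)] <- 1
  g <- msivigor:::.mfBackward(m@params, cfg, fw$caches,
                              (fw$probs - onehot) / 2)
  paths <- list(list("fc", "W"), list("head", "W"),
                list("attn", 1L, "Wq"), list("attn", 1L, "ln", "gamma"),
                list("stages", 1L, 1L, "c2", "W"),
                list("stages", 1L, 1L, "bn3", "beta"),
                list("stem", 1L, "conv", "W"))
  perturb <- function(plist, path, i, delta) {
    if (length(path) == 1L) {
      plist[[path[[1]]]][i] <- plist[[path[[1]]]][i] + delta
      return(plist)
    }
    plist[[path[[1]]]] <- perturb(plist[[path[[1]]]], path[-1], i, delta)
    plist
  }
  eps <- 1e-5
  for (path in paths) {
    ga <- g; for (k in path) ga <- ga[[k]]
    set.seed(11)
    for (i in sample(length(ga), 3)) {
      fd <- (lossOf(perturb(m@params, path, i, eps)) -
               lossOf(perturb(m@params, path, i, -eps))) / (2 * eps)
      expect_equal(ga[i], fd, tolerance = 1e-4)
    }
  }
})

test_that("checkpoints round-trip through JSON", {
  cfg <- msiFormerConfig(inChannels = 2, inputSize = 16,
                         stageChannels = c(4, 8), stageStrides = c(2, 2),
                         attentionLayers = 1)
  m <- initMsiFormer(cfg, rngSeed = 9)
  f <- withr::local_tempfile(fileext = ".json")
  saveMsiFormer(m, f)
  m2 <- loadMsiFormer(f)
  x <- array(runif(16 * 16 * 2), dim = c(16, 16, 2))
  expect_equal(msiFormerForward(m2, x), msiFormerForward(m, x),
               tolerance = 1e-12)
})
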