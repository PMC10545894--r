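# Shared fixtures, built in code at test time.

# small dish scene: 10 seeds on a 256 px frame (axes scale with frame)
smallScene <- function(rngSeed = 1, nSeeds = 10, imageSize = 256, ...) {
  generateScene(sceneSpec(nSeeds = nSeeds, imageSize = imageSize,
                          rngSeed = rngSeed, ...))
}

# reduced classifier configuration used throughout the tests
tinyConfig <- function(inChannels = 22, inputSize = 64,
                       stageChannels = c(4, 8, 16, 32, 64),
                       attentionLayers = 1, ...) {
  msiFormerConfig(inChannels = inChannels, inputSize = inputSize,
                  stageChannels = stageChannels,
                  stageStrides = c(4, 1, 2, 2, 2),
                  attentionLayers = attentionLayers, ...)
}

# published evaluation table: confusion counts and displayed metric cells
# for the four compared classifiers
publishedEvaluation <- function() {
  data.frame(
    method = c("ResNet50", "DenseNet121", "EfficientNetb4", "MsiFormer"),
    tp = c(52, 56, 59, 59), tn = c(55, 54, 32, 54),
    fp = c(5, 6, 28, 6), fn = c(8, 4, 1, 1),
    acc = c(89.17, 91.67, 75.83, 94.17),
    precision = c(91.23, 90.32, 67.82, 90.77),
    tpr = c(86.67, 93.33, 98.33, 98.33),
    fpr = c(8.33, 10.00, 46.67, 10.00),
    tnr = c(91.67, 90.00, 53.33, 90.00),
    fnr = c(13.33, 6.67, 1.67, 1.67))
}

# naive O(N^2) attention oracle: explicit similarity matrix, row-normalized
naiveLinearAttention <- function(Q, K, V) {
  phi <- function(x) ifelse(x > 0, x + 1, exp(x))
  W <- phi(Q) %*% t(phi(K))
  (W / rowSums(W)) %*% V
}

# rasterize a filled ellipse mask
ellipseMask <- function(H, W, cy, cx, a, b, theta = 0) {
  dy <- outer(seq_len(H) - cy, rep(1, W))
  dx <- outer(rep(1, H), seq_len(W) - cx)
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  u * u + v * v <= 1
}

expect_boxes_sorted <- function(boxes) {
  expect_false(is.unsorted(order(boxes$y_min, boxes$x_min)))
}
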