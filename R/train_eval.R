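#' Construct confusion counts
#'
#' @param tp,tn,fp,fn nonnegative integer counts.
#' @return a [ConfusionCounts-class].
#' @export
confusionCounts <- function(tp, tn, fp, fn) {
  new("ConfusionCounts", tp = as.integer(tp), tn = as.integer(tn),
      fp = as.integer(fp), fn = as.integer(fn))
}

#' Confusion-derived evaluation metrics, in percent
#'
#' Computes accuracy (TP+TN)/(TP+TN+FP+FN), precision TP/(TP+FP), true
#' positive rate TP/(TP+FN), false positive rate FP/(FP+TN), true negative
#' rate TN/(TN+FP) and false negative rate FN/(FN+TP), each as a percentage.
#' A metric whose denominator is zero is reported as NA. Full precision is
#' retained; display rounds half-up to 2 decimals.
#'
#' @param counts a [ConfusionCounts-class] (or four counts tp, tn, fp, fn).
#' @return a [MetricsReport-class].
#' @export
metricsFromCounts <- function(counts) {
  if (!is(counts, "ConfusionCounts")) {
    v <- unlist(counts)
    counts <- confusionCounts(v[1], v[2], v[3], v[4])
  }
  validObject(counts)
  tp <- counts@tp; tn <- counts@tn; fp <- counts@fp; fn <- counts@fn
  rate <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  new("MetricsReport",
      acc = rate(tp + tn, tp + tn + fp + fn),
      precision = rate(tp, tp + fp),
      tpr = rate(tp, tp + fn),
      fpr = rate(fp, fp + tn),
      tnr = rate(tn, tn + fp),
      fnr = rate(fn, fn + tp))
}

#' Confusion counts from scores and labels at a threshold
#'
#' A sample is predicted positive iff its score is at or above `threshold`.
#'
#' @param scores numeric score vector.
#' @param labels binary labels (1 = positive/germinated).
#' @param threshold decision threshold (default 0.5).
#' @return a [ConfusionCounts-class].
#' @export
confusionFromPredictions <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels))
    stop(sprintf("length mismatch: %d scores vs %d labels",
                 length(scores), length(labels)), call. = FALSE)
  pred <- scores >= threshold
  pos <- labels == 1
  confusionCounts(tp = sum(pred & pos), tn = sum(!pred & !pos),
                  fp = sum(pred & !pos), fn = sum(!pred & pos))
}

#' ROC curve and trapezoid AUC
#'
#' Sweeps the decision threshold over all distinct scores (plus +Inf), and
#' integrates TPR over FPR by the trapezoid rule. Tied scores are grouped,
#' so the AUC equals the pairwise concordance probability
#' P(score+ > score-) + 0.5 P(score+ = score-), and is invariant under any
#' strictly increasing transformation of the scores.
#'
#' @param scores numeric score vector (higher = more positive).
#' @param labels binary labels; both classes must be present.
#' @return a [RocCurve-class].
#' @export
rocAuc <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length", call. = FALSE)
  P <- sum(labels == 1)
  Nn <- sum(labels == 0)
  if (P == 0 || Nn == 0)
    stop("both classes must be present to compute a ROC curve",
         call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tpCum <- cumsum(y == 1)
  fpCum <- cumsum(y == 0)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tpr <- c(0, tpCum[last] / P)
  fpr <- c(0, fpCum[last] / Nn)
  thr <- c(Inf, s[last])
  aucVal <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  new("RocCurve", thresholds = thr, tpr = tpr, fpr = fpr, auc = aucVal)
}

#' Train an MsiFormer germination classifier
#'
#' Mini-batch training with softmax cross-entropy loss and the Adam
#' optimizer (the optimizer and schedule are configurable implementation
#' choices). Deterministic for a fixed `rngSeed` under single-threaded
#' numerics. After the final epoch the model is evaluated on the test half:
#' a [ConfusionCounts-class]/[MetricsReport-class] at threshold 0.5 on the
#' positive-class (germinated) probability, and a [RocCurve-class] when both
#' classes are present.
#'
#' @param split a [DatasetSplit-class].
#' @param stacks named list of [SpectralStack-class] keyed by dish_id.
#' @param config an [MsiFormerConfig-class].
#' @param epochs training epochs (0 = evaluate the untrained model).
#' @param lr Adam learning rate.
#' @param batchSize mini-batch size.
#' @param rngSeed integer seed for initialisation, shuffling and batching.
#' @param augmentTrain expand training crops with the 8 dihedral variants.
#' @return list with `model` (trained [MsiFormerModel-class]), `log`
#'   (per-epoch loss data.frame), `confusion`, `metrics`, `roc`,
#'   `testScores` and `testLabels`.
#' @export
trainMsiFormer <- function(split, stacks, config, epochs = 10, lr = 1e-3,
                           batchSize = 16, rngSeed = 1L,
                           augmentTrain = FALSE) {
  stopifnot(is(split, "DatasetSplit"), is(config, "MsiFormerConfig"))
  if (nrow(split@train) == 0L || nrow(split@test) == 0L)
    stop("split must have nonempty train and test halves", call. = FALSE)
  data <- materializeCrops(split, stacks, outSize = config@inputSize,
                           augmentTrain = augmentTrain)
  model <- initMsiFormer(config, rngSeed = rngSeed)
  params <- model@params
  mState <- .treeZero(params)
  vState <- .treeZero(params)
  nTrain <- length(data$train$y)
  log <- data.frame(epoch = integer(0), loss = numeric(0))
  set.seed(as.integer(rngSeed) + 1L)
  step <- 0L
  for (ep in seq_len(epochs)) {
    idx <- sample.int(nTrain)
    losses <- numeric(0)
    for (start in seq(1L, nTrain, by = batchSize)) {
      bi <- idx[start:min(start + batchSize - 1L, nTrain)]
      xb <- data$train$x[, , , bi, drop = FALSE]
      yb <- data$train$y[bi]
      fw <- .mfForward(params, config, xb, train = TRUE, keepCache = TRUE)
      params <- fw$params              # batch-norm running stats updated
      pPos <- fw$probs[, 2L]
      loss <- crossEntropy(pPos, yb)
      if (!is.finite(loss))
        stop(sprintf("training diverged (non-finite loss at epoch %d)", ep),
             call. = FALSE)
      losses <- c(losses, loss)
      onehot <- matrix(0, length(bi), config@nClasses)
      onehot[cbind(seq_along(bi), yb + 1L)] <- 1
      dlogits <- (fw$probs - onehot) / length(bi)
      grads <- .mfBackward(params, config, fw$caches, dlogits)
      step <- step + 1L
      upd <- .adamStep(params, grads, mState, vState, lr, step)
      params <- upd$p; mState <- upd$m; vState <- upd$v
    }
    log <- rbind(log, data.frame(epoch = ep, loss = mean(losses)))
  }
  if (epochs > 0) {
    # re-estimate batch-norm statistics exactly on one unaugmented crop per
    # training seed, so evaluation-mode normalisation matches training
    calIdx <- which(!duplicated(data$train$seed_id))
    fw <- .mfForward(params, config,
                     data$train$x[, , , calIdx, drop = FALSE],
                     train = TRUE, keepCache = FALSE, bnExact = TRUE)
    params <- fw$params
  }
  model@params <- params
  model@trained <- epochs > 0
  model@trainingLog <- log
  probs <- msiFormerForward(
    model, aperm(data$test$x, c(4, 1, 2, 3)))
  scores <- probs[, 2L]
  conf <- confusionFromPredictions(scores, data$test$y, 0.5)
  roc <- if (length(unique(data$test$y)) == 2L)
    rocAuc(scores, data$test$y) else NULL
  list(model = model, log = log, confusion = conf,
       metrics = metricsFromCounts(conf), roc = roc,
       testScores = scores, testLabels = data$test$y)
}

#' Save / load an MsiFormer checkpoint
#'
#' The checkpoint is a JSON file holding the architecture configuration and
#' all weight arrays (including batch-norm running statistics), portable
#' across platforms.
#'
#' @param model an [MsiFormerModel-class].
#' @param path checkpoint file path.
#' @return `saveMsiFormer`: invisibly, `path`; `loadMsiFormer`: the model.
#' @export
saveMsiFormer <- function(model, path) {
  ser <- function(p) {
    if (is.list(p)) return(lapply(p, ser))
    if (is.matrix(p)) return(list(.dim = dim(p), .data = as.vector(p)))
    p
  }
  cfg <- model@config
  obj <- list(
    config = list(inChannels = cfg@inChannels, inputSize = cfg@inputSize,
                  stageChannels = cfg@stageChannels,
                  stageStrides = cfg@stageStrides,
                  attentionLayers = cfg@attentionLayers,
                  nClasses = cfg@nClasses,
                  blocksPerStage = cfg@blocksPerStage),
    trained = model@trained,
    params = ser(model@params))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname saveMsiFormer
#' @export
loadMsiFormer <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  deser <- function(p) {
    if (!is.list(p)) return(p)
    if (!is.null(names(p)) && !is.null(p[[".dim"]])) {
      d <- unlist(p[[".dim"]])
      return(matrix(unlist(p[[".data"]]), d[1], d[2]))
    }
    if (is.null(names(p)) &&
        all(vapply(p, function(e) !is.list(e) && length(e) == 1L,
                   logical(1))))
      return(unlist(p))
    lapply(p, deser)
  }
  cfgL <- obj$config
  cfg <- msiFormerConfig(
    inChannels = cfgL$inChannels, inputSize = cfgL$inputSize,
    stageChannels = cfgL$stageChannels, stageStrides = cfgL$stageStrides,
    attentionLayers = cfgL$attentionLayers, nClasses = cfgL$nClasses,
    blocksPerStage = cfgL$blocksPerStage)
  new("MsiFormerModel", config = cfg, params = deser(obj$params),
      trained = isTRUE(as.logical(obj$trained)),
      trainingLog = data.frame(epoch = integer(0), loss = numeric(0)))
}
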