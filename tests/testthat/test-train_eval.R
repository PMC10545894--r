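test_that("every metric cell of the published comparison is reproduced", {
  tab <- publishedEvaluation()
  for (i in seq_len(nrow(tab))) {
    rep <- metricsFromCounts(confusionCounts(tab$tp[i], tab$tn[i],
                                             tab$fp[i], tab$fn[i]))
    got <- roundHalfUp(metricsVector(rep), 2)
    expect_equal(unname(got),
                 unlist(tab[i, c("acc", "precision", "tpr", "fpr", "tnr",
                                 "fnr")], use.names = FALSE),
                 info = tab$method[i])
  }
})

test_that("metric identities hold and zero denominators give NA", {
  set.seed(23)
  for (i in 1:20) {
    v <- sample(0:40, 4, replace = TRUE)
    if (sum(v) == 0) v[1] <- 1
    rep <- metricsVector(metricsFromCounts(confusionCounts(v[1], v[2],
                                                           v[3], v[4])))
    P <- v[1] + v[4]; N <- v[2] + v[3]
    if (P > 0) expect_equal(rep["tpr"] + rep["fnr"], c(tpr = 100))
    if (N > 0) expect_equal(rep["tnr"] + rep["fpr"], c(tnr = 100))
    if (P > 0 && N > 0)
      expect_equal(rep["acc"],
                   c(acc = (rep[["tpr"]] * P + rep[["tnr"]] * N) / (P + N)))
  }
  rep <- metricsVector(metricsFromCounts(confusionCounts(3, 0, 0, 2)))
  expect_true(is.na(rep["fpr"]))   # no negatives
  expect_equal(rep[["acc"]], 60)
  # perfect prediction
  perf <- metricsVector(metricsFromCounts(confusionCounts(5, 5, 0, 0)))
  expect_equal(perf[["acc"]], 100)
  expect_equal(perf[["fpr"]], 0)
  expect_error(metricsFromCounts(confusionCounts(0, 0, 0, 0)), "at least")
})

test_that("thresholded confusion counts match per-item enumeration", {
  expect_equal(
    confusionVector(confusionFromPredictions(c(1, 0, 1, 0), c(1, 0, 1, 0))),
    c(tp = 2, tn = 2, fp = 0, fn = 0))
  expect_equal(
    confusionVector(confusionFromPredictions(rep(0, 5), rep(1, 5))),
    c(tp = 0, tn = 0, fp = 0, fn = 5))
  set.seed(31)
  scores <- runif(50); labels <- rbinom(50, 1, 0.5); thr <- 0.4
  got <- confusionVector(confusionFromPredictions(scores, labels, thr))
  want <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  for (i in 1:50) {
    pos <- scores[i] >= thr
    key <- if (pos && labels[i] == 1) "tp" else if (pos) "fp"
      else if (labels[i] == 1) "fn" else "tn"
    want[key] <- want[key] + 1
  }
  expect_equal(got, want)
  expect_error(confusionFromPredictions(1:3, 1:2), "length mismatch")
})

test_that("ROC/AUC matches the pairwise-concordance oracle", {
  concordance <- function(scores, labels) {
    sp <- scores[labels == 1]; sn <- scores[labels == 0]
    tot <- 0
    for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(sp) * length(sn))
  }
  # perfectly separated
  expect_equal(auc(rocAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))), 1)
  # all-tied scores
  expect_equal(auc(rocAuc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))), 0.5)
  # random scores vs O(n^2) oracle, exact to 1e-12
  set.seed(47)
  scores <- round(runif(50), 2)   # force ties
  labels <- rbinom(50, 1, 0.5)
  r <- rocAuc(scores, labels)
  expect_equal(auc(r), concordance(scores, labels), tolerance = 1e-12)
  # curve endpoints and monotonicity
  expect_equal(r@fpr[1], 0); expect_equal(r@tpr[1], 0)
  expect_equal(tail(r@fpr, 1), 1); expect_equal(tail(r@tpr, 1), 1)
  expect_false(is.unsorted(r@fpr))
  # invariant under strictly monotone score transformation
  sq <- pmin(pmax(scores, 0.01), 0.99)
  expect_equal(auc(rocAuc(qlogis(sq), labels)), auc(rocAuc(sq, labels)))
  expect_error(rocAuc(runif(5), rep(1, 5)), "both classes")
})

test_that("training reduces the loss and evaluates on held-out seeds", {
  sc <- lapply(1:2, function(i)
    generateScene(sceneSpec(nSeeds = 10, imageSize = 256, nirShift = 0.15,
                            rngSeed = 700 + i)))
  stacks <- list()
  for (s in sc) stacks[[dishId(s$stack)]] <- s$stack
  recs <- do.call(rbind, lapply(sc, function(s)
    seedRecordsFromScene(s$stack, s$truth, "V1")))
  split <- buildSplit(recs, trainSeeds = 14, testSeeds = 6, rngSeed = 3)
  cfg <- tinyConfig()
  res <- trainMsiFormer(split, stacks, cfg, epochs = 3, lr = 3e-3,
                        batchSize = 8, rngSeed = 4)
  expect_true(res$model@trained)
  expect_identical(nrow(res$log), 3L)
  expect_true(all(is.finite(res$log$loss)))
  # optimization sanity: later epochs no worse than the first
  expect_lte(res$log$loss[3], res$log$loss[1])
  expect_length(res$testScores, 6L)
  expect_true(all(res$testScores >= 0 & res$testScores <= 1))
  expect_s4_class(res$metrics, "MetricsReport")
  # epochs = 0: untrained model still evaluates end to end
  res0 <- trainMsiFormer(split, stacks, cfg, epochs = 0, rngSeed = 4)
  expect_false(res0$model@trained)
  expect_identical(nrow(res0$log), 0L)
  expect_true(all(res0$testScores >= 0 & res0$testScores <= 1))
})
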