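makePixels <- function(n, mean, sd = 0.01) {
  sweep(matrix(rnorm(n * length(mean), sd = sd), n), 2, mean, "+")
}

test_that("the discriminant axis concentrates on the separating band", {
  set.seed(91)
  B <- 19
  base <- rep(0.4, B)
  shifted <- base; shifted[17] <- 0.55   # classes differ only in band 17
  X <- rbind(makePixels(200, base), makePixels(200, shifted))
  y <- rep(c(0, 1), each = 200)
  m <- fitNcda(X, y)
  w <- abs(m@weights)
  expect_gte(w[17], 5 * max(w[-17]))
  # Fisher property: class-mean projections straddle their midpoint
  p0 <- sum(m@classMeans[1, ] * m@weights) - m@intercept
  p1 <- sum(m@classMeans[2, ] * m@weights) - m@intercept
  expect_lt(p0 * p1, 0)
  expect_gt(p1, 0)   # higher label oriented positive
})

test_that("identical class means leave no between-class signal", {
  # with no population separation the maximized sample between/within
  # ratio is O(B/n); a true signal (cf. the band-17 fixture) gives >> 1
  set.seed(92)
  n <- 2000
  X <- makePixels(2 * n, rep(0.4, 6), sd = 0.02)
  y <- rep(c(0, 1), each = n)
  m <- fitNcda(X, y)
  s <- as.vector(X %*% m@weights)
  sb <- (mean(s[y == 1]) - mean(s[y == 0]))^2
  sw <- var(s[y == 1]) + var(s[y == 0])
  expect_lt(sb / sw, 10 * 6 / n)
})

test_that("scores normalize training extremes to exactly +/-1", {
  set.seed(93)
  X <- rbind(makePixels(150, rep(0.3, 4)), makePixels(150, rep(0.5, 4)))
  y <- rep(c(0, 1), each = 150)
  m <- fitNcda(X, y)
  s <- as.vector(X %*% m@weights) - m@intercept
  norm <- 2 * (s - m@scoreRange[1]) / diff(m@scoreRange) - 1
  expect_equal(min(norm), -1)
  expect_equal(max(norm), 1)
  expect_error(fitNcda(X, rep(1, 300)), "2 classes")
})

test_that("graded ageing groups order monotonically in nCDA score", {
  # four ageing groups with increasing NIR reflectance
  set.seed(94)
  wl <- canonicalWavelengths()
  nir <- wl >= 780
  base <- 0.3 + 0.2 * seq(0, 1, length.out = 19)
  groups <- lapply(0:3, function(g) {
    mu <- base; mu[nir] <- mu[nir] + 0.04 * g
    makePixels(150, mu)
  })
  X <- do.call(rbind, groups)
  y <- rep(0:3, each = 150)
  m <- fitNcda(X, y)
  s <- as.vector(X %*% m@weights) - m@intercept
  gm <- tapply(s, y, mean)
  expect_true(all(diff(gm) > 0))
  # transform a scene built from the same spectra
  sc <- generateScene(sceneSpec(nSeeds = 6, imageSize = 128, nirShift = 0.12,
                                rngSeed = 7))
  tr <- transformNcda(m, sc$stack)
  expect_identical(dim(tr$score), c(128L, 128L))
  expect_true(all(tr$score >= -1 & tr$score <= 1))
  expect_identical(dim(tr$pseudocolor), c(128L, 128L, 3L))
  # constant image projects to a constant score
  const <- spectralStack(array(0.4, dim = c(8, 8, 19)), wl)
  expect_equal(var(as.vector(transformNcda(m, const)$score)), 0)
  bad <- spectralStack(array(0.4, dim = c(8, 8, 2)), c(450, 850))
  expect_error(transformNcda(m, bad), "bands")
})

test_that("nCDA scores are invariant to invertible band recombination", {
  set.seed(95)
  X <- rbind(makePixels(100, c(0.3, 0.4, 0.5)),
             makePixels(100, c(0.35, 0.42, 0.55)))
  y <- rep(c(0, 1), each = 100)
  A <- matrix(c(1, 0.2, 0, 0.1, 1, 0.3, 0, 0, 1), 3, 3)
  m1 <- fitNcda(X, y)
  m2 <- fitNcda(X %*% A, y)
  s1 <- as.vector(X %*% m1@weights) - m1@intercept
  s2 <- as.vector((X %*% A) %*% m2@weights) - m2@intercept
  n1 <- 2 * (s1 - m1@scoreRange[1]) / diff(m1@scoreRange) - 1
  n2 <- 2 * (s2 - m2@scoreRange[1]) / diff(m2@scoreRange) - 1
  expect_lt(max(abs(n1 - n2)), 1e-4)
})

test_that("fitted axis agrees in direction with the reference LDA", {
  skip_if_not_installed("MASS")
  set.seed(96)
  X <- rbind(makePixels(200, c(0.3, 0.45, 0.5, 0.38)),
             makePixels(200, c(0.34, 0.4, 0.56, 0.4)))
  y <- rep(c(0, 1), each = 200)
  m <- fitNcda(X, y)
  ref <- MASS::lda(X, grouping = y)$scaling[, 1]
  cosang <- abs(sum(m@weights * ref)) /
    sqrt(sum(m@weights^2) * sum(ref^2))
  expect_gt(cosang, 0.999)
})

test_that("band-vigour correlations isolate the coupled bands", {
  set.seed(97)
  # vigour equals the negated band: perfect anticorrelation there
  X <- matrix(runif(60), 20, 3)
  expect_equal(bandCorrelations(X, -X[, 2])[2], -1, ignore_attr = TRUE)
  # independent noise bands: |r| below the null-distribution envelope
  n <- 400
  Xn <- matrix(rnorm(n * 10), n)
  r <- bandCorrelations(Xn, rnorm(n))
  expect_true(mean(abs(r) < 4 / sqrt(n)) >= 0.9)
  # vigour coupled only to NIR bands
  wl <- canonicalWavelengths()
  nir <- wl >= 780
  vig <- runif(80, 0, 1)
  Xs <- sapply(seq_along(wl), function(b) {
    base <- 0.4 + rnorm(80, sd = 0.02)
    if (nir[b]) base - 0.1 * vig else base
  })
  r2 <- bandCorrelations(Xs, vig)
  expect_gt(min(abs(r2[nir])), max(abs(r2[!nir])))
  expect_true(all(r2[nir] < 0))
  # constant band reports NA
  Xc <- cbind(rep(0.5, 20), runif(20))
  expect_true(is.na(bandCorrelations(Xc, runif(20))[1]))
})
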