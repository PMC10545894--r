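germTable <- function(germ, day = NULL, shoot = NULL) {
  n <- length(germ)
  data.frame(seed_id = sprintf("s%02d", seq_len(n)),
             germinated = as.integer(germ),
             day_of_germination = if (is.null(day)) rep(NA_integer_, n)
               else day,
             shoot_length_cm = if (is.null(shoot)) rep(NA_real_, n)
               else shoot)
}

test_that("germination rate is the germinated percentage", {
  t <- germTable(c(rep(1, 6), rep(0, 4)), day = c(rep(1L, 6), rep(NA, 4)),
                 shoot = c(rep(2, 6), rep(NA, 4)))
  expect_equal(germinationRate(t), 60)
  expect_equal(germinationRate(germTable(rep(0, 5))), 0)
  t1 <- germTable(rep(1, 5), day = rep(2L, 5), shoot = rep(1, 5))
  expect_equal(germinationRate(t1), 100)
  expect_error(germinationRate(germTable(integer(0))), "empty")
})

test_that("vigor index weights germination speed and shoot length", {
  # nothing germinated
  expect_equal(vigorIndex(germTable(rep(0, 4))), 0)
  # one seed, day 1, shoot 2 cm: GI = 1, VI = 2
  expect_equal(vigorIndex(germTable(1, day = 1L, shoot = 2)), 2)
  # mixed table, hand-computed: days 1,1,2,3 -> GI = 2 + 1/2 + 1/3;
  # shoots 2,3,4,1 -> mean 2.5
  t <- germTable(c(1, 1, 1, 1, 0), day = c(1L, 1L, 2L, 3L, NA),
                 shoot = c(2, 3, 4, 1, NA))
  expect_equal(vigorIndex(t), (2 + 1 / 2 + 1 / 3) * 2.5)
  # faster germination raises the index
  tSlow <- germTable(c(1, 1), day = c(4L, 4L), shoot = c(2, 2))
  tFast <- germTable(c(1, 1), day = c(2L, 4L), shoot = c(2, 2))
  expect_gt(vigorIndex(tFast), vigorIndex(tSlow))
  expect_error(vigorIndex(germTable(1, day = 1L, shoot = -2)),
               "nonnegative")
  expect_error(vigorIndex(germTable(1)), "germination day")
})

test_that("coefficient of variation matches the closed form and an oracle", {
  expect_equal(coefficientOfVariation(rep(3, 5)), 0)
  expect_equal(coefficientOfVariation(c(1, 3)), 100 * sqrt(2) / 2)
  set.seed(111)
  x <- rlnorm(50)
  twoPass <- 100 * sqrt(sum((x - mean(x))^2) / (length(x) - 1)) / mean(x)
  expect_equal(coefficientOfVariation(x), twoPass, tolerance = 1e-12)
  expect_error(coefficientOfVariation(c(-1, 1)), "zero mean")
  expect_error(coefficientOfVariation(3), "at least 2")
})

test_that("morphology of a disc is round, symmetric and compact", {
  m <- ellipseMask(64, 64, 32, 32, 22, 22)
  f <- morphFeatures(m)
  expect_equal(f$area_px, sum(m))
  expect_gt(f$width_length_ratio, 0.95)
  expect_lt(abs(f$vertical_skewness), 0.05)
  expect_gt(f$compactness_circle, 0.9)
  expect_lt(f$compactness_circle, 1.1)
})

test_that("an axis-aligned 2:1 ellipse has the expected axes", {
  m <- ellipseMask(128, 128, 64, 64, 40, 20)   # a along x
  f <- morphFeatures(m)
  expect_equal(f$width_length_ratio, 0.5, tolerance = 0.05)
  expect_equal(f$length_px, 80, tolerance = 80 * 0.05)
  expect_true(f$orientation_deg < 5 || f$orientation_deg > 175)
  expect_equal(f$compactness_ellipse, 1, tolerance = 0.1)
  # rotated ellipse: orientation follows
  mr <- ellipseMask(128, 128, 64, 64, 40, 20, theta = pi / 4)
  fr <- morphFeatures(mr)
  expect_equal(fr$orientation_deg, 45, tolerance = 3)
})

test_that("features are translation invariant and scale as expected", {
  m1 <- ellipseMask(100, 100, 40, 40, 20, 10, theta = 0.4)
  m2 <- ellipseMask(100, 100, 55, 58, 20, 10, theta = 0.4)
  f1 <- morphFeatures(m1); f2 <- morphFeatures(m2)
  expect_equal(f1$area_px, f2$area_px, tolerance = 0.02 * f1$area_px)
  expect_equal(f1$length_px, f2$length_px, tolerance = 0.05 * f1$length_px)
  # 2x upsampling: area ~x4, length ~x2
  m4 <- ellipseMask(200, 200, 80, 80, 40, 20, theta = 0.4)
  f4 <- morphFeatures(m4)
  expect_equal(f4$area_px / f1$area_px, 4, tolerance = 0.1)
  expect_equal(f4$length_px / f1$length_px, 2, tolerance = 0.1)
  expect_error(morphFeatures(matrix(FALSE, 4, 4)), "nonempty")
  disc <- matrix(FALSE, 10, 10); disc[2, 2] <- TRUE; disc[8, 8] <- TRUE
  expect_error(morphFeatures(disc), "connected")
})

test_that("beta-shape parameters are symmetric for symmetric masks", {
  m <- ellipseMask(64, 64, 32, 32, 15, 25)
  f <- morphFeatures(m)
  expect_equal(f$betashape_a, f$betashape_b, tolerance = 0.05)
  expect_gt(f$betashape_a, 1)   # unimodal row profile
})
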