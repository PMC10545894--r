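# Conventional seed-vigour statistics and per-seed morphology.

.checkGermTable <- function(t) {
  need <- c("germinated", "day_of_germination", "shoot_length_cm")
  if (!all(need %in% names(t)))
    stop(sprintf("germination table needs columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  if (nrow(t) == 0L) stop("germination table is empty", call. = FALSE)
  g <- t$germinated == 1
  if (any(g & is.na(t$day_of_germination)))
    stop("germinated seeds must have a germination day", call. = FALSE)
  if (any(!is.na(t$day_of_germination) & t$day_of_germination < 1))
    stop("germination day must be >= 1", call. = FALSE)
  invisible(t)
}

#' Germination rate (percent)
#'
#' @param t germination table (columns germinated, day_of_germination,
#'   shoot_length_cm; see [generateGerminationTable()]).
#' @return percent of seeds germinated.
#' @export
germinationRate <- function(t) {
  .checkGermTable(t)
  100 * mean(t$germinated == 1)
}

#' Vigor index
#'
#' VI = GI x mean shoot length of germinated seeds, with the germination
#' index GI = sum over days t of G_t / D_t, where G_t seeds germinated on
#' day D_t. Faster germination therefore raises the index. Returns 0 when
#' nothing germinated.
#'
#' @param t germination table.
#' @return vigor index (cm-weighted germination speed).
#' @export
vigorIndex <- function(t) {
  .checkGermTable(t)
  g <- t[t$germinated == 1, , drop = FALSE]
  if (nrow(g) == 0L) return(0)
  if (any(is.na(g$shoot_length_cm)))
    stop("germinated seeds must have a shoot length", call. = FALSE)
  if (any(g$shoot_length_cm < 0))
    stop("shoot lengths must be nonnegative", call. = FALSE)
  gi <- sum(table(g$day_of_germination) /
              as.numeric(names(table(g$day_of_germination))))
  gi * mean(g$shoot_length_cm)
}

#' Coefficient of variation (percent)
#'
#' 100 x sample standard deviation / mean.
#'
#' @param x numeric vector, length >= 2, nonzero mean.
#' @return CV in percent.
#' @export
coefficientOfVariation <- function(x) {
  if (length(x) < 2L) stop("need at least 2 values", call. = FALSE)
  m <- mean(x)
  if (m == 0) stop("zero mean: CV undefined", call. = FALSE)
  100 * sd(x) / m
}

# Crofton-formula perimeter (4 directions): classify each 2x2 pixel
# configuration and weight by the integral-geometry LUT. Low bias on
# smooth shapes (a rasterized disc scores within a few percent).
.maskPerimeter <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  img <- matrix(0L, H + 3L, W + 3L)
  img[2:(H + 1L), 2:(W + 1L)] <- as.integer(mask)
  i <- 2:(H + 3L); j <- 2:(W + 3L)
  code <- img[i, j] + 4L * img[i, j - 1L] + 2L * img[i - 1L, j] +
    8L * img[i - 1L, j - 1L]
  h <- tabulate(as.vector(code) + 1L, nbins = 16L)
  coefs <- c(0, pi / 4 * (1 + 1 / sqrt(2)), pi / (4 * sqrt(2)),
             pi / (2 * sqrt(2)), 0, pi / 4 * (1 + 1 / sqrt(2)), 0,
             pi / (4 * sqrt(2)), pi / 4, pi / 2, pi / (4 * sqrt(2)),
             pi / (4 * sqrt(2)), pi / 4, pi / 2, 0, 0)
  sum(coefs * h)
}

#' Morphological features of one seed mask
#'
#' Area (pixel count), length/width (extents along the principal axes),
#' width/length ratio, circle compactness 4 pi A / P^2 (1 for a disc),
#' ellipse compactness A / (pi (length/2) (width/2)), vertical skewness
#' (third standardized moment of the row coordinates), orientation of the
#' major principal axis (degrees from the image x-axis, in \[0, 180)), and
#' a method-of-moments Beta(a, b) fit to the min-max-normalized row
#' coordinates (the "betashape" descriptors). The perimeter uses a weighted
#' border-pixel estimator with low bias on smooth shapes.
#'
#' @param mask logical H x W matrix; must be nonempty and 4-connected.
#' @return named list of features.
#' @export
morphFeatures <- function(mask) {
  if (!is.logical(mask) || !any(mask))
    stop("mask must be a nonempty logical matrix", call. = FALSE)
  lab <- EBImage::bwlabel(mask)
  if (max(lab) != 1L)
    stop(sprintf("mask must be one connected component (found %d)",
                 max(lab)), call. = FALSE)
  idx <- which(mask, arr.ind = TRUE)
  ys <- idx[, 1L]; xs <- idx[, 2L]
  area <- nrow(idx)
  cy <- mean(ys); cx <- mean(xs)
  covm <- stats::cov(cbind(xs, ys)) * (area - 1) / area
  eg <- eigen(covm, symmetric = TRUE)
  major <- eg$vectors[, 1L]
  minor <- eg$vectors[, 2L]
  pMaj <- (xs - cx) * major[1] + (ys - cy) * major[2]
  pMin <- (xs - cx) * minor[1] + (ys - cy) * minor[2]
  len <- diff(range(pMaj)) + 1
  wid <- diff(range(pMin)) + 1
  P <- .maskPerimeter(mask)
  u <- (ys - min(ys)) / max(1, diff(range(ys)))
  mu <- mean(u); vu <- var(u)
  shape <- if (is.na(vu) || vu == 0) c(NA_real_, NA_real_) else {
    k <- mu * (1 - mu) / vu - 1
    c(mu * k, (1 - mu) * k)
  }
  sdy <- sd(ys)
  list(
    area_px = area,
    length_px = len,
    width_px = wid,
    width_length_ratio = wid / len,
    compactness_circle = 4 * pi * area / P^2,
    compactness_ellipse = area / (pi * (len / 2) * (wid / 2)),
    vertical_skewness = if (sdy == 0) 0 else
      mean((ys - cy)^3) / (mean((ys - cy)^2))^1.5,
    orientation_deg = (atan2(major[2], major[1]) * 180 / pi) %% 180,
    betashape_a = shape[1],
    betashape_b = shape[2]
  )
}
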