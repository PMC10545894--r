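# CIELab-mediated colour quantification of (stained-)seed RGB images.
# Conversion assumes sRGB encoding and the D65/2-degree reference white;
# both are exposed because the acquisition hardware's colour pipeline is
# generally unspecified.

.srgbToXyzM <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)

.d65 <- c(X = 0.95047, Y = 1.00000, Z = 1.08883)

.labF <- function(t) {
  d <- (6 / 29)^3
  ifelse(t > d, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
}

.labFinv <- function(f) {
  d <- 6 / 29
  ifelse(f > d, f^3, 3 * d^2 * (f - 4 / 29))
}

#' Convert sRGB to CIE 1976 L*a*b*
#'
#' Decodes the sRGB transfer function (IEC 61966-2-1), maps to CIE XYZ and
#' applies the CIE 1976 formulas under the D65/2-degree white point.
#'
#' @param rgb numeric array H x W x 3 in \[0, 1\], or an N x 3 matrix of
#'   colours.
#' @param whitePoint XYZ reference white (default D65).
#' @return same shape as the input, channels (L*, a*, b*); L* in \[0, 100\].
#' @export
rgbToLab <- function(rgb, whitePoint = c(0.95047, 1, 1.08883)) {
  isArr <- length(dim(rgb)) == 3L
  m <- if (isArr) matrix(rgb, ncol = 3L) else as.matrix(rgb)
  if (ncol(m) != 3L) stop("need 3 colour channels", call. = FALSE)
  if (anyNA(m) || min(m) < 0 || max(m) > 1)
    stop("RGB values must lie in [0, 1]", call. = FALSE)
  lin <- ifelse(m <= 0.04045, m / 12.92, ((m + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(.srgbToXyzM)
  xyz <- sweep(xyz, 2, whitePoint, "/")
  fx <- .labF(xyz[, 1]); fy <- .labF(xyz[, 2]); fz <- .labF(xyz[, 3])
  lab <- cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
  if (isArr) array(lab, dim = dim(rgb)) else lab
}

#' Convert CIE 1976 L*a*b* back to sRGB
#'
#' Inverse of [rgbToLab()]; round trips on in-gamut colours agree to
#' floating-point precision. Out-of-gamut results are clipped to \[0, 1\].
#'
#' @param lab array H x W x 3 or N x 3 matrix of (L*, a*, b*).
#' @param whitePoint XYZ reference white (default D65).
#' @return sRGB values in \[0, 1\], same shape as the input.
#' @export
labToRgb <- function(lab, whitePoint = c(0.95047, 1, 1.08883)) {
  isArr <- length(dim(lab)) == 3L
  m <- if (isArr) matrix(lab, ncol = 3L) else as.matrix(lab)
  fy <- (m[, 1] + 16) / 116
  fx <- fy + m[, 2] / 500
  fz <- fy - m[, 3] / 200
  xyz <- cbind(.labFinv(fx), .labFinv(fy), .labFinv(fz))
  xyz <- sweep(xyz, 2, whitePoint, "*")
  lin <- xyz %*% t(solve(.srgbToXyzM))
  srgb <- ifelse(lin <= 0.0031308, 12.92 * lin,
                 1.055 * pmax(lin, 0)^(1 / 2.4) - 0.055)
  srgb <- clamp(srgb, 0, 1)
  if (isArr) array(srgb, dim = dim(lab)) else srgb
}

#' LabSummary: colorimetric summary of one stained region
#'
#' @slot LStar,AStar,BStar mean CIELab coordinates over the region.
#' @slot stainedFraction fraction of region pixels called stained
#'   (a* at or above the staining threshold).
#' @slot regionPx region size in pixels.
#' @export
setClass("LabSummary",
  representation(LStar = "numeric", AStar = "numeric", BStar = "numeric",
                 stainedFraction = "numeric", regionPx = "integer"))

setMethod("show", "LabSummary", function(object) {
  cat(sprintf(
    "LabSummary: L* %.2f  a* %.2f  b* %.2f  stained %.1f%% of %d px\n",
    object@LStar, object@AStar, object@BStar,
    100 * object@stainedFraction, object@regionPx))
})

#' Colorimetric summary of a masked image region
#'
#' Mean L*, a*, b* over the mask, plus the fraction of mask pixels whose a*
#' (green-red axis; red formazan staining drives a* up) is at or above
#' `stainThresholdA`. The default threshold of 15 a* units is a documented
#' surrogate for a visual "stained" call.
#'
#' @param rgb numeric array H x W x 3 in \[0, 1\].
#' @param mask logical H x W matrix, nonempty.
#' @param stainThresholdA a* threshold for calling a pixel stained.
#' @return a [LabSummary-class].
#' @export
summarizeRegion <- function(rgb, mask, stainThresholdA = 15) {
  if (!is.logical(mask) || !all(dim(mask) == dim(rgb)[1:2]))
    stop("'mask' must be a logical H x W matrix matching the image",
         call. = FALSE)
  if (!any(mask)) stop("mask is empty (no TRUE pixel)", call. = FALSE)
  px <- cbind(rgb[, , 1][mask], rgb[, , 2][mask], rgb[, , 3][mask])
  lab <- rgbToLab(px)
  new("LabSummary",
      LStar = mean(lab[, 1]), AStar = mean(lab[, 2]), BStar = mean(lab[, 3]),
      stainedFraction = mean(lab[, 2] >= stainThresholdA),
      regionPx = sum(mask))
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper used for all correlation reporting (colorimetry
#' vs vigour, band reflectance vs vigour).
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  cor(x, y)
}
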