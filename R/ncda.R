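# Normalized canonical discriminant analysis of per-pixel spectra.
#
# The instrument vendor's nCDA is proprietary; here it is defined as the
# first canonical axis of a regularized Fisher discriminant (between-class
# over within-class scatter), with training projections min-max normalized
# to [-1, 1] for rendering. This definition is this package's own and is
# not claimed to be bit-compatible with any instrument software.

#' Fit a normalized canonical discriminant axis on pixel spectra
#'
#' Computes the leading eigenvector of `solve(Sw + lambda I) Sb`, where Sw
#' and Sb are the within- and between-class scatter matrices of the pixel
#' spectra. The within-class scatter is ridge-regularized with
#' `lambda = 1e-6 trace(Sw) / B` (applied always; it is what makes singular
#' scatter solvable). The axis is oriented so that the class with the
#' highest label (by convention the longest-aged group) has positive mean
#' score, and the training projection range is stored for normalization.
#'
#' @param pixelSpectra numeric matrix n x B of per-pixel reflectance.
#' @param classLabels vector of class labels (>= 2 classes, each with at
#'   least B + 1 pixels).
#' @return an [NcdaModel-class].
#' @export
fitNcda <- function(pixelSpectra, classLabels) {
  X <- as.matrix(pixelSpectra)
  B <- ncol(X)
  cls <- sort(unique(as.numeric(classLabels)))
  if (length(cls) < 2L)
    stop("need at least 2 classes to fit a discriminant axis", call. = FALSE)
  counts <- table(classLabels)
  if (any(counts < B + 1L))
    warning(sprintf(
      "class '%s' has fewer pixels (%d) than bands + 1 (%d); scatter is rank-deficient and relies on regularization",
      names(counts)[which.min(counts)], min(counts), B + 1L))
  grand <- colMeans(X)
  Sw <- matrix(0, B, B)
  Sb <- matrix(0, B, B)
  classMeans <- matrix(0, length(cls), B,
                       dimnames = list(as.character(cls), colnames(X)))
  for (i in seq_along(cls)) {
    Xi <- X[classLabels == cls[i], , drop = FALSE]
    mi <- colMeans(Xi)
    classMeans[i, ] <- mi
    Xc <- sweep(Xi, 2, mi)
    Sw <- Sw + crossprod(Xc)
    Sb <- Sb + nrow(Xi) * tcrossprod(mi - grand)
  }
  lambda <- 1e-6 * sum(diag(Sw)) / B
  if (lambda == 0) lambda <- 1e-12
  M <- solve(Sw + diag(lambda, B), Sb)
  eg <- eigen(M)
  w <- Re(eg$vectors[, which.max(Re(eg$values))])
  # orient: highest-label class scores positive
  if (sum((classMeans[length(cls), ] - grand) * w) < 0) w <- -w
  intercept <- sum(grand * w)
  scores <- as.vector(X %*% w) - intercept
  rng <- range(scores)
  if (rng[1] >= rng[2]) rng <- c(rng[1] - 1e-9, rng[2] + 1e-9)
  new("NcdaModel", weights = w, intercept = intercept, scoreRange = rng,
      classMeans = classMeans, classes = cls)
}

# fixed blue -> green -> yellow -> red rendering ramp
.ncdaRamp <- grDevices::colorRamp(c("blue", "green", "yellow", "red"))

#' Project a spectral stack onto a fitted nCDA axis
#'
#' Pixel scores are the discriminant projections min-max normalized by the
#' training score range to \[-1, 1\] and clipped; a pseudocolor rendering
#' maps -1..1 through a fixed blue-green-yellow-red ramp (low-vigour groups
#' cold, long-aged groups hot).
#'
#' @param model a fitted [NcdaModel-class].
#' @param stack a [SpectralStack-class] with the same band count.
#' @return list with `score` (H x W matrix in \[-1, 1\]) and `pseudocolor`
#'   (H x W x 3 sRGB array).
#' @export
transformNcda <- function(model, stack) {
  stopifnot(is(model, "NcdaModel"), is(stack, "SpectralStack"))
  b <- bands(stack)
  B <- dim(b)[3]
  if (B != length(model@weights))
    stop(sprintf("stack has %d bands but model was fitted on %d",
                 B, length(model@weights)), call. = FALSE)
  flat <- matrix(b, ncol = B)
  s <- as.vector(flat %*% model@weights) - model@intercept
  lo <- model@scoreRange[1]; hi <- model@scoreRange[2]
  s <- clamp(2 * (s - lo) / (hi - lo) - 1, -1, 1)
  score <- matrix(s, dim(b)[1], dim(b)[2])
  cols <- .ncdaRamp((s + 1) / 2) / 255
  pseudo <- array(cols, dim = c(dim(b)[1], dim(b)[2], 3L))
  list(score = score, pseudocolor = pseudo)
}

#' Per-band correlation between seed spectra and vigour
#'
#' Pearson correlation of each band's per-seed mean reflectance with a
#' vigour measure. A band with zero variance yields NA.
#'
#' @param perSeedSpectra numeric matrix n x B (rows = seeds).
#' @param vigor numeric vigour vector of length n (n >= 3).
#' @return named numeric vector of B correlation coefficients.
#' @export
bandCorrelations <- function(perSeedSpectra, vigor) {
  X <- as.matrix(perSeedSpectra)
  if (nrow(X) != length(vigor))
    stop("spectra rows and vigour length differ", call. = FALSE)
  if (nrow(X) < 3L) stop("need at least 3 seeds", call. = FALSE)
  out <- vapply(seq_len(ncol(X)), function(b) {
    if (sd(X[, b]) == 0 || sd(vigor) == 0) return(NA_real_)
    cor(X[, b], vigor)
  }, numeric(1))
  names(out) <- colnames(X)
  out
}
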