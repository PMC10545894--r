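# internal helpers shared across modules

#' Round half-up to a fixed number of decimals
#'
#' Display rounding used for percent metrics (base `round()` rounds half to
#' even, which does not match conventional table formatting).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector; NAs pass through.
#' @export
roundHalfUp <- function(x, digits = 2) {
  m <- 10^digits
  out <- floor(x * m + 0.5) / m
  out[is.na(x)] <- NA_real_
  out
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# canonical 19-band wavelength set of the imaging instrument (nm)
#' Canonical instrument wavelengths
#'
#' The 19 acquisition wavelengths (365-970 nm) of the multispectral
#' instrument the pipeline targets.
#'
#' @return numeric vector of 19 wavelengths in nm.
#' @export
canonicalWavelengths <- function() {
  c(365, 405, 430, 450, 470, 490, 515, 540, 570, 590,
    630, 645, 660, 690, 780, 850, 880, 890, 970)
}

.assertScalarNumber <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
}
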