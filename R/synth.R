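#' SceneSpec: parameters of a synthetic multispectral dish scene
#'
#' The generator emulates one acquisition: ~50 elliptical seeds placed evenly
#' (jittered grid) inside a circular dish, imaged in B spectral bands plus
#' RGB. The two seed classes share a smooth base spectrum; the aged /
#' non-germinating class gains `nirShift` reflectance in every band at or
#' above 780 nm, so class contrast concentrates in the near infrared while
#' visible bands differ only by noise. Pixel noise is i.i.d. Gaussian per
#' band, clipped to \[0, 1\].
#'
#' @slot nSeeds number of seeds (>= 0).
#' @slot dishRadiusPx dish radius in pixels.
#' @slot imageSize square image side in pixels.
#' @slot classSpectra 2 x B matrix of per-class base mean reflectances
#'   (row 1 = germinated, row 2 = aged/non-germinating, before `nirShift`).
#' @slot nirShift reflectance added to the aged class in bands >= 780 nm.
#' @slot noiseSd Gaussian pixel noise standard deviation.
#' @slot seedAxesPx (min, max) ellipse semi-axes in pixels.
#' @slot germinatedFraction fraction of seeds labelled germinated.
#' @slot rngSeed integer random seed (scenes are bitwise reproducible).
#' @slot wavelengths band wavelengths in nm.
#' @slot background background reflectance level.
#' @export
setClass("SceneSpec",
  representation(
    nSeeds = "integer", dishRadiusPx = "integer", imageSize = "integer",
    classSpectra = "matrix", nirShift = "numeric", noiseSd = "numeric",
    seedAxesPx = "numeric", germinatedFraction = "numeric",
    rngSeed = "integer", wavelengths = "numeric", background = "numeric"
  )
)

setValidity("SceneSpec", function(object) {
  if (object@nSeeds < 0L) return("nSeeds must be >= 0")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (nrow(object@classSpectra) != 2L)
    return("classSpectra must have 2 rows (germinated, aged)")
  if (ncol(object@classSpectra) != length(object@wavelengths))
    return("classSpectra columns must match wavelength count")
  if (any(object@classSpectra < 0 | object@classSpectra > 1))
    return("class spectra must lie in [0, 1]")
  if (length(object@seedAxesPx) != 2L ||
      object@seedAxesPx[1] > object@seedAxesPx[2])
    return("seedAxesPx must be (min, max) with min <= max")
  if (object@germinatedFraction < 0 || object@germinatedFraction > 1)
    return("germinatedFraction must be in [0, 1]")
  TRUE
})

#' Build a SceneSpec with study-scale defaults
#'
#' Defaults emulate the acquisition geometry of the target instrument at half
#' resolution: a 1096 px frame (half of the instrument's 2192 px), 50 seeds
#' in a dish of radius ~0.45 x frame, 19 canonical wavelengths, seed
#' semi-axes 18-48 px (a ~8 x 3 mm rice grain at this scale), smooth base
#' reflectance rising from 0.30 (365 nm) to 0.55 (970 nm) against a 0.05
#' background, noise SD 0.01, and an aged-class NIR shift of +0.08.
#'
#' @param nSeeds seeds per dish.
#' @param imageSize square frame side (px). All downstream modules are
#'   size-agnostic; tests use smaller frames.
#' @param dishRadiusPx dish radius; default 45\% of the frame.
#' @param wavelengths band wavelengths (nm).
#' @param baseSpectrum length-B base reflectance (default smooth ramp).
#' @param nirShift aged-class reflectance increment in bands >= 780 nm.
#' @param noiseSd Gaussian pixel noise SD.
#' @param seedAxesPx (min, max) ellipse semi-axes (px). Scaled with
#'   `imageSize` relative to the 1096 default if not given.
#' @param germinatedFraction fraction of seeds labelled germinated.
#' @param rngSeed integer random seed.
#' @param background background reflectance.
#' @return a [SceneSpec-class].
#' @export
sceneSpec <- function(nSeeds = 50, imageSize = 1096,
                      dishRadiusPx = NULL,
                      wavelengths = canonicalWavelengths(),
                      baseSpectrum = NULL,
                      nirShift = 0.08, noiseSd = 0.01,
                      seedAxesPx = NULL,
                      germinatedFraction = 0.5,
                      rngSeed = 1L, background = 0.05) {
  if (is.null(dishRadiusPx)) dishRadiusPx <- floor(imageSize * 0.45)
  if (is.null(seedAxesPx)) {
    s <- imageSize / 1096
    seedAxesPx <- c(18, 48) * s
  }
  if (is.null(baseSpectrum)) {
    baseSpectrum <- 0.30 + 0.25 * (wavelengths - min(wavelengths)) /
      (max(wavelengths) - min(wavelengths))
  }
  cs <- rbind(germinated = baseSpectrum, aged = baseSpectrum)
  new("SceneSpec",
      nSeeds = as.integer(nSeeds), dishRadiusPx = as.integer(dishRadiusPx),
      imageSize = as.integer(imageSize), classSpectra = cs,
      nirShift = nirShift, noiseSd = noiseSd,
      seedAxesPx = as.numeric(seedAxesPx),
      germinatedFraction = germinatedFraction,
      rngSeed = as.integer(rngSeed), wavelengths = as.numeric(wavelengths),
      background = background)
}

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(
    "SceneSpec: %d seeds, %d px frame, %d bands, nirShift %.3g, noiseSd %.3g, seed %d\n",
    object@nSeeds, object@imageSize, length(object@wavelengths),
    object@nirShift, object@noiseSd, object@rngSeed))
})

#' Generate a synthetic dish scene with ground truth
#'
#' Seeds are randomly oriented ellipses placed on a jittered grid restricted
#' to the dish interior (emulating even manual placement; guarantees
#' pairwise-disjoint bounding boxes). Each seed's pixels take its class mean
#' spectrum; the aged class additionally gains `nirShift` in bands >= 780 nm.
#' I.i.d. Gaussian noise (SD `noiseSd`) is added per band and per RGB
#' channel, then clipped to \[0, 1\]. The RGB image is rendered from the
#' bands nearest 630, 540 and 450 nm so colorimetry has a defined relation
#' to the spectral cube. Output is deterministic for a fixed `rngSeed`.
#'
#' @param spec a [SceneSpec-class].
#' @return list with elements `stack` ([SpectralStack-class]) and
#'   `truth` ([GroundTruth-class]).
#' @export
generateScene <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  validObject(spec)
  set.seed(spec@rngSeed)
  n <- spec@nSeeds
  sz <- spec@imageSize
  wl <- spec@wavelengths
  B <- length(wl)
  # gap >= 10% of the major axis bounds the jittered seed's diagonal reach
  # by cell/2, so "cell centre within dishRadius - cell/2" keeps seeds inside
  gap <- max(2, ceiling(spec@seedAxesPx[2] * 0.1))

  # jittered-grid placement: cells sized to hold any seed orientation
  cell <- 2 * (spec@seedAxesPx[2] + gap)
  centres <- NULL
  if (n > 0) {
    half <- sz / 2
    k <- floor(2 * spec@dishRadiusPx / cell)
    if (k < 1) stop("infeasible packing: dish smaller than one seed cell",
                    call. = FALSE)
    offs <- (seq_len(k) - (k + 1) / 2) * cell
    grid <- expand.grid(cx = half + offs, cy = half + offs)
    # keep cells where a seed fits at the cell centre; jitter is clamped
    # per seed below so boundary-cell seeds stay inside the dish
    ok <- sqrt((grid$cx - half)^2 + (grid$cy - half)^2) +
      spec@seedAxesPx[2] <= spec@dishRadiusPx
    grid <- grid[ok, , drop = FALSE]
    if (nrow(grid) < n)
      stop(sprintf(
        "infeasible packing: %d seeds requested but only %d placement cells fit the dish",
        n, nrow(grid)), call. = FALSE)
    centres <- grid[sample.int(nrow(grid), n), , drop = FALSE]
  }

  nGerm <- round(n * spec@germinatedFraction)
  labels <- integer(n)
  if (n > 0) labels[sample.int(n, nGerm)] <- 1L

  nir <- wl >= 780
  spectra <- spec@classSpectra
  spectra["aged", nir] <- pmin(1, spectra["aged", nir] + spec@nirShift)

  bandsArr <- array(spec@background, dim = c(sz, sz, B))
  boxes <- data.frame(x_min = integer(0), y_min = integer(0),
                      x_max = integer(0), y_max = integer(0))
  masks <- vector("list", n)

  if (n > 0) {
    amin <- spec@seedAxesPx[1]; amax <- spec@seedAxesPx[2]
    for (i in seq_len(n)) {
      a <- runif(1, 0.80 * amax, amax)                 # major semi-axis
      b <- runif(1, amin, min(a, 1.30 * amin))         # minor semi-axis
      th <- runif(1, 0, pi)
      cdist <- sqrt((centres$cx[i] - sz / 2)^2 + (centres$cy[i] - sz / 2)^2)
      jmax <- max(0, min(cell / 2 - a - gap,
                         (spec@dishRadiusPx - a - cdist) / sqrt(2)))
      cx <- centres$cx[i] + runif(1, -1, 1) * jmax
      cy <- centres$cy[i] + runif(1, -1, 1) * jmax
      hx <- sqrt((a * cos(th))^2 + (b * sin(th))^2)
      hy <- sqrt((a * sin(th))^2 + (b * cos(th))^2)
      xs <- max(1L, floor(cx - hx)):min(sz, ceiling(cx + hx))
      ys <- max(1L, floor(cy - hy)):min(sz, ceiling(cy + hy))
      dx <- outer(rep(1, length(ys)), xs - cx)
      dy <- outer(ys - cy, rep(1, length(xs)))
      u <- (dx * cos(th) + dy * sin(th)) / a
      v <- (-dx * sin(th) + dy * cos(th)) / b
      m <- u * u + v * v <= 1
      rr <- range(which(rowSums(m) > 0)); cc <- range(which(colSums(m) > 0))
      m <- m[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
      y0 <- ys[rr[1]]; x0 <- xs[cc[1]]
      rows <- y0:(y0 + nrow(m) - 1L); cols <- x0:(x0 + ncol(m) - 1L)
      spec_i <- spectra[if (labels[i] == 1L) "germinated" else "aged", ]
      for (k2 in seq_len(B)) {
        plane <- bandsArr[rows, cols, k2]
        plane[m] <- spec_i[k2]
        bandsArr[rows, cols, k2] <- plane
      }
      boxes <- rbind(boxes, data.frame(
        x_min = x0 - 1L, y_min = y0 - 1L,
        x_max = x0 - 1L + ncol(m), y_max = y0 - 1L + nrow(m)))
      masks[[i]] <- m
    }
  }

  rgbIdx <- vapply(c(630, 540, 450), function(t) which.min(abs(wl - t)),
                   integer(1))
  rgb <- bandsArr[, , rgbIdx, drop = FALSE]

  if (spec@noiseSd > 0) {
    bandsArr <- bandsArr + rnorm(length(bandsArr), sd = spec@noiseSd)
    rgb <- rgb + rnorm(length(rgb), sd = spec@noiseSd)
  }
  bandsArr <- clamp(bandsArr, 0, 1)
  rgb <- clamp(rgb, 0, 1)

  stack <- spectralStack(bandsArr, wl, rgb = array(rgb, dim = c(sz, sz, 3L)),
                         dishId = sprintf("synthetic-%d", spec@rngSeed))
  truth <- new("GroundTruth", boxes = boxes, labels = labels, masks = masks)
  list(stack = stack, truth = truth)
}

#' Generate a synthetic per-seed germination table
#'
#' Each seed germinates independently with probability `rate`; germinated
#' seeds draw a germination day (geometric-weighted towards early days,
#' truncated at `maxDay`) and a positive shoot length; non-germinated rows
#' carry missing day and shoot length.
#'
#' @param n number of seeds.
#' @param rate germination probability in \[0, 1\].
#' @param maxDay latest possible germination day.
#' @param shootMean mean shoot length (cm) of germinated seeds.
#' @param rngSeed integer random seed.
#' @return data.frame with columns seed_id, germinated (0/1),
#'   day_of_germination, shoot_length_cm.
#' @export
generateGerminationTable <- function(n, rate, maxDay = 10, shootMean = 5,
                                     rngSeed = 1L) {
  if (rate < 0 || rate > 1) stop("'rate' must be in [0, 1]", call. = FALSE)
  set.seed(as.integer(rngSeed))
  germ <- stats::rbinom(n, 1L, rate)
  day <- rep(NA_integer_, n)
  shoot <- rep(NA_real_, n)
  idx <- which(germ == 1L)
  if (length(idx) > 0) {
    p <- stats::dgeom(seq_len(maxDay) - 1L, 0.4)
    day[idx] <- sample(seq_len(maxDay), length(idx), replace = TRUE,
                       prob = p / sum(p))
    shoot[idx] <- pmax(0.1, rnorm(length(idx), shootMean, 0.25 * shootMean))
  }
  data.frame(seed_id = sprintf("seed%04d", seq_len(n)),
             germinated = as.integer(germ),
             day_of_germination = day, shoot_length_cm = shoot)
}
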