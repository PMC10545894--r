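#' Construct a SpectralStack
#'
#' @param bands numeric array H x W x B of reflectance in \[0, 1\] (a matrix is
#'   promoted to a single-band array).
#' @param wavelengths numeric vector of B wavelengths in nm, strictly
#'   increasing.
#' @param rgb numeric array H x W x 3 in \[0, 1\]. Defaults to a grey preview
#'   rendered from the first band when the acquisition carries no RGB image.
#' @param dishId acquisition identifier.
#' @return a [SpectralStack-class].
#' @export
spectralStack <- function(bands, wavelengths, rgb = NULL, dishId = "dish") {
  if (is.matrix(bands)) bands <- array(bands, dim = c(dim(bands), 1L))
  if (is.null(rgb)) {
    rgb <- array(bands[, , 1L], dim = c(dim(bands)[1:2], 3L))
  }
  new("SpectralStack", bands = bands, wavelengths = as.numeric(wavelengths),
      rgb = rgb, dishId = dishId)
}

.readImageFile <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    "tif" = , "tiff" = tiff::readTIFF(path),
    "png" = png::readPNG(path),
    stop(sprintf("unsupported image format '%s' for file '%s'", ext, path),
         call. = FALSE)
  )
  # drop alpha if present; collapse single-channel planes to a matrix
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
    if (dim(img)[3] == 1L) img <- img[, , 1L]
  }
  img
}

.asGrey <- function(img, path) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3L && dim(img)[3] == 3L) {
    # colour file supplied for a single band: average channels
    return((img[, , 1] + img[, , 2] + img[, , 3]) / 3)
  }
  stop(sprintf("file '%s' is not a single-band image", path), call. = FALSE)
}

#' Read a multispectral dish acquisition from disk
#'
#' Accepts three dialects: (i) a character vector of per-band image files
#' (PNG or TIFF, ascending wavelength order), (ii) a directory containing
#' files named `<dish>_<wavelength>nm.<ext>` plus an optional
#' `<dish>_rgb.<ext>`, or (iii) a single multi-page TIFF whose pages are
#' bands in ascending wavelength order, with the RGB image as an optional
#' final 3-channel page or a separate file passed via `rgbPath`. Integer
#' pixel encodings are scaled by their maximum representable value, so an
#' 8-bit 255 and a 16-bit 65535 both read as reflectance 1.0.
#'
#' @param paths character vector of band files, a directory, or one
#'   multi-page TIFF.
#' @param wavelengths numeric vector of band wavelengths (nm). May be omitted
#'   for the directory dialect (parsed from file names) and defaults to
#'   [canonicalWavelengths()] when 19 bands are supplied without it.
#' @param rgbPath optional path of the RGB image when not deducible.
#' @param dishId acquisition identifier; defaults to a name derived from the
#'   input path.
#' @return a [SpectralStack-class].
#' @export
readStack <- function(paths, wavelengths = NULL, rgbPath = NULL,
                      dishId = NULL) {
  rgb <- if (!is.null(rgbPath)) .readImageFile(rgbPath) else NULL

  if (length(paths) == 1L && dir.exists(paths)) {
    files <- list.files(paths, pattern = "_[0-9.]+nm\\.(tif|tiff|png)$",
                        full.names = TRUE, ignore.case = TRUE)
    if (length(files) == 0L)
      stop(sprintf("no '<dish>_<wavelength>nm.*' band files found in '%s'",
                   paths), call. = FALSE)
    wl <- as.numeric(sub(".*_([0-9.]+)nm\\.[A-Za-z]+$", "\\1",
                         basename(files)))
    ord <- order(wl)
    files <- files[ord]
    if (is.null(wavelengths)) wavelengths <- wl[ord]
    if (is.null(rgb)) {
      rgbFiles <- list.files(paths, pattern = "_rgb\\.(tif|tiff|png)$",
                             full.names = TRUE, ignore.case = TRUE)
      if (length(rgbFiles) >= 1L) rgb <- .readImageFile(rgbFiles[1L])
    }
    if (is.null(dishId))
      dishId <- sub("_[0-9.]+nm\\.[A-Za-z]+$", "", basename(files[1L]))
    paths <- files
    imgs <- lapply(paths, .readImageFile)
    bandsList <- mapply(.asGrey, imgs, paths, SIMPLIFY = FALSE)
  } else if (length(paths) == 1L && grepl("\\.tiff?$", paths,
                                          ignore.case = TRUE)) {
    pages <- tiff::readTIFF(paths, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) {
      if (length(dim(p)) == 3L && dim(p)[3] == 4L) p[, , 1:3] else p
    })
    isColour <- vapply(pages, function(p) length(dim(p)) == 3L, logical(1))
    if (is.null(rgb) && isColour[length(pages)]) {
      rgb <- pages[[length(pages)]]
      pages <- pages[-length(pages)]
    }
    bandsList <- lapply(pages, .asGrey, path = paths)
    if (is.null(dishId))
      dishId <- tools::file_path_sans_ext(basename(paths))
  } else {
    imgs <- lapply(paths, .readImageFile)
    bandsList <- mapply(.asGrey, imgs, paths, SIMPLIFY = FALSE)
    if (is.null(dishId))
      dishId <- tools::file_path_sans_ext(basename(paths[1L]))
  }

  dims <- vapply(bandsList, dim, integer(2))
  bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])
  if (length(bad) > 0)
    stop(sprintf(
      "band dimension mismatch: '%s' is %d x %d but '%s' is %d x %d",
      basename(as.character(paths[1])), dims[1, 1], dims[2, 1],
      basename(as.character(paths[bad[1]])), dims[1, bad[1]], dims[2, bad[1]]),
      call. = FALSE)

  B <- length(bandsList)
  if (is.null(wavelengths) && B == 19L) wavelengths <- canonicalWavelengths()
  if (is.null(wavelengths))
    stop("'wavelengths' must be supplied (could not be inferred)",
         call. = FALSE)
  if (length(wavelengths) != B)
    stop(sprintf("wavelength count (%d) != band count (%d)",
                 length(wavelengths), B), call. = FALSE)

  bands <- array(unlist(bandsList, use.names = FALSE),
                 dim = c(dims[1, 1], dims[2, 1], B))
  if (!is.null(rgb) && !all(dim(rgb)[1:2] == dims[, 1]))
    stop(sprintf("RGB image is %d x %d but bands are %d x %d",
                 dim(rgb)[1], dim(rgb)[2], dims[1, 1], dims[2, 1]),
         call. = FALSE)
  spectralStack(bands, wavelengths, rgb = rgb, dishId = dishId)
}

#' Write a SpectralStack to per-band files with a JSON sidecar
#'
#' Writes one TIFF per band (`<dish>_<wavelength>nm.tif`), the RGB image
#' (`<dish>_rgb.tif`), and a `<dish>.json` sidecar recording `dish_id` and
#' `wavelengths_nm`.
#'
#' @param stack a [SpectralStack-class].
#' @param dir output directory (created if missing).
#' @param bitsPerSample 8 or 16.
#' @return invisibly, the sidecar path.
#' @export
writeStack <- function(stack, dir, bitsPerSample = 16) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- dishId(stack)
  wl <- wavelengths(stack)
  for (b in seq_along(wl)) {
    tiff::writeTIFF(bands(stack)[, , b],
                    file.path(dir, sprintf("%s_%gnm.tif", id, wl[b])),
                    bits.per.sample = bitsPerSample)
  }
  tiff::writeTIFF(rgbImage(stack), file.path(dir, sprintf("%s_rgb.tif", id)),
                  bits.per.sample = bitsPerSample)
  sidecar <- file.path(dir, sprintf("%s.json", id))
  jsonlite::write_json(list(dish_id = id, wavelengths_nm = wl), sidecar,
                       auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Merge spectral bands and RGB channels into one data cube
#'
#' Stacks the B spectral bands (ascending wavelength) and then the R, G, B
#' channels into a single H x W x (B+3) cube — the multi-channel input the
#' germination classifier consumes (22 channels for the 19-band instrument).
#' Pixel values are copied unchanged.
#'
#' @param stack a [SpectralStack-class].
#' @return a [MergedCube-class] with C = B + 3 channels.
#' @export
mergeChannels <- function(stack) {
  stopifnot(is(stack, "SpectralStack"))
  b <- bands(stack)
  d <- dim(b)
  cube <- array(0, dim = c(d[1], d[2], d[3] + 3L))
  cube[, , seq_len(d[3])] <- b
  cube[, , d[3] + 1:3] <- rgbImage(stack)
  new("MergedCube", cube = cube,
      channelNames = c(sprintf("%gnm", wavelengths(stack)), "R", "G", "B"))
}

#' Per-band mean reflectance over a pixel mask
#'
#' @param stack a [SpectralStack-class].
#' @param mask logical H x W matrix with at least one TRUE pixel.
#' @return named numeric vector of length B (names = wavelengths in nm).
#' @export
meanSpectrum <- function(stack, mask) {
  stopifnot(is(stack, "SpectralStack"))
  b <- bands(stack)
  if (!is.logical(mask) || !all(dim(mask) == dim(b)[1:2]))
    stop("'mask' must be a logical H x W matrix matching the stack",
         call. = FALSE)
  if (!any(mask)) stop("mask is empty (no TRUE pixel)", call. = FALSE)
  out <- vapply(seq_len(dim(b)[3]), function(k) mean(b[, , k][mask]),
                numeric(1))
  names(out) <- sprintf("%gnm", wavelengths(stack))
  out
}
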