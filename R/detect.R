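# Classical per-seed ROI detection. Fulfils the contract of the pipeline's
# object-detection stage with a deterministic detector: Otsu threshold on the
# band of maximal foreground/background contrast, hole filling, connected
# components, area filtering, and an optional single watershed split pass for
# oversized (touching) components. External detector output can be imported
# from YOLO-format annotation files instead.

.otsuVarB <- function(v, t) {
  lo <- v < t
  w0 <- mean(lo)
  if (w0 == 0 || w0 == 1) return(0)
  w0 * (1 - w0) * (mean(v[!lo]) - mean(v[lo]))^2
}

.componentBoxes <- function(lab) {
  nlab <- max(lab)
  out <- vector("list", nlab)
  idx <- which(lab > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(out)
  l <- lab[lab > 0]
  for (k in seq_len(nlab)) {
    sel <- l == k
    if (!any(sel)) next
    rows <- idx[sel, 1L]; cols <- idx[sel, 2L]
    out[[k]] <- c(x_min = min(cols) - 1L, y_min = min(rows) - 1L,
                  x_max = max(cols), y_max = max(rows),
                  area = sum(sel))
  }
  out
}

#' Detect seed bounding boxes on a dish acquisition
#'
#' Deterministic classical detector: the band with the largest Otsu
#' between-class variance (the highest-contrast band) is thresholded, holes
#' are filled, connected components are extracted, and components with pixel
#' area inside `[minAreaPx, maxAreaPx]` become detections. A component larger
#' than `maxAreaPx` (touching seeds) undergoes one watershed split pass on
#' its distance map before the area filter is re-applied. Boxes are 0-based
#' half-open and sorted row-major by (y_min, x_min). Detection is invariant
#' to image-wide affine intensity rescaling.
#'
#' @param stack a [SpectralStack-class].
#' @param minAreaPx minimum component pixel area.
#' @param maxAreaPx maximum component pixel area before a split is attempted.
#' @param minContrast minimum foreground/background mean separation as a
#'   fraction of the band's dynamic range; below it the image is treated as
#'   seed-free (Otsu always "finds" a split, even in pure noise). The ratio
#'   is invariant to affine intensity rescaling.
#' @return data.frame of boxes (x_min, y_min, x_max, y_max, score); zero rows
#'   when nothing is found.
#' @export
detectSeeds <- function(stack, minAreaPx = 50, maxAreaPx = Inf,
                        minContrast = 0.35) {
  stopifnot(is(stack, "SpectralStack"))
  b <- bands(stack)
  B <- dim(b)[3]
  # pick the band whose Otsu threshold separates classes best
  stats <- vapply(seq_len(B), function(k) {
    m <- b[, , k]
    t <- EBImage::otsu(m, range = c(0, 1))
    c(t = t, varB = .otsuVarB(as.vector(m), t))
  }, numeric(2))
  k <- which.max(stats["varB", ])
  v <- b[, , k]
  mask <- v > stats["t", k]
  rng <- max(v) - min(v)
  lowContrast <- rng == 0 || !any(mask) || all(mask) ||
    (mean(v[mask]) - mean(v[!mask])) < minContrast * rng
  if (lowContrast)
    return(data.frame(x_min = integer(0), y_min = integer(0),
                      x_max = integer(0), y_max = integer(0),
                      score = numeric(0)))
  mask <- EBImage::fillHull(mask)
  lab <- EBImage::bwlabel(mask)
  comps <- .componentBoxes(lab)
  keep <- list()
  for (ci in seq_along(comps)) {
    cb <- comps[[ci]]
    if (is.null(cb)) next
    if (cb["area"] < minAreaPx) next
    if (cb["area"] <= maxAreaPx) {
      keep[[length(keep) + 1L]] <- cb
    } else {
      # single watershed split pass on the oversized component
      rows <- (cb["y_min"] + 1L):cb["y_max"]
      cols <- (cb["x_min"] + 1L):cb["x_max"]
      sub <- lab[rows, cols, drop = FALSE] == ci
      ws <- EBImage::watershed(EBImage::distmap(sub))
      for (sb in .componentBoxes(ws)) {
        if (is.null(sb) || sb["area"] < minAreaPx || sb["area"] > maxAreaPx)
          next
        sb[c("x_min", "x_max")] <- sb[c("x_min", "x_max")] + cb["x_min"]
        sb[c("y_min", "y_max")] <- sb[c("y_min", "y_max")] + cb["y_min"]
        keep[[length(keep) + 1L]] <- sb
      }
    }
  }
  if (length(keep) == 0L)
    return(data.frame(x_min = integer(0), y_min = integer(0),
                      x_max = integer(0), y_max = integer(0),
                      score = numeric(0)))
  df <- as.data.frame(do.call(rbind, keep))
  df <- df[order(df$y_min, df$x_min), c("x_min", "y_min", "x_max", "y_max")]
  rownames(df) <- NULL
  df$score <- 1.0
  df
}

#' Read YOLO-format bounding-box annotations
#'
#' Parses the YOLO txt dialect (`class cx cy w h`, all normalized to
#' \[0, 1\]) into 0-based half-open pixel boxes. Line order is preserved.
#'
#' @param path annotation file.
#' @param imageSize integer (H, W) of the annotated image.
#' @return data.frame (class, x_min, y_min, x_max, y_max, score).
#' @export
loadYoloBoxes <- function(path, imageSize) {
  stopifnot(length(imageSize) == 2L)
  H <- imageSize[1]; W <- imageSize[2]
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(class = integer(0), x_min = integer(0),
                      y_min = integer(0), x_max = integer(0),
                      y_max = integer(0), score = numeric(0)))
  rows <- lapply(seq_along(lines), function(i) {
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    val <- suppressWarnings(as.numeric(tok))
    if (length(val) < 5L || anyNA(val[1:5]))
      stop(sprintf("malformed YOLO annotation at line %d: '%s'", i, lines[i]),
           call. = FALSE)
    c(class = val[1],
      x_min = round((val[2] - val[4] / 2) * W),
      y_min = round((val[3] - val[5] / 2) * H),
      x_max = round((val[2] + val[4] / 2) * W),
      y_max = round((val[3] + val[5] / 2) * H),
      score = if (length(val) >= 6L) val[6] else 1.0)
  })
  df <- as.data.frame(do.call(rbind, rows))
  df$class <- as.integer(df$class)
  df
}

#' Write boxes in YOLO txt format
#'
#' Inverse of [loadYoloBoxes()]; round trips agree within 1 px.
#'
#' @param boxes data.frame with x_min, y_min, x_max, y_max (0-based
#'   half-open) and optionally class.
#' @param path output file.
#' @param imageSize integer (H, W).
#' @return invisibly, `path`.
#' @export
writeYoloBoxes <- function(boxes, path, imageSize) {
  H <- imageSize[1]; W <- imageSize[2]
  cls <- if ("class" %in% names(boxes)) boxes$class else rep(0L, nrow(boxes))
  lines <- sprintf("%d %.8f %.8f %.8f %.8f", cls,
                   (boxes$x_min + boxes$x_max) / 2 / W,
                   (boxes$y_min + boxes$y_max) / 2 / H,
                   (boxes$x_max - boxes$x_min) / W,
                   (boxes$y_max - boxes$y_min) / H)
  writeLines(lines, path)
  invisible(path)
}

.padEdge <- function(m, before, after, dim) {
  if (dim == 1L) {
    rbind(m[rep(1L, before), , drop = FALSE], m,
          m[rep(nrow(m), after), , drop = FALSE])
  } else {
    cbind(m[, rep(1L, before), drop = FALSE], m,
          m[, rep(ncol(m), after), drop = FALSE])
  }
}

#' Extract and resize one seed's multi-channel crop
#'
#' Cuts `box` out of the merged cube, pads the shorter side symmetrically
#' (edge replication) to a square, and bilinearly resizes every channel
#' identically to `outSize` x `outSize`. A crop already at the target square
#' size is returned pixel-identically. The default output side of 256 px is
#' the classifier's native input resolution.
#'
#' @param cube a [MergedCube-class] (or plain H x W x C array).
#' @param box one-row data.frame or named vector with x_min, y_min, x_max,
#'   y_max (0-based half-open).
#' @param outSize output side in pixels.
#' @return numeric array outSize x outSize x C.
#' @export
cropSeed <- function(cube, box, outSize = 256) {
  arr <- if (is(cube, "MergedCube")) cubeArray(cube) else cube
  stopifnot(length(dim(arr)) == 3L)
  bx <- unlist(box[c("x_min", "y_min", "x_max", "y_max")])
  if (anyNA(bx) || bx["x_min"] >= bx["x_max"] || bx["y_min"] >= bx["y_max"])
    stop("degenerate box: need x_min < x_max and y_min < y_max",
         call. = FALSE)
  if (bx["x_min"] < 0 || bx["y_min"] < 0 ||
      bx["x_max"] > dim(arr)[2] || bx["y_max"] > dim(arr)[1])
    stop("box exceeds image bounds", call. = FALSE)
  rows <- (bx["y_min"] + 1L):bx["y_max"]
  cols <- (bx["x_min"] + 1L):bx["x_max"]
  C <- dim(arr)[3]
  h <- length(rows); w <- length(cols)
  side <- max(h, w)
  out <- array(0, dim = c(outSize, outSize, C))
  for (ch in seq_len(C)) {
    m <- arr[rows, cols, ch, drop = TRUE]
    m <- matrix(m, h, w)
    if (h < side) m <- .padEdge(m, floor((side - h) / 2),
                                ceiling((side - h) / 2), 1L)
    if (w < side) m <- .padEdge(m, floor((side - w) / 2),
                                ceiling((side - w) / 2), 2L)
    if (side != outSize) {
      m <- EBImage::resize(EBImage::Image(m), w = outSize, h = outSize)
      m <- EBImage::imageData(m)
    }
    out[, , ch] <- m
  }
  out
}

#' Intersection-over-union of two boxes
#'
#' @param a,b boxes (x_min, y_min, x_max, y_max; 0-based half-open).
#' @return IoU in \[0, 1\].
#' @export
boxIoU <- function(a, b) {
  a <- unlist(a[c("x_min", "y_min", "x_max", "y_max")])
  b <- unlist(b[c("x_min", "y_min", "x_max", "y_max")])
  ix <- max(0, min(a["x_max"], b["x_max"]) - max(a["x_min"], b["x_min"]))
  iy <- max(0, min(a["y_max"], b["y_max"]) - max(a["y_min"], b["y_min"]))
  inter <- ix * iy
  areaA <- (a["x_max"] - a["x_min"]) * (a["y_max"] - a["y_min"])
  areaB <- (b["x_max"] - b["x_min"]) * (b["y_max"] - b["y_min"])
  unname(inter / (areaA + areaB - inter))
}
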