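# Dataset construction for germination prediction: per-seed records,
# dihedral augmentation, class-balanced sampling, and a by-seed train/test
# split with image accounting.

.rot90ccw <- function(m) t(m[, rev(seq_len(ncol(m))), drop = FALSE])
.mirrorLR <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]

.applyChannelwise <- function(crop, f) {
  out <- array(0, dim = dim(crop))
  for (ch in seq_len(dim(crop)[3])) out[, , ch] <- f(crop[, , ch])
  out
}

#' Dihedral-group augmentation of a square seed crop
#'
#' Returns the 8 dihedral variants (4 right-angle rotations x optional
#' left-right mirror) of a square multi-channel crop, original first, each
#' transform applied identically to every channel. Right-angle rotations and
#' mirrors permute pixels without interpolation, so per-channel histograms
#' are preserved exactly.
#'
#' @param crop numeric array S x S x C (a matrix is promoted).
#' @return named list of 8 arrays; names tag the transform
#'   (r0, r90, r180, r270, m0, m90, m180, m270; rotations counter-clockwise,
#'   mirror applied first).
#' @export
augmentCrop <- function(crop) {
  if (is.matrix(crop)) crop <- array(crop, dim = c(dim(crop), 1L))
  d <- dim(crop)
  if (length(d) != 3L || d[1] != d[2])
    stop("augmentation requires a square crop", call. = FALSE)
  rot <- function(m, k) { for (i in seq_len(k)) m <- .rot90ccw(m); m }
  out <- list()
  for (k in 0:3)
    out[[sprintf("r%d", 90 * k)]] <-
      .applyChannelwise(crop, function(m) rot(m, k))
  for (k in 0:3)
    out[[sprintf("m%d", 90 * k)]] <-
      .applyChannelwise(crop, function(m) rot(.mirrorLR(m), k))
  out
}

#' Uniform class-balanced seed sampling
#'
#' Samples exactly `nPerClass` distinct seeds per class, uniformly without
#' replacement; deterministic for a fixed `rngSeed`.
#'
#' @param records data.frame with at least `seed_id` and `label` (0/1).
#' @param nPerClass seeds to draw from each class.
#' @param rngSeed integer seed.
#' @return the sampled record rows (both classes interleaved in draw order).
#' @export
balancedSample <- function(records, nPerClass, rngSeed = 1L) {
  stopifnot(all(c("seed_id", "label") %in% names(records)))
  set.seed(as.integer(rngSeed))
  picks <- lapply(c(1L, 0L), function(cl) {
    ids <- unique(records$seed_id[records$label == cl])
    if (length(ids) < nPerClass)
      stop(sprintf(
        "class %d has only %d distinct seeds but %d were requested",
        cl, length(ids), nPerClass), call. = FALSE)
    if (nPerClass == 0L) character(0) else sample(ids, nPerClass)
  })
  out <- records[records$seed_id %in% unlist(picks), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Seed records of one dish scene
#'
#' Flattens a scene's ground truth into one manifest row per seed.
#'
#' @param stack a [SpectralStack-class].
#' @param truth the matching [GroundTruth-class].
#' @param variety variety tag carried into the records.
#' @return data.frame (seed_id, variety, label, dish_id, box coordinates).
#' @export
seedRecordsFromScene <- function(stack, truth, variety = "unknown") {
  bx <- truthBoxes(truth)
  n <- nrow(bx)
  if (n == 0L)
    return(data.frame(seed_id = character(0), variety = character(0),
                      label = integer(0), dish_id = character(0),
                      x_min = integer(0), y_min = integer(0),
                      x_max = integer(0), y_max = integer(0)))
  data.frame(seed_id = sprintf("%s-s%03d", dishId(stack), seq_len(n)),
             variety = variety, label = truthLabels(truth),
             dish_id = dishId(stack),
             x_min = bx$x_min, y_min = bx$y_min,
             x_max = bx$x_max, y_max = bx$y_max)
}

#' Split seed records into train and test sets, by seed
#'
#' Draws `trainSeeds` + `testSeeds` distinct seeds and partitions them so no
#' seed contributes images to both halves. The manifest reports both image
#' countings: single-band acquisition images (`imagesPerSeed` = B + 1 per
#' seed: B spectral bands plus the RGB image) and merged multi-channel cubes
#' (one per seed) — the classifier consumes one merged cube per seed while
#' acquisition counts enumerate single-band images.
#'
#' @param records per-seed record data.frame (see [seedRecordsFromScene()]).
#' @param trainSeeds,testSeeds seeds in each half.
#' @param rngSeed integer seed.
#' @param imagesPerSeed acquisition images per seed (default 20 = 19 + RGB).
#' @return a [DatasetSplit-class].
#' @export
buildSplit <- function(records, trainSeeds, testSeeds, rngSeed = 1L,
                       imagesPerSeed = 20L) {
  trainSeeds <- as.integer(trainSeeds)
  testSeeds <- as.integer(testSeeds)
  imagesPerSeed <- as.integer(imagesPerSeed)
  ids <- unique(records$seed_id)
  if (length(ids) < trainSeeds + testSeeds)
    stop(sprintf("need %d distinct seeds but only %d are available",
                 trainSeeds + testSeeds, length(ids)), call. = FALSE)
  set.seed(as.integer(rngSeed))
  pick <- sample(ids, trainSeeds + testSeeds)
  trainIds <- pick[seq_len(trainSeeds)]
  testIds <- pick[trainSeeds + seq_len(testSeeds)]
  tr <- records[records$seed_id %in% trainIds, , drop = FALSE]
  te <- records[records$seed_id %in% testIds, , drop = FALSE]
  rownames(tr) <- rownames(te) <- NULL
  manifest <- list(
    total_seeds = length(ids),
    total_images = length(ids) * imagesPerSeed,
    images_per_seed = imagesPerSeed,
    train_seeds = trainSeeds, test_seeds = testSeeds,
    train_images = trainSeeds * imagesPerSeed,
    test_images = testSeeds * imagesPerSeed,
    train_cubes = trainSeeds, test_cubes = testSeeds,
    rng_seed = as.integer(rngSeed))
  new("DatasetSplit", train = tr, test = te, manifest = manifest)
}

#' Write / read a dataset split manifest as CSV
#'
#' One row per seed record with its split assignment; the inverse
#' reconstructs a [DatasetSplit-class] (image accounting is recomputed).
#'
#' @param split a [DatasetSplit-class].
#' @param path CSV file path.
#' @param imagesPerSeed acquisition images per seed for the rebuilt
#'   manifest.
#' @return `writeDatasetManifest`: invisibly, `path`;
#'   `readDatasetManifest`: a [DatasetSplit-class].
#' @export
writeDatasetManifest <- function(split, path) {
  tr <- cbind(trainRecords(split), split = "train")
  te <- cbind(testRecords(split), split = "test")
  write.csv(rbind(tr, te), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDatasetManifest
#' @export
readDatasetManifest <- function(path, imagesPerSeed = 20L) {
  tab <- read.csv(path)
  tr <- tab[tab$split == "train", names(tab) != "split", drop = FALSE]
  te <- tab[tab$split == "test", names(tab) != "split", drop = FALSE]
  rownames(tr) <- rownames(te) <- NULL
  manifest <- list(
    total_seeds = length(unique(tab$seed_id)),
    total_images = length(unique(tab$seed_id)) * imagesPerSeed,
    images_per_seed = as.integer(imagesPerSeed),
    train_seeds = length(unique(tr$seed_id)),
    test_seeds = length(unique(te$seed_id)),
    train_images = length(unique(tr$seed_id)) * as.integer(imagesPerSeed),
    test_images = length(unique(te$seed_id)) * as.integer(imagesPerSeed),
    train_cubes = length(unique(tr$seed_id)),
    test_cubes = length(unique(te$seed_id)),
    rng_seed = NA_integer_)
  new("DatasetSplit", train = tr, test = te, manifest = manifest)
}

#' Write / read one seed crop as a multi-page TIFF
#'
#' Pages are the crop's channels in cube order (bands ascending, then
#' R, G, B), 16-bit.
#'
#' @param crop numeric array S x S x C in \[0, 1\].
#' @param path TIFF file path.
#' @return `writeCropTiff`: invisibly, `path`; `readCropTiff`: the array.
#' @export
writeCropTiff <- function(crop, path) {
  pages <- lapply(seq_len(dim(crop)[3]), function(ch) crop[, , ch])
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname writeCropTiff
#' @export
readCropTiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  array(unlist(pages, use.names = FALSE),
        dim = c(dim(pages[[1]])[1:2], length(pages)))
}

#' Materialise per-seed crop tensors for a split
#'
#' Extracts (and resizes to `outSize`) the merged-cube crop of every record
#' in the split from the supplying stacks. Training records can be expanded
#' by the 8 dihedral augmentation variants; test records never are.
#'
#' @param split a [DatasetSplit-class].
#' @param stacks named list of [SpectralStack-class] keyed by dish_id.
#' @param outSize crop side in pixels.
#' @param augmentTrain expand training crops by [augmentCrop()].
#' @return list with `train` and `test`, each holding `x` (array
#'   S x S x C x n), `y` (integer labels) and `seed_id`.
#' @export
materializeCrops <- function(split, stacks, outSize = 256,
                             augmentTrain = FALSE) {
  cubes <- lapply(stacks, mergeChannels)
  half <- function(recs, augment) {
    crops <- list(); ys <- integer(0); ids <- character(0)
    for (r in seq_len(nrow(recs))) {
      rec <- recs[r, ]
      cube <- cubes[[rec$dish_id]]
      if (is.null(cube))
        stop(sprintf("no stack supplied for dish '%s'", rec$dish_id),
             call. = FALSE)
      cr <- cropSeed(cube, rec, outSize = outSize)
      if (augment) {
        av <- augmentCrop(cr)
        crops <- c(crops, av)
        ys <- c(ys, rep(rec$label, length(av)))
        ids <- c(ids, rep(rec$seed_id, length(av)))
      } else {
        crops[[length(crops) + 1L]] <- cr
        ys <- c(ys, rec$label)
        ids <- c(ids, rec$seed_id)
      }
    }
    C <- if (length(crops) > 0) dim(crops[[1]])[3] else 0L
    x <- array(unlist(crops, use.names = FALSE),
               dim = c(outSize, outSize, C, length(crops)))
    list(x = x, y = as.integer(ys), seed_id = ids)
  }
  list(train = half(split@train, augmentTrain),
       test = half(split@test, FALSE))
}
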