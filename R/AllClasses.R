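#' @import methods
#' @importFrom stats cor rnorm runif sd var quantile setNames
#' @importFrom utils head tail read.csv write.csv
NULL

#' SpectralStack: one multispectral dish acquisition
#'
#' Holds the co-registered single-band reflectance images of one petri-dish
#' acquisition together with the instrument's RGB preview. Band images share
#' one geometry; reflectance is stored as floating point in \[0, 1\] (integer
#' pixel encodings are scaled by their maximum representable value on read).
#'
#' @slot bands numeric array H x W x B of reflectance in \[0, 1\], bands in
#'   ascending wavelength order.
#' @slot wavelengths numeric vector of B wavelengths in nm, strictly increasing.
#' @slot rgb numeric array H x W x 3 in \[0, 1\].
#' @slot dishId character scalar identifying the acquisition.
#'
#' @seealso [readStack()], [mergeChannels()], [meanSpectrum()]
#' @export
setClass("SpectralStack",
  representation(
    bands = "array",
    wavelengths = "numeric",
    rgb = "array",
    dishId = "character"
  )
)

setValidity("SpectralStack", function(object) {
  b <- object@bands
  if (length(dim(b)) != 3L) return("'bands' must be an H x W x B array")
  if (dim(b)[3] < 1L) return("need at least one band (B >= 1)")
  if (length(object@wavelengths) != dim(b)[3])
    return(sprintf("wavelength count (%d) != band count (%d)",
                   length(object@wavelengths), dim(b)[3]))
  if (any(diff(object@wavelengths) <= 0))
    return("wavelengths must be strictly increasing")
  if (length(dim(object@rgb)) != 3L || dim(object@rgb)[3] != 3L)
    return("'rgb' must be an H x W x 3 array")
  if (!all(dim(object@rgb)[1:2] == dim(b)[1:2]))
    return("rgb image dimensions differ from band dimensions")
  if (!all(is.finite(b)) || !all(is.finite(object@rgb)))
    return("pixel values must be finite")
  if (min(b) < 0 || max(b) > 1 || min(object@rgb) < 0 || max(object@rgb) > 1)
    return("pixel values must lie in [0, 1] after normalization")
  if (length(object@dishId) != 1L) return("'dishId' must be a single string")
  TRUE
})

#' MergedCube: per-dish multi-channel data cube
#'
#' The B spectral bands (ascending wavelength) followed by the R, G, B
#' channels of the RGB image, so C = B + 3. This fixed channel order is the
#' input layout the germination classifier consumes (22 channels for the
#' canonical 19-band instrument).
#'
#' @slot cube numeric array H x W x C.
#' @slot channelNames character vector of C channel names.
#' @export
setClass("MergedCube",
  representation(cube = "array", channelNames = "character")
)

setValidity("MergedCube", function(object) {
  if (length(dim(object@cube)) != 3L) return("'cube' must be H x W x C")
  if (length(object@channelNames) != dim(object@cube)[3])
    return("channelNames length != channel count")
  TRUE
})

#' GroundTruth: per-seed annotation of a (synthetic) dish scene
#'
#' Boxes use 0-based half-open pixel coordinates (x along columns, y along
#' rows). Masks are stored cropped to each seed's box, so the i-th mask is a
#' logical matrix of dimension (y_max - y_min) x (x_max - x_min) and each box
#' is exactly the bounding box of its mask.
#'
#' @slot boxes data.frame with integer columns x_min, y_min, x_max, y_max.
#' @slot labels integer vector, 1 = germinated / non-aged, 0 = non-germinated.
#' @slot masks list of logical matrices, one per seed, cropped to the box.
#' @export
setClass("GroundTruth",
  representation(boxes = "data.frame", labels = "integer", masks = "list")
)

setValidity("GroundTruth", function(object) {
  n <- nrow(object@boxes)
  need <- c("x_min", "y_min", "x_max", "y_max")
  if (!all(need %in% names(object@boxes)))
    return("boxes must have columns x_min, y_min, x_max, y_max")
  if (length(object@labels) != n || length(object@masks) != n)
    return("boxes, labels and masks must have equal length")
  if (n > 0 && !all(object@labels %in% c(0L, 1L)))
    return("labels must be binary (0/1)")
  TRUE
})

#' MsiFormerConfig: architecture description of the germination classifier
#'
#' Defaults reproduce the published stage trajectory: a 256 x 256 x 22 input
#' reduced by five convolutional stages (widths 64, 256, 512, 1024, 2048 and
#' strides 4, 1, 2, 2, 2) to an 8 x 8 x 2048 feature map, five linear-attention
#' transformer layers that preserve that shape, a full-extent convolution head
#' to 1 x 1 x 2048, and a fully connected softmax classifier over 2 classes.
#'
#' @slot inChannels integer, input channel count (22 = 19 bands + RGB).
#' @slot inputSize integer, square input side in pixels.
#' @slot stageChannels integer vector of per-stage output widths (ascending).
#' @slot stageStrides integer vector of per-stage spatial strides.
#' @slot attentionLayers integer, number of linear-attention layers.
#' @slot nClasses integer, output classes (2: germinated / non-germinated).
#' @slot featureDim integer, feature width after the head (= last stage width).
#' @slot blocksPerStage integer, residual bottleneck blocks per stage.
#' @export
setClass("MsiFormerConfig",
  representation(
    inChannels = "integer", inputSize = "integer",
    stageChannels = "integer", stageStrides = "integer",
    attentionLayers = "integer", nClasses = "integer",
    featureDim = "integer", blocksPerStage = "integer"
  )
)

setValidity("MsiFormerConfig", function(object) {
  if (length(object@stageChannels) != length(object@stageStrides))
    return("stageChannels and stageStrides must have equal length")
  if (any(diff(object@stageChannels) < 0))
    return("stageChannels must be ascending")
  tot <- prod(object@stageStrides)
  if (object@inputSize %% tot != 0)
    return(sprintf("inputSize (%d) not divisible by product of strides (%d)",
                   object@inputSize, tot))
  if (object@featureDim != tail(object@stageChannels, 1L))
    return("featureDim must equal the last stage width")
  if (object@attentionLayers < 0L) return("attentionLayers must be >= 0")
  if (object@nClasses < 2L) return("need at least 2 classes")
  TRUE
})

#' MsiFormerModel: a parameterised (possibly trained) classifier
#'
#' @slot config the [MsiFormerConfig-class] the parameters realise.
#' @slot params named list of layer parameter arrays.
#' @slot trained logical, whether [trainMsiFormer()] has updated the weights.
#' @slot trainingLog data.frame of per-epoch loss (empty before training).
#' @export
setClass("MsiFormerModel",
  representation(
    config = "MsiFormerConfig", params = "list",
    trained = "logical", trainingLog = "data.frame"
  )
)

#' ConfusionCounts: TP/TN/FP/FN tallies
#'
#' @slot tp,tn,fp,fn nonnegative integer counts.
#' @export
setClass("ConfusionCounts",
  representation(tp = "integer", tn = "integer", fp = "integer", fn = "integer")
)

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@tn, object@fp, object@fn)
  if (any(v < 0)) return("counts must be nonnegative")
  if (sum(v) < 1) return("at least one prediction is required")
  TRUE
})

#' MetricsReport: the six confusion-derived rates, in percent
#'
#' Accuracy, precision, true/false positive rate and true/false negative rate
#' derived from a [ConfusionCounts-class]. A metric whose denominator is zero
#' is reported as NA. Values are kept at full precision; display rounds
#' half-up to 2 decimals.
#'
#' @slot acc,precision,tpr,fpr,tnr,fnr numeric percentages in \[0, 100\] or NA.
#' @export
setClass("MetricsReport",
  representation(
    acc = "numeric", precision = "numeric", tpr = "numeric",
    fpr = "numeric", tnr = "numeric", fnr = "numeric"
  )
)

#' RocCurve: receiver operating characteristic with trapezoid AUC
#'
#' @slot thresholds score thresholds in decreasing order (with +Inf first).
#' @slot tpr,fpr operating points; both start at 0 and end at 1.
#' @slot auc area under the curve by the trapezoid rule.
#' @export
setClass("RocCurve",
  representation(
    thresholds = "numeric", tpr = "numeric", fpr = "numeric", auc = "numeric"
  )
)

setValidity("RocCurve", function(object) {
  n <- length(object@fpr)
  if (length(object@tpr) != n || length(object@thresholds) != n)
    return("thresholds, tpr and fpr must have equal length")
  if (is.unsorted(object@fpr)) return("fpr points must be nondecreasing")
  TRUE
})

#' NcdaModel: fitted normalized canonical discriminant axis
#'
#' The first canonical axis of a (regularized) Fisher discriminant over
#' per-pixel spectra, together with the training projection range used to
#' normalize transformed scores into \[-1, 1\].
#'
#' @slot weights numeric vector of B band weights.
#' @slot intercept numeric scalar subtracted before projection (grand mean
#'   offset so training scores are centred).
#' @slot scoreRange numeric (lo, hi) of training projections.
#' @slot classMeans matrix of per-class mean spectra (classes x B).
#' @slot classes sorted unique class labels the model was fitted on.
#' @export
setClass("NcdaModel",
  representation(
    weights = "numeric", intercept = "numeric", scoreRange = "numeric",
    classMeans = "matrix", classes = "numeric"
  )
)

setValidity("NcdaModel", function(object) {
  if (!all(is.finite(object@weights)) || all(object@weights == 0))
    return("weights must be finite and not all zero")
  if (length(object@scoreRange) != 2L ||
      object@scoreRange[1] >= object@scoreRange[2])
    return("scoreRange must be (lo, hi) with lo < hi")
  TRUE
})

#' DatasetSplit: per-seed train/test partition with manifest
#'
#' Records are manifest rows (one per seed with its provenance, label and
#' box); pixel tensors are materialised on demand with [materializeCrops()].
#' The partition is by seed: no seed_id ever appears in both halves.
#'
#' @slot train,test data.frames of seed records.
#' @slot manifest list of image-accounting counts (seeds, images per seed,
#'   single-band image totals, merged-cube totals).
#' @export
setClass("DatasetSplit",
  representation(train = "data.frame", test = "data.frame", manifest = "list")
)

setValidity("DatasetSplit", function(object) {
  both <- intersect(object@train$seed_id, object@test$seed_id)
  if (length(both) > 0)
    return(sprintf("seed(s) in both train and test: %s",
                   paste(head(both, 3), collapse = ", ")))
  TRUE
})
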