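#' @describeIn SpectralStack-class band array accessor (H x W x B)
#' @param x object
#' @export
setGeneric("bands", function(x) standardGeneric("bands"))

#' @describeIn SpectralStack-class wavelength vector accessor (nm)
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @describeIn SpectralStack-class RGB image accessor (H x W x 3)
#' @export
setGeneric("rgbImage", function(x) standardGeneric("rgbImage"))

#' @describeIn SpectralStack-class dish identifier accessor
#' @export
setGeneric("dishId", function(x) standardGeneric("dishId"))

#' @describeIn SpectralStack-class number of spectral bands
#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))

#' @describeIn MergedCube-class cube array accessor (H x W x C)
#' @param x object
#' @export
setGeneric("cubeArray", function(x) standardGeneric("cubeArray"))

#' @describeIn MergedCube-class channel name accessor
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @describeIn GroundTruth-class bounding-box data.frame accessor
#' @param x object
#' @export
setGeneric("truthBoxes", function(x) standardGeneric("truthBoxes"))

#' @describeIn GroundTruth-class per-seed binary label accessor
#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))

#' @describeIn GroundTruth-class per-seed (box-cropped) mask accessor
#' @export
setGeneric("truthMasks", function(x) standardGeneric("truthMasks"))

#' @describeIn ConfusionCounts-class named count vector (tp, tn, fp, fn)
#' @param x object
#' @export
setGeneric("confusionVector", function(x) standardGeneric("confusionVector"))

#' @describeIn MetricsReport-class named percent vector of the six metrics
#' @param x object
#' @export
setGeneric("metricsVector", function(x) standardGeneric("metricsVector"))

#' @describeIn RocCurve-class area under the ROC curve
#' @param x object
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

#' @describeIn DatasetSplit-class training-record accessor
#' @param x object
#' @export
setGeneric("trainRecords", function(x) standardGeneric("trainRecords"))

#' @describeIn DatasetSplit-class test-record accessor
#' @export
setGeneric("testRecords", function(x) standardGeneric("testRecords"))

#' @describeIn DatasetSplit-class image-accounting manifest accessor
#' @export
setGeneric("splitManifest", function(x) standardGeneric("splitManifest"))

setMethod("bands", "SpectralStack", function(x) x@bands)
setMethod("wavelengths", "SpectralStack", function(x) x@wavelengths)
setMethod("rgbImage", "SpectralStack", function(x) x@rgb)
setMethod("dishId", "SpectralStack", function(x) x@dishId)
setMethod("nBands", "SpectralStack", function(x) dim(x@bands)[3])

setMethod("cubeArray", "MergedCube", function(x) x@cube)
setMethod("channelNames", "MergedCube", function(x) x@channelNames)

setMethod("truthBoxes", "GroundTruth", function(x) x@boxes)
setMethod("truthLabels", "GroundTruth", function(x) x@labels)
setMethod("truthMasks", "GroundTruth", function(x) x@masks)

setMethod("confusionVector", "ConfusionCounts", function(x)
  c(tp = x@tp, tn = x@tn, fp = x@fp, fn = x@fn))

setMethod("metricsVector", "MetricsReport", function(x)
  c(acc = x@acc, precision = x@precision, tpr = x@tpr,
    fpr = x@fpr, tnr = x@tnr, fnr = x@fnr))

setMethod("auc", "RocCurve", function(x) x@auc)

setMethod("trainRecords", "DatasetSplit", function(x) x@train)
setMethod("testRecords", "DatasetSplit", function(x) x@test)
setMethod("splitManifest", "DatasetSplit", function(x) x@manifest)

setMethod("show", "SpectralStack", function(object) {
  d <- dim(object@bands)
  cat(sprintf("SpectralStack '%s': %d x %d pixels, %d bands (%g-%g nm) + RGB\n",
              object@dishId, d[1], d[2], d[3],
              min(object@wavelengths), max(object@wavelengths)))
})

setMethod("show", "MergedCube", function(object) {
  d <- dim(object@cube)
  cat(sprintf("MergedCube: %d x %d x %d channels [%s, ...]\n",
              d[1], d[2], d[3], paste(head(object@channelNames, 3),
                                      collapse = ", ")))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d seeds (%d germinated, %d non-germinated)\n",
              nrow(object@boxes), sum(object@labels == 1L),
              sum(object@labels == 0L)))
})

setMethod("show", "MsiFormerConfig", function(object) {
  cat(sprintf(
    "MsiFormerConfig: %d x %d x %d input -> stages [%s] (strides [%s]) -> %d attention layer(s) -> %d features -> %d classes\n",
    object@inputSize, object@inputSize, object@inChannels,
    paste(object@stageChannels, collapse = ","),
    paste(object@stageStrides, collapse = ","),
    object@attentionLayers, object@featureDim, object@nClasses))
})

setMethod("show", "MsiFormerModel", function(object) {
  np <- sum(vapply(object@params, function(p) length(unlist(p)), numeric(1)))
  cat(sprintf("MsiFormerModel (%s): %s parameters\n",
              if (object@trained) "trained" else "untrained",
              format(np, big.mark = ",")))
  show(object@config)
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%d TN=%d FP=%d FN=%d (n=%d)\n",
              object@tp, object@tn, object@fp, object@fn,
              object@tp + object@tn + object@fp + object@fn))
})

setMethod("show", "MetricsReport", function(object) {
  v <- roundHalfUp(metricsVector(object), 2)
  cat(sprintf(
    "MetricsReport: ACC %.2f  Precision %.2f  TPR %.2f  FPR %.2f  TNR %.2f  FNR %.2f (percent)\n",
    v["acc"], v["precision"], v["tpr"], v["fpr"], v["tnr"], v["fnr"]))
})

setMethod("show", "RocCurve", function(object) {
  cat(sprintf("RocCurve: %d operating points, AUC = %.4f\n",
              length(object@fpr), object@auc))
})

setMethod("show", "NcdaModel", function(object) {
  cat(sprintf("NcdaModel: %d bands, %d classes, score range [%.4g, %.4g]\n",
              length(object@weights), nrow(object@classMeans),
              object@scoreRange[1], object@scoreRange[2]))
})

setMethod("show", "DatasetSplit", function(object) {
  m <- object@manifest
  cat(sprintf(
    "DatasetSplit: %d train / %d test seeds (%d / %d single-band images)\n",
    nrow(object@train), nrow(object@test),
    m$train_images, m$test_images))
})
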