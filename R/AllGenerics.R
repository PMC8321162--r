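#' Pixel array of a patch
#' @param x an [RGBPatch] or [SyntheticPhantom].
#' @return `H x W x 3` numeric array in \[0, 255\].
#' @export
setGeneric("pixelArray", function(x) standardGeneric("pixelArray"))

#' @rdname pixelArray
setMethod("pixelArray", "RGBPatch", function(x) x@pixels)

#' @rdname pixelArray
setMethod("pixelArray", "SyntheticPhantom", function(x) x@patch@pixels)

#' Label matrix of a segmentation
#' @param x a [NucleiLabelMap] or [SyntheticPhantom].
#' @return integer `H x W` matrix, 0 = background.
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @rdname labelMatrix
setMethod("labelMatrix", "NucleiLabelMap", function(x) x@labels)

#' @rdname labelMatrix
setMethod("labelMatrix", "SyntheticPhantom", function(x) x@labels@labels)

#' Number of nuclei
#' @param x a [NucleiLabelMap] or [SyntheticPhantom].
#' @return integer count.
#' @export
setGeneric("nNuclei", function(x) standardGeneric("nNuclei"))

#' @rdname nNuclei
setMethod("nNuclei", "NucleiLabelMap", function(x) x@nNuclei)

#' @rdname nNuclei
setMethod("nNuclei", "SyntheticPhantom", function(x) x@labels@nNuclei)

#' Plane mask of a colour separation
#' @param x a [ColorPlaneSet].
#' @param plane one of `"pink"`, `"blue"`, `"background"`.
#' @return logical `H x W` mask.
#' @export
setGeneric("planeMask", function(x, plane) standardGeneric("planeMask"))

#' @rdname planeMask
setMethod("planeMask", "ColorPlaneSet", function(x, plane) {
  switch(match.arg(plane, c("pink", "blue", "background")),
         pink = x@ipMask, blue = x@ibMask, background = x@ibaMask)
})

#' HSV channels as an array
#' @param x an [HSVImage].
#' @return `H x W x 3` array with channels h, s, v.
#' @export
setGeneric("hsvArray", function(x) standardGeneric("hsvArray"))

#' @rdname hsvArray
setMethod("hsvArray", "HSVImage", function(x) {
  a <- array(0, c(dim(x@h), 3), dimnames = list(NULL, NULL, c("h", "s", "v")))
  a[, , 1] <- x@h; a[, , 2] <- x@s; a[, , 3] <- x@v
  a
})

#' Estimated or planted tumour cellularity
#' @param x a [CellularityResult] or [SyntheticPhantom].
#' @return numeric TC in \[0, 1\].
#' @export
setGeneric("tcValue", function(x) standardGeneric("tcValue"))

#' @rdname tcValue
setMethod("tcValue", "CellularityResult", function(x) x@tc)

#' @rdname tcValue
setMethod("tcValue", "SyntheticPhantom", function(x) x@trueTC)

#' Dilated malignant-cell mask of a cellularity result
#' @param x a [CellularityResult].
#' @return logical `H x W` mask.
#' @export
setGeneric("malignantMask", function(x) standardGeneric("malignantMask"))

#' @rdname malignantMask
setMethod("malignantMask", "CellularityResult", function(x) x@malignantMask)

#' Ground-truth nucleus classes of a phantom
#' @param x a [SyntheticPhantom].
#' @return character vector, one `"benign"`/`"malignant"` per label.
#' @export
setGeneric("nucleusClasses", function(x) standardGeneric("nucleusClasses"))

#' @rdname nucleusClasses
setMethod("nucleusClasses", "SyntheticPhantom", function(x) x@classes)

setMethod("show", "RGBPatch", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("RGBPatch: %d x %d px, %.2f um/px\n", d[1], d[2],
              object@pixelSize))
})

setMethod("show", "ColorPlaneSet", function(object) {
  cat(sprintf(
    "ColorPlaneSet: pink %.1f%%, blue %.1f%%, background %.1f%%\n",
    100 * mean(object@ipMask), 100 * mean(object@ibMask),
    100 * mean(object@ibaMask)))
})

setMethod("show", "NucleiLabelMap", function(object) {
  cat(sprintf("NucleiLabelMap: %d nuclei over %d x %d px\n",
              object@nNuclei, nrow(object@labels), ncol(object@labels)))
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult: %d of %d features kept (levels: %s)\n",
              object@nSelected, nrow(object@perFeature),
              paste(object@tcLevels, collapse = ", ")))
})

setMethod("show", "ClassifierModel", function(object) {
  cat(sprintf("ClassifierModel <%s>: %d features, seed %d\n",
              object@algorithm, length(object@manifest), object@seed))
  if (!is.null(object@metrics$accuracy))
    cat(sprintf("  training accuracy %.3f, TPR %.3f, AUC %.3f\n",
                object@metrics$accuracy, object@metrics$tpr,
                object@metrics$auc))
})

setMethod("show", "CellularityResult", function(object) {
  cat(sprintf("CellularityResult '%s': TC = %.4f (%s/%s nuclei malignant)\n",
              object@patchId, object@tc,
              ifelse(is.na(object@nMalignant), "?", object@nMalignant),
              ifelse(is.na(object@nNuclei), "?", object@nNuclei)))
})

setMethod("show", "SyntheticPhantom", function(object) {
  cat(sprintf(
    "SyntheticPhantom: %d x %d px, %d nuclei (%d malignant), true TC %.4f\n",
    nrow(object@ductLabels), ncol(object@ductLabels), object@labels@nNuclei,
    sum(object@classes == "malignant"), object@trueTC))
})
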