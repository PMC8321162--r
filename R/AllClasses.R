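#' @import methods
#' @importFrom stats kmeans cor cov var sd coef predict rnorm runif quantile
#'   aggregate qf lm
#' @importFrom utils write.csv read.csv modifyList head tail
NULL

#' RGBPatch: one H&E image patch
#'
#' Container for a single RGB histology patch. Pixels are stored as an
#' `H x W x 3` numeric array of 8-bit intensities (0--255), row = y,
#' column = x. The default pixel size of 0.5 um/px corresponds to 20x
#' magnification, the scale all pixel-unit defaults in this package
#' (window sizes, dilation radii, area cut-offs) are expressed in.
#'
#' @slot pixels numeric array, `H x W x 3`, values in \[0, 255\].
#' @slot pixelSize numeric, physical size of one pixel in micrometres.
#' @export
setClass("RGBPatch",
  representation(pixels = "array", pixelSize = "numeric"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (length(d) != 3 || d[3] != 3)
      return("pixels must be an H x W x 3 array")
    if (d[1] < 32 || d[2] < 32)
      return("patch must be at least 32 x 32 pixels")
    if (anyNA(object@pixels) ||
        min(object@pixels) < 0 || max(object@pixels) > 255)
      return("intensities must lie in [0, 255]")
    if (length(object@pixelSize) != 1 || object@pixelSize <= 0)
      return("pixelSize must be a single positive number")
    TRUE
  })

#' @describeIn RGBPatch constructor.
#' @param pixels `H x W x 3` numeric array of intensities in \[0, 255\].
#' @param pixelSize pixel size in um/px (default 0.5, i.e. 20x).
#' @export
RGBPatch <- function(pixels, pixelSize = 0.5) {
  storage.mode(pixels) <- "double"
  new("RGBPatch", pixels = pixels, pixelSize = pixelSize)
}

#' HSVImage: per-channel HSV planes of a patch
#'
#' Hue, saturation and value planes of an [RGBPatch], each an `H x W`
#' matrix scaled to \[0, 1\] (hue as a fraction of the full circle).
#'
#' @slot h,s,v numeric matrices in \[0, 1\].
#' @export
setClass("HSVImage",
  representation(h = "matrix", s = "matrix", v = "matrix"),
  validity = function(object) {
    dh <- dim(object@h)
    if (!identical(dh, dim(object@s)) || !identical(dh, dim(object@v)))
      return("h, s, v must share dimensions")
    rng <- range(object@h, object@s, object@v)
    if (anyNA(rng) || rng[1] < 0 || rng[2] > 1)
      return("all HSV values must lie in [0, 1]")
    TRUE
  })

#' ColorPlaneSet: K-means colour separation of a patch
#'
#' The three colour component images obtained by clustering HSV pixel
#' triples: `Ip` (pink / stroma), `Ib` (blue / nuclei) and `Iba`
#' (background). The boolean masks partition the patch: every pixel
#' belongs to exactly one plane.
#'
#' @slot ipImage,ibImage,ibaImage `H x W x 3` arrays holding the patch
#'   pixels of the respective cluster and zero elsewhere.
#' @slot ipMask,ibMask,ibaMask logical `H x W` masks, pairwise disjoint,
#'   jointly covering the patch.
#' @slot centers 3 x 3 numeric matrix of HSV cluster centroids, rows named
#'   `pink`, `blue`, `background`.
#' @export
setClass("ColorPlaneSet",
  representation(ipImage = "array", ibImage = "array", ibaImage = "array",
                 ipMask = "matrix", ibMask = "matrix", ibaMask = "matrix",
                 centers = "matrix"),
  validity = function(object) {
    cover <- object@ipMask + object@ibMask + object@ibaMask
    if (any(cover != 1))
      return("masks must partition the image (exactly one TRUE per pixel)")
    if (!all(rownames(object@centers) %in% c("pink", "blue", "background")))
      return("centers rows must be named pink/blue/background")
    TRUE
  })

#' EnhancedImage: nuclei-enhanced grayscale planes
#'
#' Result of the nuclei enhancement step. `inPixels` is the enhanced
#' image In = (K1 * Io * Im + K2 * Io + Im^gamma) / (K1 + K2 + 1) on
#' \[0, 1\] intensities; `ioPixels` the luminance grayscale Io and
#' `imPixels` its median-filtered version Im.
#'
#' @slot inPixels,ioPixels,imPixels numeric `H x W` matrices in \[0, 1\].
#' @export
setClass("EnhancedImage",
  representation(inPixels = "matrix", ioPixels = "matrix",
                 imPixels = "matrix"),
  validity = function(object) {
    if (!identical(dim(object@inPixels), dim(object@ioPixels)) ||
        !identical(dim(object@inPixels), dim(object@imPixels)))
      return("planes must share dimensions")
    rng <- range(object@inPixels)
    if (rng[1] < 0 || rng[2] > 1) return("inPixels must lie in [0, 1]")
    TRUE
  })

#' NucleiLabelMap: labelled segmented nuclei
#'
#' Integer label image of segmented nuclei: 0 is background, labels
#' 1..n are individual nuclei, numbered consecutively.
#'
#' @slot labels integer `H x W` matrix.
#' @slot nNuclei integer, the number of labelled nuclei.
#' @export
setClass("NucleiLabelMap",
  representation(labels = "matrix", nNuclei = "integer"),
  validity = function(object) {
    u <- sort(unique(as.integer(object@labels)))
    u <- u[u != 0]
    if (length(u) != object@nNuclei)
      return("nNuclei must equal the number of distinct non-zero labels")
    if (object@nNuclei > 0 && !identical(u, seq_len(object@nNuclei)))
      return("labels must be consecutive 1..n")
    TRUE
  })

#' @describeIn NucleiLabelMap constructor (renumbers labels consecutively).
#' @param labels integer `H x W` matrix, 0 = background.
#' @export
NucleiLabelMap <- function(labels) {
  storage.mode(labels) <- "integer"
  u <- sort(unique(as.integer(labels)))
  u <- u[u != 0]
  if (length(u) > 0 && !identical(u, seq_along(u))) {
    relab <- integer(max(u))
    relab[u] <- seq_along(u)
    pos <- labels != 0L
    labels[pos] <- relab[labels[pos]]
  }
  new("NucleiLabelMap", labels = labels, nNuclei = length(u))
}

#' SelectionResult: outcome of key-parameter selection
#'
#' @slot perFeature data.frame with columns `feature`, `r`, `slope`,
#'   `lasso`, `kept`, ordered by decreasing `|r|`.
#' @slot tcLevels numeric vector of cellularity levels used.
#' @slot nSelected integer count of kept features.
#' @export
setClass("SelectionResult",
  representation(perFeature = "data.frame", tcLevels = "numeric",
                 nSelected = "integer"),
  validity = function(object) {
    need <- c("feature", "r", "slope", "lasso", "kept")
    if (!all(need %in% names(object@perFeature)))
      return("perFeature must have feature/r/slope/lasso/kept columns")
    if (object@nSelected != sum(object@perFeature$kept))
      return("nSelected must equal the number of kept features")
    if (any(abs(object@perFeature$r) > 1 + 1e-12))
      return("|r| must not exceed 1")
    TRUE
  })

#' ClassifierModel: fitted benign/malignant nucleus classifier
#'
#' @slot algorithm one of `"svm"`, `"knn"`, `"adaboost"`.
#' @slot manifest ordered character vector of feature-column names the
#'   model consumes (default: the canonical 22-parameter set).
#' @slot fit opaque fitted state.
#' @slot center,scale per-feature standardisation statistics.
#' @slot seed integer training seed.
#' @slot metrics list of training metrics (accuracy, TPR, AUC, CV accuracy).
#' @export
setClass("ClassifierModel",
  representation(algorithm = "character", manifest = "character",
                 fit = "ANY", center = "numeric", scale = "numeric",
                 seed = "integer", metrics = "list"),
  validity = function(object) {
    if (!object@algorithm %in% c("svm", "knn", "adaboost"))
      return("algorithm must be svm, knn or adaboost")
    if (length(object@center) != length(object@manifest) ||
        length(object@scale) != length(object@manifest))
      return("center/scale must match the manifest length")
    TRUE
  })

#' CellularityResult: patch-level tumour cellularity
#'
#' TC is the fraction of patch area covered by the malignant-cell mask
#' (malignant nuclei dilated by a disc approximating cytoplasm). The
#' stored mask is the dilated one, so `tc == mean(malignantMask)` exactly.
#'
#' @slot patchId character identifier.
#' @slot tc numeric in \[0, 1\].
#' @slot nNuclei,nMalignant integer counts (NA for mask-only results).
#' @slot malignantMask logical `H x W` dilated malignant mask.
#' @slot dilationRadius numeric, disc radius in pixels.
#' @export
setClass("CellularityResult",
  representation(patchId = "character", tc = "numeric",
                 nNuclei = "integer", nMalignant = "integer",
                 malignantMask = "matrix", dilationRadius = "numeric"),
  validity = function(object) {
    if (object@tc < 0 || object@tc > 1) return("tc must lie in [0, 1]")
    if (!is.na(object@nNuclei) && !is.na(object@nMalignant) &&
        object@nMalignant > object@nNuclei)
      return("nMalignant cannot exceed nNuclei")
    if (abs(mean(object@malignantMask) - object@tc) > 1e-12)
      return("tc must equal the true-pixel fraction of malignantMask")
    TRUE
  })

#' PhantomSpec: parameters of the synthetic H&E phantom generator
#'
#' Describes one synthetic patch: pink textured stroma, white fat blobs,
#' blue elliptical nuclei (benign small and round, malignant larger,
#' eccentric, with irregular boundaries) and optional duct clusters of
#' packed nuclei. All geometry is in pixels at the default 0.5 um/px.
#'
#' @slot size patch side in pixels.
#' @slot nBenign,nMalignant nucleus counts.
#' @slot benignRadius,malignantRadius length-2 semi-major-axis ranges (px).
#' @slot benignEccentricity,malignantEccentricity length-2 ranges.
#' @slot nDucts number of duct clusters.
#' @slot ductCells length-2 range of nuclei per duct.
#' @slot stromaColor,nucleusColor,fatColor RGB triples in \[0, 255\].
#' @slot colorJitterSd per-structure colour jitter SD (intensity units).
#' @slot fatFraction target area fraction of fat.
#' @slot noiseSd global Gaussian pixel noise SD (intensity units).
#' @slot dilationRadius cytoplasm dilation radius used for the planted TC.
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomSpec",
  representation(size = "integer", nBenign = "integer", nMalignant = "integer",
                 benignRadius = "numeric", malignantRadius = "numeric",
                 benignEccentricity = "numeric",
                 malignantEccentricity = "numeric",
                 nDucts = "integer", ductCells = "numeric",
                 stromaColor = "numeric", nucleusColor = "numeric",
                 fatColor = "numeric", colorJitterSd = "numeric",
                 fatFraction = "numeric", noiseSd = "numeric",
                 dilationRadius = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@size < 64) return("size must be at least 64 px")
    if (object@nBenign < 0 || object@nMalignant < 0 || object@nDucts < 0)
      return("counts must be non-negative")
    if (min(object@benignRadius) < 3 || min(object@malignantRadius) < 3)
      return("nucleus radii must be at least 3 px")
    for (col in list(object@stromaColor, object@nucleusColor,
                     object@fatColor))
      if (length(col) != 3 || min(col) < 0 || max(col) > 255)
        return("colours must be RGB triples in [0, 255]")
    if (object@fatFraction < 0 || object@fatFraction > 1)
      return("fatFraction must lie in [0, 1]")
    TRUE
  })

#' SyntheticPhantom: generated patch plus pixel-exact ground truth
#'
#' @slot patch the rendered [RGBPatch].
#' @slot labels ground-truth [NucleiLabelMap] of planted nuclei.
#' @slot classes character vector (`"benign"`/`"malignant"`), one per label.
#' @slot ductLabels integer `H x W` map of duct regions (0 = none).
#' @slot trueTC planted tumour cellularity, computed from the malignant
#'   masks with [computeTCFromMasks()] at the spec's dilation radius.
#' @slot spec the generating [PhantomSpec].
#' @export
setClass("SyntheticPhantom",
  representation(patch = "RGBPatch", labels = "NucleiLabelMap",
                 classes = "character", ductLabels = "matrix",
                 trueTC = "numeric", spec = "PhantomSpec"),
  validity = function(object) {
    if (length(object@classes) != object@labels@nNuclei)
      return("classes length must equal the number of planted nuclei")
    if (!all(object@classes %in% c("benign", "malignant")))
      return("classes must be benign or malignant")
    if (object@trueTC < 0 || object@trueTC > 1)
      return("trueTC must lie in [0, 1]")
    TRUE
  })
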