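#' Default pipeline configuration
#'
#' Nested list of every tunable parameter of the pipeline, in pixel
#' units at 0.5 um/px. Override individual entries by passing a
#' modified copy, or load overrides from YAML with [readConfig()].
#'
#' @return nested named list.
#' @export
defaultConfig <- function() {
  list(
    kmeans = list(k = 3, seed = 0),
    pinkFilter = list(hLo = 0.85, hHi = 0.05, sLo = 0.05, sHi = 0.6,
                      vLo = 0.5, vHi = 1.0),
    enhance = list(k1 = 0.7, k2 = 0.3, gamma = 0.1, medianWindow = 3),
    segment = list(minArea = 20, hMaxima = 2, minContrast = 0.08,
                   minBlueExcess = 15),
    features = list(windows = c(30, 60, 90, 120), textureLevels = 8,
                    cytoplasmRadius = 10,
                    cluster = list(closeRadius = 7, openRadius = 3,
                                   minArea = 2000, minCells = 5)),
    cellularity = list(dilationRadius = 10)
  )
}

#' Read a configuration file
#'
#' Loads a YAML file and merges it recursively over [defaultConfig()];
#' only the keys present in the file are overridden.
#'
#' @param path YAML file path.
#' @return nested named list.
#' @export
readConfig <- function(path) {
  user <- yaml::read_yaml(path)
  merge2 <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]))
        merge2(base[[k]], over[[k]]) else over[[k]]
    }
    base
  }
  merge2(defaultConfig(), user)
}

#' Read an image patch from PNG or TIFF
#'
#' @param path image file path.
#' @param pixelSize pixel size in um/px.
#' @return an [RGBPatch].
#' @export
readPatch <- function(path, pixelSize = 0.5) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) == 2) stop("dimensional error: expected a 3-channel image")
  a <- EBImage::imageData(img)
  if (d[3] > 3) a <- a[, , 1:3]   # drop alpha
  RGBPatch(aperm(a, c(2, 1, 3)) * 255, pixelSize = pixelSize)
}

#' Write an image patch, mask or label map
#'
#' Patches are written as 8-bit RGB; logical masks as black-and-white;
#' label maps as 16-bit grayscale (label value preserved).
#'
#' @param x an [RGBPatch], logical matrix or [NucleiLabelMap].
#' @param path output path (`.png` or `.tif`).
#' @return the path, invisibly.
#' @export
writePatch <- function(x, path) {
  if (is(x, "RGBPatch")) {
    img <- EBImage::Image(aperm(x@pixels / 255, c(2, 1, 3)),
                          colormode = "Color")
    EBImage::writeImage(img, path)
  } else if (is(x, "NucleiLabelMap")) {
    EBImage::writeImage(.asImage(x@labels / 65535), path, bits.per.sample = 16L)
  } else if (is.matrix(x)) {
    EBImage::writeImage(.asImage(x * 1), path)
  } else stop("unsupported object")
  invisible(path)
}
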