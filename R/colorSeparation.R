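#' Convert a patch to HSV
#'
#' Standard channel-wise RGB to HSV conversion; all three channels are
#' scaled to \[0, 1\] (hue as a fraction of the colour circle).
#'
#' @param patch an [RGBPatch].
#' @return an [HSVImage] of the same dimensions.
#' @export
toHSV <- function(patch) {
  stopifnot(is(patch, "RGBPatch"))
  px <- patch@pixels
  d <- dim(px)
  m <- rbind(as.vector(px[, , 1]), as.vector(px[, , 2]),
             as.vector(px[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
  new("HSVImage",
      h = matrix(hsv[1, ], d[1], d[2]),
      s = matrix(hsv[2, ], d[1], d[2]),
      v = matrix(hsv[3, ], d[1], d[2]))
}

# k-means++ initial centres (Arthur & Vassilvitskii) on the current RNG.
.kmeansppInit <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    tot <- sum(d2)
    i <- if (tot <= 0) sample.int(n, 1L)
         else sample.int(n, 1L, prob = d2 / tot)
    centers[j, ] <- X[i, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
  }
  centers
}

#' K-means colour separation into stroma, nuclei and background planes
#'
#' Clusters every pixel's HSV triple into `k` groups (Lloyd iterations
#' from a seeded k-means++ initialisation, so the result is
#' deterministic for a given seed) and, for `k = 3`, labels the clusters
#' as the pink stroma plane `Ip`, blue nuclei plane `Ib` and background
#' plane `Iba`. The background role goes to the centroid with the
#' highest value-minus-saturation (bright, achromatic); of the remaining
#' two, the centroid whose hue is circularly closest to pink
#' (0.95 on the \[0, 1\] hue circle) becomes `Ip` and the other `Ib`.
#'
#' @param patch an [RGBPatch] with at least `k` distinct colours.
#' @param k number of clusters (role labelling requires `k = 3`).
#' @param seed integer seed for the k-means++ initialisation.
#' @return a [ColorPlaneSet].
#' @export
kmeansColorSeparation <- function(patch, k = 3, seed = 0) {
  stopifnot(is(patch, "RGBPatch"))
  hsv <- toHSV(patch)
  X <- cbind(as.vector(hsv@h), as.vector(hsv@s), as.vector(hsv@v))
  if (nrow(unique(X)) < k)
    stop("degenerate clustering: patch has fewer than k distinct colours")
  init <- .withSeed(seed, .kmeansppInit(X, k))
  km <- suppressWarnings(
    stats::kmeans(X, centers = init, iter.max = 200, algorithm = "Lloyd"))
  if (k != 3) stop("role labelling is only defined for k = 3")

  cent <- km$centers
  bg <- which.max(cent[, 3] - cent[, 2])
  rest <- setdiff(seq_len(k), bg)
  pink <- rest[which.min(.hueDistance(cent[rest, 1], 0.95))]
  blue <- setdiff(rest, pink)

  d <- dim(patch@pixels)
  mk <- function(i) matrix(km$cluster == i, d[1], d[2])
  ipMask <- mk(pink); ibMask <- mk(blue); ibaMask <- mk(bg)
  plane <- function(mask) {
    img <- patch@pixels
    img[, , 1][!mask] <- 0; img[, , 2][!mask] <- 0; img[, , 3][!mask] <- 0
    img
  }
  centers <- cent[c(pink, blue, bg), , drop = FALSE]
  dimnames(centers) <- list(c("pink", "blue", "background"),
                            c("h", "s", "v"))
  new("ColorPlaneSet",
      ipImage = plane(ipMask), ibImage = plane(ibMask),
      ibaImage = plane(ibaMask),
      ipMask = ipMask, ibMask = ibMask, ibaMask = ibaMask,
      centers = centers)
}

#' Pink-filter configuration
#'
#' HSV interval bounds of the stroma pink filter. The hue interval may
#' wrap around the origin of the hue circle (`hLo > hHi`), as the
#' default does: H in \[0.85, 1\] plus \[0, 0.05\].
#'
#' @param hLo,hHi hue bounds (wrap allowed).
#' @param sLo,sHi saturation bounds.
#' @param vLo,vHi value bounds.
#' @return a named list of bounds.
#' @export
pinkFilterConfig <- function(hLo = 0.85, hHi = 0.05, sLo = 0.05, sHi = 0.6,
                             vLo = 0.5, vHi = 1.0) {
  cfg <- list(hLo = hLo, hHi = hHi, sLo = sLo, sHi = sHi,
              vLo = vLo, vHi = vHi)
  if (sLo > sHi || vLo > vHi)
    stop("configuration error: empty saturation or value interval")
  cfg
}

#' Stroma pink filter
#'
#' Flags pixels whose HSV triple lies inside the configured pink
#' interval and reports the mean stroma concentration, i.e. the flagged
#' fraction of the patch.
#'
#' @param patch an [RGBPatch].
#' @param config interval bounds from [pinkFilterConfig()].
#' @return list with `mask` (logical `H x W`) and `meanConcentration`
#'   (fraction in \[0, 1\]).
#' @export
stromaPinkFilter <- function(patch, config = pinkFilterConfig()) {
  stopifnot(is(patch, "RGBPatch"))
  hsv <- toHSV(patch)
  inH <- if (config$hLo <= config$hHi)
    hsv@h >= config$hLo & hsv@h <= config$hHi
  else
    hsv@h >= config$hLo | hsv@h <= config$hHi
  mask <- inH &
    hsv@s >= config$sLo & hsv@s <= config$sHi &
    hsv@v >= config$vLo & hsv@v <= config$vHi
  list(mask = mask, meanConcentration = mean(mask))
}
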