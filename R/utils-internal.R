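# Internal helpers shared across modules. The package-wide pixel convention
# is row = y, column = x, 0-based coordinates at the user surface; EBImage
# stores images x-major, hence the transposition wrappers.

.asImage <- function(m) EBImage::Image(t(m))

.fromImage <- function(img) t(EBImage::imageData(img))

# Disc structuring element of integer radius r: offsets with dx^2+dy^2 <= r^2.
.discKernel <- function(r) {
  r <- as.integer(round(r))
  if (r <= 0) return(matrix(1, 1, 1))
  d <- -r:r
  k <- outer(d, d, function(y, x) as.numeric(x * x + y * y <= r * r))
  k
}

# Evaluate code under a temporary RNG state seeded with `seed`.
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Luminance grayscale on [0,1] (ITU-R BT.601 weights).
.luminance <- function(pixels) {
  (0.2989 * pixels[, , 1] + 0.5870 * pixels[, , 2] +
     0.1140 * pixels[, , 3]) / 255
}

# Summed-area table with a zero-padded first row/column, so that the sum of
# m[r1:r2, c1:c2] is S[r2+1,c2+1] - S[r1,c2+1] - S[r2+1,c1] + S[r1,c1].
.sat <- function(m) {
  h <- nrow(m); w <- ncol(m)
  S <- matrix(0, h + 1, w + 1)
  S[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  S
}

.satSum <- function(S, r1, r2, c1, c2) {
  S[r2 + 1, c2 + 1] - S[r1, c2 + 1] - S[r2 + 1, c1] + S[r1, c1]
}

# Window extent of side w centred at 0-based coordinate c along an axis of
# length n; returns 1-based inclusive [lo, hi], cropped to the image.
.windowRange <- function(c0, w, n) {
  lo <- c0 - floor(w / 2) + 1L
  hi <- lo + w - 1L
  c(max(1L, lo), min(n, hi))
}

# Boundary pixel count: mask pixels with at least one 4-neighbour outside
# the mask (pixels on the image edge count as boundary).
.boundaryCount <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  core <- pad[2:(h + 1), 2:(w + 1)]
  interior <- core &
    pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
    pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  sum(core) - sum(interior)
}

# Circular distance between hues on the unit circle [0,1).
.hueDistance <- function(h, ref) {
  d <- abs(h - ref)
  pmin(d, 1 - d)
}

.emptyLabelMap <- function(h, w) {
  NucleiLabelMap(matrix(0L, h, w))
}
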