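# Independent brute-force oracles and small patch builders used across
# the suite. Oracles deliberately use naive loops, not the package's
# vectorised code paths.

# Exhaustive Otsu: try every split of the histogram, recompute class
# weights and means explicitly, return the maximising split's midpoint.
bruteOtsu <- function(counts, values) {
  n <- length(counts)
  best <- -Inf; bestJ <- NA
  for (j in 1:(n - 1)) {
    w1 <- sum(counts[1:j]); w2 <- sum(counts[(j + 1):n])
    if (w1 == 0 || w2 == 0) next
    m1 <- sum(counts[1:j] * values[1:j]) / w1
    m2 <- sum(counts[(j + 1):n] * values[(j + 1):n]) / w2
    sb <- (w1 / (w1 + w2)) * (w2 / (w1 + w2)) * (m1 - m2)^2
    if (sb > best + 1e-15) { best <- sb; bestJ <- j }
  }
  (values[bestJ] + values[bestJ + 1]) / 2
}

# Naive dilation: every pixel within Euclidean distance <= r of a true
# pixel becomes true.
bruteDilate <- function(mask, r) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) == 0) return(out)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    d2 <- (pts[, 1] - i)^2 + (pts[, 2] - j)^2
    if (any(d2 <= r^2)) out[i, j] <- TRUE
  }
  out
}

# Naive windowed concentration: loop the window pixel by pixel.
bruteConcentration <- function(mask, center, window) {
  h <- nrow(mask); w <- ncol(mask)
  x <- round(center[1]); y <- round(center[2])
  lo <- function(c0) c0 - floor(window / 2)
  tw <- 0; tp <- 0
  for (yy in lo(y):(lo(y) + window - 1)) for (xx in lo(x):(lo(x) + window - 1)) {
    if (yy < 0 || yy >= h || xx < 0 || xx >= w) next
    tp <- tp + 1
    if (mask[yy + 1, xx + 1]) tw <- tw + 1
  }
  tw / tp
}

# Pairwise concordance probability (ties count half) = AUC.
bruteAUC <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Filled ellipse mask (pixel-centre inclusion), 1-based centre.
ellipseMask <- function(h, w, cy, cx, a, b, theta) {
  m <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    dx <- j - cx; dy <- i - cy
    u <- (dx * cos(theta) + dy * sin(theta)) / a
    v <- (-dx * sin(theta) + dy * cos(theta)) / b
    if (u^2 + v^2 <= 1) m[i, j] <- TRUE
  }
  m
}

# Solid-colour patch with optional rectangular blocks of other colours.
solidPatch <- function(h, w, rgb) {
  px <- array(0, c(h, w, 3))
  for (ch in 1:3) px[, , ch] <- rgb[ch]
  RGBPatch(px)
}

# Paint a filled disc of a given colour onto a patch's pixel array.
paintDisc <- function(px, cy, cx, r, rgb) {
  h <- dim(px)[1]; w <- dim(px)[2]
  for (i in max(1, cy - r):min(h, cy + r))
    for (j in max(1, cx - r):min(w, cx + r))
      if ((i - cy)^2 + (j - cx)^2 <= r^2)
        px[i, j, ] <- rgb
  px
}

# H&E-like patch: noisy pink stroma background, optional dark nuclei
# discs; deterministic for a given seed.
stromaPatch <- function(h = 96, w = 96, seed = 1, discs = NULL,
                        noiseSd = 4) {
  withr::with_seed(seed, {
    px <- array(0, c(h, w, 3))
    base <- c(230, 160, 200)
    for (ch in 1:3) px[, , ch] <- base[ch] + rnorm(h * w, 0, noiseSd)
    if (!is.null(discs))
      for (d in discs) px <- paintDisc(px, d[1], d[2], d[3], c(60, 40, 120))
    RGBPatch(round(pmin(pmax(px, 0), 255)))
  })
}

# Small fast phantom spec shared by pipeline tests.
testSpec <- function(...) {
  args <- list(...)
  defaults <- list(size = 160, nBenign = 12, nMalignant = 5, nDucts = 0,
                   fatFraction = 0.04, seed = 1)
  do.call(phantomSpec, utils::modifyList(defaults, args))
}

# Per-truth-nucleus best-overlap Jaccard against a segmentation.
truthJaccards <- function(phantom, seg) {
  truth <- labelMatrix(phantom)
  segm <- labelMatrix(seg)
  vapply(seq_len(nNuclei(phantom)), function(k) {
    tm <- truth == k
    cand <- segm[tm]
    cand <- cand[cand > 0]
    if (!length(cand)) return(0)
    lab <- as.integer(names(which.max(table(cand))))
    jaccardIndex(tm, segm == lab)
  }, 0)
}

# Feature table + ground-truth classes for a list of phantoms.
phantomTrainingData <- function(phantoms, config = defaultConfig()) {
  tabs <- list(); cls <- list()
  for (i in seq_along(phantoms)) {
    ph <- phantoms[[i]]
    seg <- segmentNuclei(ph@patch)
    m <- matchToGroundTruth(seg, ph)
    tab <- extractFeatureTable(ph@patch, config, patchId = paste0("p", i))
    tabs[[i]] <- tab
    cls[[i]] <- m$class[match(tab$nucleus, m$nucleus)]
  }
  list(table = do.call(rbind, tabs), classes = unlist(cls))
}

# Synthetic labelled feature tables for the selection module: `nInfo`
# informative features linear in TC plus `nNoise` pure-noise features,
# rows at the 11-level grid.
selectionTable <- function(seed, nInfo = 5, nNoise = 20, rowsPerLevel = 40,
                           slope = 10, noiseSd = 1) {
  withr::with_seed(seed, {
    tc <- rep(seq(0, 1, by = 0.1), each = rowsPerLevel)
    n <- length(tc)
    df <- data.frame(patch_id = "s", nucleus = seq_len(n))
    for (j in seq_len(nInfo))
      df[[paste0("info_", j)]] <- slope * tc + rnorm(n, 0, noiseSd)
    for (j in seq_len(nNoise))
      df[[paste0("noise_", j)]] <- rnorm(n)
    df$tc_label <- tc
    df
  })
}
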