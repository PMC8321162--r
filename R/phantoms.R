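# Synthetic H&E-like phantoms with pixel-exact ground truth: pink textured
# stroma, white fat blobs, blue elliptical nuclei (benign small and round,
# malignant larger, eccentric, irregular and more textured) and optional
# duct clusters of packed nuclei. Malignancy is expressed through size,
# eccentricity and texture so the morphological features are genuinely
# discriminative on phantoms -- a modelling choice of the fixture, not
# biology.

#' @describeIn PhantomSpec constructor with the default study conditions
#'   (512 x 512 px at 0.5 um/px).
#' @param size patch side in pixels.
#' @param nBenign,nMalignant nucleus counts.
#' @param benignRadius,malignantRadius semi-major-axis ranges in px.
#' @param benignEccentricity,malignantEccentricity eccentricity ranges.
#' @param nDucts duct cluster count.
#' @param ductCells range of nuclei per duct.
#' @param stromaColor,nucleusColor,fatColor RGB triples.
#' @param colorJitterSd colour jitter SD (intensity units).
#' @param fatFraction target fat area fraction.
#' @param noiseSd global Gaussian pixel noise SD.
#' @param dilationRadius cytoplasm dilation radius for the planted TC.
#' @param seed integer RNG seed.
#' @export
phantomSpec <- function(size = 512, nBenign = 40, nMalignant = 15,
                        benignRadius = c(4, 7),
                        malignantRadius = c(8, 14),
                        benignEccentricity = c(0, 0.3),
                        malignantEccentricity = c(0.4, 0.8),
                        nDucts = 1, ductCells = c(8, 15),
                        stromaColor = c(230, 160, 200),
                        nucleusColor = c(60, 40, 120),
                        fatColor = c(245, 245, 245),
                        colorJitterSd = 6, fatFraction = 0.08,
                        noiseSd = 4, dilationRadius = 10, seed = 0) {
  new("PhantomSpec", size = as.integer(size),
      nBenign = as.integer(nBenign), nMalignant = as.integer(nMalignant),
      benignRadius = benignRadius, malignantRadius = malignantRadius,
      benignEccentricity = benignEccentricity,
      malignantEccentricity = malignantEccentricity,
      nDucts = as.integer(nDucts), ductCells = ductCells,
      stromaColor = stromaColor, nucleusColor = nucleusColor,
      fatColor = fatColor, colorJitterSd = colorJitterSd,
      fatFraction = fatFraction, noiseSd = noiseSd,
      dilationRadius = dilationRadius, seed = as.integer(seed))
}

# Pixels (1-based arr.ind) of a rotated ellipse centred at (cx, cy) with
# semi-axes a >= b and optional radial boundary irregularity.
.rasterEllipse <- function(cx, cy, a, b, theta, S, irregular = NULL) {
  ext <- ceiling(a * 1.25) + 1
  r1 <- max(1, floor(cy - ext)); r2 <- min(S, ceiling(cy + ext))
  c1 <- max(1, floor(cx - ext)); c2 <- min(S, ceiling(cx + ext))
  rows <- r1:r2; cols <- c1:c2
  dy <- outer(rows - cy, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - cx)
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  rho <- u^2 + v^2
  inside <- if (is.null(irregular)) rho <= 1 else {
    phi <- atan2(v, u)
    m <- 1 + irregular$a1 * sin(3 * phi + irregular$p1) +
      irregular$a2 * sin(5 * phi + irregular$p2)
    rho <= m^2
  }
  w <- which(inside, arr.ind = TRUE)
  cbind(row = rows[w[, 1]], col = cols[w[, 2]])
}

.sampleGeometry <- function(radRange, eccRange, irregularAmp) {
  a <- runif(1, radRange[1], radRange[2])
  e <- runif(1, eccRange[1], eccRange[2])
  b <- a * sqrt(1 - e^2)
  theta <- runif(1, 0, pi)
  irr <- if (irregularAmp > 0)
    list(a1 = irregularAmp, p1 = runif(1, 0, 2 * pi),
         a2 = irregularAmp / 2, p2 = runif(1, 0, 2 * pi))
  else NULL
  list(a = a, b = b, theta = theta, irr = irr)
}

# Mutable phantom canvas passed through the placement helpers.
.newCanvas <- function(S) {
  env <- new.env(parent = emptyenv())
  env$S <- S
  env$occ <- matrix(FALSE, S, S)      # claimed pixels (1 px gap enforced)
  env$labels <- matrix(0L, S, S)
  env$fat <- matrix(FALSE, S, S)
  env$duct <- matrix(0L, S, S)
  env$classes <- character()
  env$texture <- numeric()            # within-nucleus texture noise SD
  env
}

# Try to place one nucleus; returns TRUE on success.
.tryPlace <- function(cv, cx, cy, geom, class, textureSd) {
  S <- cv$S
  if (cx - geom$a < 2 || cx + geom$a > S - 1 ||
      cy - geom$a < 2 || cy + geom$a > S - 1) return(FALSE)
  idx <- .rasterEllipse(cx, cy, geom$a, geom$b, geom$theta, S, geom$irr)
  if (nrow(idx) == 0 || any(cv$occ[idx])) return(FALSE)
  id <- length(cv$classes) + 1L
  cv$labels[idx] <- id
  # claim a 1 px ring so neighbouring nuclei never touch
  grow <- unique(do.call(rbind, lapply(list(c(0, 0), c(0, 1), c(0, -1),
                                            c(1, 0), c(-1, 0)),
    function(d) cbind(pmin(pmax(idx[, 1] + d[1], 1), S),
                      pmin(pmax(idx[, 2] + d[2], 1), S)))))
  cv$occ[grow] <- TRUE
  cv$classes <- c(cv$classes, class)
  cv$texture <- c(cv$texture, textureSd)
  TRUE
}

.placeRandom <- function(cv, n, radRange, eccRange, class, irregularAmp,
                         textureSd, budget = 300, centerFn = NULL,
                         strict = TRUE) {
  placed <- 0L
  while (placed < n) {
    ok <- FALSE
    for (t in seq_len(budget)) {
      g <- .sampleGeometry(radRange, eccRange, irregularAmp)
      ctr <- if (is.null(centerFn))
        runif(2, g$a + 2, cv$S - g$a - 1) else centerFn(g)
      if (.tryPlace(cv, ctr[1], ctr[2], g, class, textureSd)) {
        ok <- TRUE; break
      }
    }
    if (!ok) {
      if (strict)
        stop("placement error: could not place all nuclei without ",
             "overlap; reduce counts or radii")
      break
    }
    placed <- placed + 1L
  }
  placed
}

.placeFat <- function(cv, fatFraction) {
  if (fatFraction <= 0) return(invisible())
  S <- cv$S
  tries <- 0
  while (mean(cv$fat) < fatFraction && tries < 200) {
    tries <- tries + 1
    a <- runif(1, 12, min(40, S / 6))
    b <- a * runif(1, 0.6, 1)
    th <- runif(1, 0, pi)
    ctr <- runif(2, a + 1, S - a)
    idx <- .rasterEllipse(ctr[1], ctr[2], a, b, th, S)
    cv$fat[idx] <- TRUE
  }
  grown <- .fromImage(EBImage::dilate(.asImage(cv$fat), .discKernel(2)))
  cv$occ <- cv$occ | (grown != 0)
  invisible()
}

.placeDucts <- function(cv, spec) {
  S <- cv$S
  for (d in seq_len(spec@nDucts)) {
    cells <- spec@ductCells[1] +
      sample.int(spec@ductCells[2] - spec@ductCells[1] + 1, 1) - 1
    rmean <- mean(spec@benignRadius)
    Rd <- sqrt(cells * (rmean + 1.5)^2 / 0.5)
    if (2 * (Rd + 6) > S - 10) next
    ctr <- runif(2, Rd + 6, S - Rd - 6)
    sampler <- function(g) {
      rr <- sqrt(runif(1)) * (Rd - g$a)
      an <- runif(1, 0, 2 * pi)
      c(ctr[1] + rr * cos(an), ctr[2] + rr * sin(an))
    }
    got <- .placeRandom(cv, cells, spec@benignRadius,
                        spec@benignEccentricity, "benign",
                        irregularAmp = 0, textureSd = 3, budget = 400,
                        centerFn = sampler, strict = FALSE)
    if (got > 0) {
      didx <- .rasterEllipse(ctr[1], ctr[2], Rd + 4, Rd + 4, 0, S)
      cv$duct[didx] <- d
    }
  }
  invisible()
}

.renderCanvas <- function(cv, spec) {
  S <- cv$S
  px <- array(0, c(S, S, 3))
  for (ch in 1:3)
    px[, , ch] <- spec@stromaColor[ch] +
      rnorm(S * S, 0, spec@colorJitterSd)
  if (any(cv$fat)) {
    f <- cv$fat
    for (ch in 1:3) {
      pl <- px[, , ch]; pl[f] <- spec@fatColor[ch]; px[, , ch] <- pl
    }
  }
  nlab <- length(cv$classes)
  if (nlab > 0) {
    pos <- which(cv$labels > 0)
    l <- cv$labels[pos]
    shift <- matrix(rnorm(3 * nlab, 0, spec@colorJitterSd), nlab, 3)
    texsd <- cv$texture[l]
    for (ch in 1:3) {
      pl <- px[, , ch]
      pl[pos] <- spec@nucleusColor[ch] + shift[l, ch] +
        rnorm(length(pos), 0, texsd)
      px[, , ch] <- pl
    }
  }
  px <- px + rnorm(length(px), 0, spec@noiseSd)
  px <- round(pmin(pmax(px, 0), 255))
  px
}

.finishPhantom <- function(cv, spec) {
  px <- .renderCanvas(cv, spec)
  labs <- NucleiLabelMap(cv$labels)
  mal <- matrix(cv$labels %in% which(cv$classes == "malignant"),
                cv$S, cv$S)
  tc <- computeTCFromMasks(mal, dilationRadius = spec@dilationRadius)@tc
  new("SyntheticPhantom", patch = RGBPatch(px),
      labels = labs, classes = cv$classes, ductLabels = cv$duct,
      trueTC = tc, spec = spec)
}

#' Generate one synthetic phantom
#'
#' Renders a phantom patch from its spec and records the pixel-exact
#' ground truth before rendering: the nucleus label map, per-nucleus
#' benign/malignant classes, the duct map and the planted TC (computed
#' from the malignant masks with [computeTCFromMasks()] at the spec's
#' dilation radius). Deterministic per seed: the same spec reproduces
#' identical pixels.
#'
#' @param spec a [PhantomSpec].
#' @return a [SyntheticPhantom].
#' @export
generatePhantom <- function(spec = phantomSpec()) {
  stopifnot(is(spec, "PhantomSpec"))
  .withSeed(spec@seed, {
    cv <- .newCanvas(spec@size)
    .placeFat(cv, spec@fatFraction)
    if (spec@nDucts > 0) .placeDucts(cv, spec)
    .placeRandom(cv, spec@nMalignant, spec@malignantRadius,
                 spec@malignantEccentricity, "malignant",
                 irregularAmp = 0.12, textureSd = 9)
    .placeRandom(cv, spec@nBenign, spec@benignRadius,
                 spec@benignEccentricity, "benign",
                 irregularAmp = 0, textureSd = 3)
    .finishPhantom(cv, spec)
  })
}

# Place malignant nuclei until the dilated coverage reaches the target.
# Candidate centres are sampled from still-uncovered pixels, so holes are
# targeted directly; dilation distributes over union, so coverage is
# maintained exactly with local updates.
.buildToTarget <- function(spec, target) {
  S <- spec@size
  cv <- .newCanvas(S)
  fatEff <- min(spec@fatFraction, max(0, 1 - target - 0.1))
  .placeFat(cv, fatEff)
  if (spec@nDucts > 0 && target <= 0.6) .placeDucts(cv, spec)
  kernR <- spec@dilationRadius
  covered <- matrix(FALSE, S, S)
  if (target > 0) {
    repeat {
      remaining <- target - mean(covered)
      if (remaining < 0.005) break
      open <- which(!covered)
      placedOne <- FALSE
      # when close to the target, prefer smaller nuclei so the final
      # increment does not overshoot
      rad <- spec@malignantRadius
      if (remaining < 2 * pi * (mean(rad) + kernR)^2 / S^2)
        rad <- c(rad[1], rad[1] + 0.15 * diff(rad))
      for (t in seq_len(200)) {
        g <- .sampleGeometry(rad, spec@malignantEccentricity, 0.12)
        pos <- open[sample.int(length(open), 1)]
        # a centre anywhere within the dilation reach of the hole still
        # covers it; alternate exact-hole centres with jittered ones to
        # find room in crowded neighbourhoods
        jit <- if (t %% 2 == 0) round(runif(2, -kernR, kernR)) else c(0, 0)
        cy <- (pos - 1) %% S + 1 + jit[1]
        cx <- (pos - 1) %/% S + 1 + jit[2]
        if (.tryPlace(cv, cx, cy, g, "malignant", 9)) {
          id <- length(cv$classes)
          idx <- which(cv$labels == id, arr.ind = TRUE)
          r1 <- max(1, min(idx[, 1]) - kernR)
          r2 <- min(S, max(idx[, 1]) + kernR)
          c1 <- max(1, min(idx[, 2]) - kernR)
          c2 <- min(S, max(idx[, 2]) + kernR)
          sub <- cv$labels[r1:r2, c1:c2, drop = FALSE] == id
          dsub <- .fromImage(EBImage::dilate(.asImage(sub),
                                             .discKernel(kernR))) != 0
          covered[r1:r2, c1:c2] <- covered[r1:r2, c1:c2] | dsub
          placedOne <- TRUE
          break
        }
      }
      if (!placedOne) break   # best achievable coverage
    }
  }
  nB <- round(spec@nBenign * (1 - mean(covered)))
  .placeRandom(cv, nB, spec@benignRadius, spec@benignEccentricity,
               "benign", irregularAmp = 0, textureSd = 3, budget = 100,
               strict = FALSE)
  .finishPhantom(cv, spec)
}

#' Generate a suite of phantoms with planted cellularity levels
#'
#' For each target TC level, malignant nuclei are placed until the
#' dilated ground-truth coverage reaches the target (checked exactly
#' during construction), mirroring a training design with cellularity
#' uniformly spread from zero to one. Targets are normally met within
#' 0.03; an unreachable target (dense packing exhausted) yields the
#' best achievable coverage.
#'
#' @param targets numeric TC targets in \[0, 1\] (e.g.
#'   `seq(0, 1, by = 0.1)`).
#' @param nPerLevel phantoms per target.
#' @param seed integer master seed; each phantom derives its own.
#' @param spec base [PhantomSpec] (its `nMalignant` is ignored; its
#'   `nBenign` scales down with coverage).
#' @return list of [SyntheticPhantom] objects, with the target of each
#'   phantom in the `"target"` attribute.
#' @export
phantomSuite <- function(targets, nPerLevel = 3, seed = 0,
                         spec = phantomSpec()) {
  stopifnot(all(targets >= 0 & targets <= 1))
  out <- list()
  counter <- 0L
  for (tg in targets) for (i in seq_len(nPerLevel)) {
    counter <- counter + 1L
    si <- as.integer((seed * 1009L + counter * 7L) %% 2147483647L)
    sp <- spec
    sp@seed <- si
    ph <- .withSeed(si, .buildToTarget(sp, tg))
    attr(ph, "target") <- tg
    out[[counter]] <- ph
  }
  out
}

#' Match segmented nuclei to phantom ground truth
#'
#' For every segmented label, finds the ground-truth nucleus with the
#' largest pixel overlap and reports its class; segmented regions whose
#' majority overlap is background are reported with `truth_label = 0`
#' and class `"benign"` (they contribute nothing malignant).
#'
#' @param segmentation a [NucleiLabelMap] from [segmentNuclei()].
#' @param phantom the [SyntheticPhantom] the patch came from.
#' @return data.frame with columns `nucleus`, `truth_label`, `class`,
#'   `overlap_fraction` (overlap with the majority truth label as a
#'   fraction of the segmented area).
#' @export
matchToGroundTruth <- function(segmentation, phantom) {
  stopifnot(is(segmentation, "NucleiLabelMap"),
            is(phantom, "SyntheticPhantom"))
  seg <- segmentation@labels
  truth <- phantom@labels@labels
  n <- segmentation@nNuclei
  if (n == 0)
    return(data.frame(nucleus = integer(), truth_label = integer(),
                      class = character(), overlap_fraction = numeric()))
  pos <- which(seg > 0)
  sl <- seg[pos]; tl <- truth[pos]
  res <- t(vapply(split(tl, factor(sl, levels = seq_len(n))), function(v) {
    tb <- tabulate(v + 1L)
    best <- which.max(tb)
    c(best - 1L, tb[best] / length(v))
  }, numeric(2)))
  truthLab <- as.integer(res[, 1])
  cls <- ifelse(truthLab == 0, "benign", phantom@classes[pmax(truthLab, 1)])
  data.frame(nucleus = as.integer(rownames(res)),
             truth_label = truthLab, class = cls,
             overlap_fraction = res[, 2])
}
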