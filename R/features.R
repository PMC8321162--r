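# Per-nucleus, regional, cluster and global morphological features.
# Coordinates at the user surface are 0-based with x = column, y = row;
# windows are axis-aligned squares centred on the rounded nucleus centroid
# and cropped at the image border (the denominator counts in-image pixels
# only, so border windows carry no padding bias).

.labelIndices <- function(lab, label) {
  idx <- which(lab == label, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("lookup error: label ", label, " not present")
  idx
}

# Second-central-moment ellipse of a pixel set (equivalent-ellipse
# convention: axis lengths are 4 * sqrt(eigenvalue)).
.momentEllipse <- function(xs, ys) {
  cx <- mean(xs); cy <- mean(ys)
  mxx <- mean((xs - cx)^2); myy <- mean((ys - cy)^2)
  mxy <- mean((xs - cx) * (ys - cy))
  tr <- (mxx + myy) / 2
  det <- sqrt(((mxx - myy) / 2)^2 + mxy^2)
  l1 <- tr + det; l2 <- max(tr - det, 0)
  list(cx = cx, cy = cy,
       major = 4 * sqrt(l1), minor = 4 * sqrt(l2),
       ecc = if (l1 > 0) sqrt(1 - l2 / l1) else 0,
       orientation = 0.5 * atan2(2 * mxy, mxx - myy) * 180 / pi)
}

#' Geometric features of one segmented nucleus
#'
#' Area (pixel count), perimeter (4-connected boundary pixel count),
#' roundness `4 * pi * A / P^2` (values slightly above 1 can occur from
#' discretisation and are reported as-is), centroid in 0-based pixel
#' coordinates, and the equivalent-ellipse major/minor axis,
#' eccentricity and orientation (degrees of the major axis from the
#' x-axis in image coordinates, y pointing down, range (-90, 90\]).
#'
#' @param labels a [NucleiLabelMap].
#' @param label integer label present in the map.
#' @return named list of geometry features.
#' @export
nucleusMorphology <- function(labels, label) {
  stopifnot(is(labels, "NucleiLabelMap"))
  lab <- labels@labels
  idx <- .labelIndices(lab, label)
  xs <- idx[, 2] - 1; ys <- idx[, 1] - 1
  area <- nrow(idx)
  r1 <- min(idx[, 1]); r2 <- max(idx[, 1])
  c1 <- min(idx[, 2]); c2 <- max(idx[, 2])
  sub <- lab[r1:r2, c1:c2, drop = FALSE] == label
  per <- .boundaryCount(sub)
  ell <- .momentEllipse(xs, ys)
  list(area = area, perimeter = per,
       roundness = 4 * pi * area / per^2,
       eccentricity = ell$ecc,
       centroid_x = ell$cx, centroid_y = ell$cy,
       major_axis = ell$major, minor_axis = ell$minor,
       orientation = ell$orientation)
}

# Quantise [0,1] grayscale into `levels` equal bins.
.quantize <- function(x, levels) pmin(floor(x * levels) + 1L, levels)

# Symmetric normalised co-occurrence statistics for one offset (dr, dc)
# restricted to pixel pairs both inside `mask`. A region with no valid
# pair degenerates to contrast 0, homogeneity 1 (a constant).
.glcmStats <- function(q, mask, dr, dc, levels) {
  h <- nrow(mask); w <- ncol(mask)
  r1 <- 1:(h - dr); c1 <- 1:(w - dc)
  a <- mask[r1, c1, drop = FALSE] &
    mask[r1 + dr, c1 + dc, drop = FALSE]
  if (!any(a)) return(c(contrast = 0, homogeneity = 1))
  qi <- q[r1, c1, drop = FALSE][a]
  qj <- q[r1 + dr, c1 + dc, drop = FALSE][a]
  cnt <- tabulate((qi - 1L) * levels + qj, levels * levels)
  P <- matrix(cnt, levels, levels, byrow = TRUE)
  P <- P + t(P)
  P <- P / sum(P)
  ij <- outer(seq_len(levels), seq_len(levels), "-")
  c(contrast = sum(P * ij^2), homogeneity = sum(P / (1 + abs(ij))))
}

.textureForMask <- function(gray, hsv, lab, label, levels) {
  idx <- .labelIndices(lab, label)
  r1 <- min(idx[, 1]); r2 <- max(idx[, 1])
  c1 <- min(idx[, 2]); c2 <- max(idx[, 2])
  sub <- lab[r1:r2, c1:c2, drop = FALSE] == label
  # erode by a 3x3 box to stay inside the cell body; fall back to the
  # full nucleus when nothing survives
  h <- nrow(sub); w <- ncol(sub)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- sub
  er <- sub
  for (dr in -1:1) for (dc in -1:1)
    er <- er & pad[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
  if (!any(er)) er <- sub
  g <- gray[r1:r2, c1:c2, drop = FALSE]
  q <- .quantize(g, levels)
  s1 <- .glcmStats(q, er, 0L, 1L, levels)
  s2 <- .glcmStats(q, er, 1L, 0L, levels)
  hh <- hsv@h[r1:r2, c1:c2, drop = FALSE]
  ss <- hsv@s[r1:r2, c1:c2, drop = FALSE]
  vv <- hsv@v[r1:r2, c1:c2, drop = FALSE]
  list(texture_contrast_1 = unname(s1["contrast"]),
       texture_contrast_2 = unname(s2["contrast"]),
       texture_homogeneity_1 = unname(s1["homogeneity"]),
       texture_homogeneity_2 = unname(s2["homogeneity"]),
       mean_h = mean(hh[er]), mean_s = mean(ss[er]), mean_v = mean(vv[er]))
}

#' Texture and mean-HSV features inside one nucleus
#'
#' Gray-level co-occurrence contrast and homogeneity at the two offsets
#' (0, 1) and (1, 0) -- 8 quantisation levels over \[0, 1\], symmetric
#' and normalised -- computed on an eroded sub-region inside the
#' segmented cell body (falling back to the full nucleus when erosion
#' empties it), together with the mean H/S/V over the same sub-region.
#'
#' @param patch an [RGBPatch].
#' @param labels a [NucleiLabelMap].
#' @param label integer label present in the map.
#' @param levels number of gray levels of the co-occurrence matrix.
#' @return named list of texture and mean-HSV features.
#' @export
nucleusTextureHSV <- function(patch, labels, label, levels = 8) {
  stopifnot(is(patch, "RGBPatch"), is(labels, "NucleiLabelMap"))
  gray <- .luminance(patch@pixels)
  hsv <- toHSV(patch)
  .textureForMask(gray, hsv, labels@labels, label, levels)
}

#' Regional concentration R = TW / TP
#'
#' Fraction of foreground pixels of a binary plane inside the square
#' window of side `window` centred on `center`, cropped at the image
#' border (TP counts in-image pixels only).
#'
#' @param mask logical `H x W` plane.
#' @param center length-2 vector `c(x, y)` in 0-based pixel coordinates.
#' @param window window side in pixels (30/60/90/120 in the pipeline).
#' @return fraction in \[0, 1\].
#' @export
regionalConcentration <- function(mask, center, window) {
  stopifnot(is.matrix(mask), window >= 1)
  h <- nrow(mask); w <- ncol(mask)
  x <- round(center[1]); y <- round(center[2])
  if (x < 0 || x >= w || y < 0 || y >= h)
    stop("coordinate error: center outside image")
  rr <- .windowRange(y, as.integer(window), h)
  cc <- .windowRange(x, as.integer(window), w)
  mean(mask[rr[1]:rr[2], cc[1]:cc[2]] != 0)
}

#' Regional HSV histograms and means
#'
#' Four-bin equal-width histograms over \[0, 1\] per HSV channel,
#' normalised to sum to one, plus the per-channel means, over the square
#' window centred on `center` (cropped at the border).
#'
#' @param hsv an [HSVImage].
#' @param center length-2 vector `c(x, y)`, 0-based.
#' @param window window side in pixels.
#' @return list with `hist_h`, `hist_s`, `hist_v` (length-4 fractions)
#'   and `mean_h`, `mean_s`, `mean_v`.
#' @export
regionalHSVHistograms <- function(hsv, center, window) {
  stopifnot(is(hsv, "HSVImage"))
  h <- nrow(hsv@h); w <- ncol(hsv@h)
  x <- round(center[1]); y <- round(center[2])
  if (x < 0 || x >= w || y < 0 || y >= h)
    stop("coordinate error: center outside image")
  rr <- .windowRange(y, as.integer(window), h)
  cc <- .windowRange(x, as.integer(window), w)
  grab <- function(m) m[rr[1]:rr[2], cc[1]:cc[2]]
  histo <- function(vals) tabulate(.quantize(vals, 4L), 4L) / length(vals)
  hh <- grab(hsv@h); ss <- grab(hsv@s); vv <- grab(hsv@v)
  list(hist_h = histo(hh), hist_s = histo(ss), hist_v = histo(vv),
       mean_h = mean(hh), mean_s = mean(ss), mean_v = mean(vv))
}

.labelCentroids <- function(lab) {
  pos <- which(lab > 0)
  if (!length(pos))
    return(data.frame(label = integer(), x = numeric(), y = numeric()))
  l <- lab[pos]
  r <- (pos - 1) %% nrow(lab) + 1
  cc <- (pos - 1) %/% nrow(lab) + 1
  data.frame(label = sort(unique(l)),
             x = as.numeric(tapply(cc - 1, l, mean)),
             y = as.numeric(tapply(r - 1, l, mean)))
}

#' Detect duct/cluster regions
#'
#' Ducts appear as dense groups of packed nuclei. Candidate foreground
#' is the blue nuclei plane (the tissue left after removing background
#' and stroma); a morphological opening (disc `openRadius`) first
#' removes sub-nucleus specks, then a closing (disc `closeRadius`)
#' merges packed nuclei into one region (opening after the closing
#' would sever the thin bridges the closing just built). Connected
#' components with area at least
#' `minArea` containing at least `minCells` nucleus centroids become
#' clusters; each reports area, roundness `4 * pi * A / P^2`, the number
#' of member nuclei and the mean distance from their centroids to the
#' cluster centroid.
#'
#' @param planes a [ColorPlaneSet].
#' @param labels a [NucleiLabelMap] of the same patch.
#' @param closeRadius,openRadius structuring disc radii in pixels.
#' @param minArea minimum cluster area in px^2.
#' @param minCells minimum member nucleus count.
#' @return list with `clusters` (data.frame: `cluster_id`,
#'   `cluster_area`, `cluster_roundness`, `n_cells_inside`,
#'   `mean_cell_to_centroid_distance`) and `labelMap` (integer matrix of
#'   kept clusters, 0 = none). An empty data.frame is a valid result.
#' @export
detectClusters <- function(planes, labels, closeRadius = 7, openRadius = 3,
                           minArea = 2000, minCells = 5) {
  stopifnot(is(planes, "ColorPlaneSet"), is(labels, "NucleiLabelMap"))
  cand <- planes@ibMask
  empty <- list(clusters = data.frame(cluster_id = integer(),
                                      cluster_area = numeric(),
                                      cluster_roundness = numeric(),
                                      n_cells_inside = integer(),
                                      mean_cell_to_centroid_distance =
                                        numeric()),
                labelMap = matrix(0L, nrow(cand), ncol(cand)))
  if (!any(cand)) return(empty)
  img <- .asImage(cand)
  if (openRadius > 0) img <- EBImage::opening(img, .discKernel(openRadius))
  img <- EBImage::closing(img, .discKernel(closeRadius))
  lab <- .fromImage(EBImage::bwlabel(img))
  storage.mode(lab) <- "integer"
  if (max(lab) == 0) return(empty)
  cents <- .labelCentroids(labels@labels)
  memb <- if (nrow(cents))
    lab[cbind(round(cents$y) + 1, round(cents$x) + 1)]
  else integer()
  rows <- list(); keptMap <- matrix(0L, nrow(lab), ncol(lab)); nid <- 0L
  for (cl in seq_len(max(lab))) {
    idx <- which(lab == cl, arr.ind = TRUE)
    area <- nrow(idx)
    if (area < minArea) next
    inside <- which(memb == cl)
    if (length(inside) < minCells) next
    r1 <- min(idx[, 1]); r2 <- max(idx[, 1])
    c1 <- min(idx[, 2]); c2 <- max(idx[, 2])
    per <- .boundaryCount(lab[r1:r2, c1:c2, drop = FALSE] == cl)
    cx <- mean(idx[, 2] - 1); cy <- mean(idx[, 1] - 1)
    dd <- sqrt((cents$x[inside] - cx)^2 + (cents$y[inside] - cy)^2)
    nid <- nid + 1L
    keptMap[lab == cl] <- nid
    rows[[nid]] <- data.frame(
      cluster_id = nid, cluster_area = area,
      cluster_roundness = 4 * pi * area / per^2,
      n_cells_inside = length(inside),
      mean_cell_to_centroid_distance = mean(dd))
  }
  if (nid == 0L) return(empty)
  list(clusters = do.call(rbind, rows), labelMap = keptMap)
}

#' Global (whole-patch) features
#'
#' Concentrations of the three colour planes over the full patch (their
#' sum is 1 by the partition property), whole-patch HSV means, and the
#' stroma pink-filter mean concentration.
#'
#' @param patch an [RGBPatch].
#' @param planes a [ColorPlaneSet] of the same patch.
#' @param pink output of [stromaPinkFilter()] on the same patch.
#' @return named list of global features.
#' @export
globalFeatures <- function(patch, planes, pink) {
  hsv <- toHSV(patch)
  list(global_conc_stroma = mean(planes@ipMask),
       global_conc_background = mean(planes@ibaMask),
       global_conc_nuclei = mean(planes@ibMask),
       global_mean_h = mean(hsv@h), global_mean_s = mean(hsv@s),
       global_mean_v = mean(hsv@v),
       stroma_filter_mean = pink$meanConcentration)
}

.featureColumnNames <- function(windows) {
  nuc <- c("area", "perimeter", "roundness", "eccentricity",
           "centroid_x", "centroid_y", "major_axis", "minor_axis",
           "orientation", "texture_contrast_1", "texture_contrast_2",
           "texture_homogeneity_1", "texture_homogeneity_2",
           "mean_h", "mean_s", "mean_v")
  reg <- unlist(lapply(windows, function(w) {
    paste0(c("conc_stroma", "conc_background", "conc_nuclei",
             "conc_epithelial", "mean_h", "mean_s", "mean_v",
             paste0("hist_h_b", 1:4), paste0("hist_s_b", 1:4),
             paste0("hist_v_b", 1:4)), "_w", w)
  }))
  clu <- c("cluster_area", "cluster_roundness", "cluster_n_cells",
           "cluster_mean_dist")
  glo <- c("global_conc_stroma", "global_conc_background",
           "global_conc_nuclei", "global_mean_h", "global_mean_s",
           "global_mean_v", "stroma_filter_mean")
  c(nuc, reg, clu, glo)
}

# Core table builder reused by extractFeatureTable and the cellularity
# pipeline (which supplies its own segmentation).
.featureTable <- function(patch, hsv, planes, pink, labels, config,
                          patchId, tcLabel) {
  windows <- config$features$windows
  cols <- .featureColumnNames(windows)
  n <- labels@nNuclei
  meta <- data.frame(patch_id = rep(patchId, n),
                     nucleus = seq_len(n))
  if (n == 0) {
    out <- cbind(meta,
                 as.data.frame(matrix(numeric(0), 0, length(cols),
                                      dimnames = list(NULL, cols))))
    out$tc_label <- numeric(0)
    return(out)
  }
  gray <- .luminance(patch@pixels)
  epith <- .fromImage(EBImage::dilate(
    .asImage(planes@ibMask),
    .discKernel(config$features$cytoplasmRadius))) != 0
  satP <- .sat(planes@ipMask); satB <- .sat(planes@ibaMask)
  satN <- .sat(planes@ibMask); satE <- .sat(epith)
  satH <- .sat(hsv@h); satS <- .sat(hsv@s); satV <- .sat(hsv@v)
  qh <- .quantize(hsv@h, 4L); qs <- .quantize(hsv@s, 4L)
  qv <- .quantize(hsv@v, 4L)
  satBins <- lapply(1:4, function(b)
    list(h = .sat(qh == b), s = .sat(qs == b), v = .sat(qv == b)))
  cc <- config$features$cluster
  clus <- detectClusters(planes, labels, closeRadius = cc$closeRadius,
                         openRadius = cc$openRadius, minArea = cc$minArea,
                         minCells = cc$minCells)
  H <- nrow(gray); W <- ncol(gray)
  lab <- labels@labels
  glob <- globalFeatures(patch, planes, pink)
  mat <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  for (i in seq_len(n)) {
    geo <- nucleusMorphology(labels, i)
    tex <- .textureForMask(gray, hsv, lab, i,
                           config$features$textureLevels)
    x <- round(geo$centroid_x); y <- round(geo$centroid_y)
    regvals <- numeric(0)
    for (w in windows) {
      rr <- .windowRange(y, as.integer(w), H)
      cc2 <- .windowRange(x, as.integer(w), W)
      tp <- (rr[2] - rr[1] + 1) * (cc2[2] - cc2[1] + 1)
      g <- function(S) .satSum(S, rr[1], rr[2], cc2[1], cc2[2]) / tp
      hb <- vapply(satBins, function(sb) g(sb$h), 0)
      sb <- vapply(satBins, function(sb2) g(sb2$s), 0)
      vb <- vapply(satBins, function(sb3) g(sb3$v), 0)
      regvals <- c(regvals, g(satP), g(satB), g(satN), g(satE),
                   g(satH), g(satS), g(satV), hb, sb, vb)
    }
    cid <- if (nrow(clus$clusters))
      clus$labelMap[y + 1, x + 1] else 0L
    cf <- if (cid > 0) {
      k <- which(clus$clusters$cluster_id == cid)
      c(clus$clusters$cluster_area[k], clus$clusters$cluster_roundness[k],
        clus$clusters$n_cells_inside[k],
        clus$clusters$mean_cell_to_centroid_distance[k])
    } else c(0, 0, 0, 0)
    mat[i, ] <- c(geo$area, geo$perimeter, geo$roundness,
                  geo$eccentricity, geo$centroid_x, geo$centroid_y,
                  geo$major_axis, geo$minor_axis, geo$orientation,
                  tex$texture_contrast_1, tex$texture_contrast_2,
                  tex$texture_homogeneity_1, tex$texture_homogeneity_2,
                  tex$mean_h, tex$mean_s, tex$mean_v,
                  regvals, cf, unlist(glob, use.names = FALSE))
  }
  out <- cbind(meta, as.data.frame(mat))
  out$tc_label <- rep(tcLabel, n)
  out
}

#' Extract the full per-nucleus feature table of a patch
#'
#' Runs colour separation, nuclei segmentation and all feature
#' extractors, returning one row per segmented nucleus with the
#' per-nucleus geometry/texture block, the regional block replicated at
#' every configured window size (30/60/90/120 px by default), the
#' cluster-membership block (zero sentinels for nuclei outside any
#' cluster, so the table has no missing values) and the global block.
#' Counting the per-window replicates, well over 150 feature values
#' describe each nucleus.
#'
#' @param patch an [RGBPatch].
#' @param config pipeline configuration from [defaultConfig()].
#' @param patchId identifier stored in the `patch_id` column.
#' @param tcLabel optional known cellularity in \[0, 1\] (`NA` if none).
#' @return data.frame; zero nuclei yield a zero-row table with the full
#'   column schema.
#' @export
extractFeatureTable <- function(patch, config = defaultConfig(),
                                patchId = "patch", tcLabel = NA_real_) {
  stopifnot(is(patch, "RGBPatch"))
  hsv <- toHSV(patch)
  planes <- kmeansColorSeparation(patch, k = config$kmeans$k,
                                  seed = config$kmeans$seed)
  pink <- stromaPinkFilter(patch, do.call(pinkFilterConfig,
                                          config$pinkFilter))
  labels <- segmentNuclei(patch,
                          enhancementParams(config$enhance$k1,
                                            config$enhance$k2,
                                            config$enhance$gamma,
                                            config$enhance$medianWindow),
                          minArea = config$segment$minArea,
                          hMaxima = config$segment$hMaxima,
                          minContrast = config$segment$minContrast,
                          minBlueExcess = config$segment$minBlueExcess)
  .featureTable(patch, hsv, planes, pink, labels, config, patchId, tcLabel)
}
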