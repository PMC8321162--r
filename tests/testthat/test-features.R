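labelMapFrom <- function(mask) NucleiLabelMap(mask * 1L)

test_that("morphology of canonical shapes follows hand geometry", {
  m <- matrix(FALSE, 30, 30); m[11:20, 11:20] <- TRUE  # 10x10 square
  geo <- nucleusMorphology(labelMapFrom(m), 1)
  expect_equal(geo$area, 100)
  expect_equal(geo$perimeter, 36)
  expect_equal(geo$roundness, 4 * pi * 100 / 36^2, tolerance = 1e-12)
  expect_equal(geo$centroid_x, mean(10:19))  # 0-based columns
  expect_equal(geo$centroid_y, mean(10:19))

  disc <- ellipseMask(60, 60, 30, 30, 20, 20, 0)
  gd <- nucleusMorphology(labelMapFrom(disc), 1)
  expect_lt(gd$eccentricity, 0.1)
  expect_gt(gd$roundness, 0.9)

  bar <- matrix(FALSE, 60, 60); bar[29:32, 11:50] <- TRUE  # 40x4 bar
  gb <- nucleusMorphology(labelMapFrom(bar), 1)
  expect_gt(gb$eccentricity, 0.9)
  expect_gt(gb$major_axis / gb$minor_axis, 5)
  expect_error(nucleusMorphology(labelMapFrom(bar), 7), "lookup")
})

test_that("moment ellipse recovers known axes and orientation", {
  m <- ellipseMask(60, 60, 30, 30, 12, 8, 30 * pi / 180)
  g <- nucleusMorphology(labelMapFrom(m), 1)
  expect_lt(abs(g$major_axis - 24) / 24, 0.05)
  expect_lt(abs(g$minor_axis - 16) / 16, 0.05)
  expect_lt(min(abs(g$orientation - 30), abs(g$orientation - 30 + 180),
                abs(g$orientation - 30 - 180)), 5)
})

test_that("co-occurrence texture matches hand computation", {
  # constant nucleus: contrast 0, homogeneity 1 at both offsets
  p <- solidPatch(40, 40, c(90, 90, 90))
  m <- matrix(FALSE, 40, 40); m[11:20, 11:20] <- TRUE
  tex <- nucleusTextureHSV(p, labelMapFrom(m), 1)
  expect_equal(tex$texture_contrast_1, 0)
  expect_equal(tex$texture_contrast_2, 0)
  expect_equal(tex$texture_homogeneity_1, 1)
  expect_equal(tex$texture_homogeneity_2, 1)

  # 1-px checkerboard of 0/255: every horizontal pair hops between the
  # extreme quantisation levels 1 and 8, so contrast = 49 and
  # homogeneity = 1/8 at both offsets
  px <- array(0, c(40, 40, 3))
  chk <- outer(1:40, 1:40, function(i, j) (i + j) %% 2 == 0)
  for (ch in 1:3) px[, , ch] <- ifelse(chk, 255, 0)
  tex2 <- nucleusTextureHSV(RGBPatch(px), labelMapFrom(m), 1)
  expect_equal(tex2$texture_contrast_1, 49)
  expect_equal(tex2$texture_homogeneity_1, 1 / 8)
})

test_that("mean HSV inside a pure blue nucleus is the HSV of blue", {
  px <- array(0, c(40, 40, 3))
  for (ch in 1:3) px[, , ch] <- c(230, 160, 200)[ch]
  m <- matrix(FALSE, 40, 40); m[15:24, 15:24] <- TRUE
  px[, , 1][m] <- 0; px[, , 2][m] <- 0; px[, , 3][m] <- 255
  tex <- nucleusTextureHSV(RGBPatch(px), labelMapFrom(m), 1)
  expect_equal(tex$mean_h, 2 / 3, tolerance = 1e-9)
  expect_equal(tex$mean_s, 1)
  expect_equal(tex$mean_v, 1)
})

test_that("regional concentration is the windowed foreground fraction", {
  all_t <- matrix(TRUE, 80, 80)
  expect_equal(regionalConcentration(all_t, c(40, 40), 30), 1)
  expect_equal(regionalConcentration(!all_t, c(40, 40), 30), 0)

  m <- matrix(FALSE, 80, 80)
  # window of 30 centred at (40, 40): rows/cols 26..55 (1-based); fill 450
  m[26:40, 26:55] <- TRUE   # 15 x 30 = 450 of 900
  expect_equal(regionalConcentration(m, c(40, 40), 30), 0.5)
  expect_error(regionalConcentration(m, c(100, 40), 30), "coordinate")
})

test_that("regional concentration matches brute-force counting", {
  for (seed in 1:40) {
    out <- withr::with_seed(seed, {
      m <- matrix(runif(70 * 90) < runif(1), 70, 90)
      ctr <- c(sample(0:89, 1), sample(0:69, 1))
      w <- sample(c(30, 60, 90, 120), 1)
      list(got = regionalConcentration(m, ctr, w),
           want = bruteConcentration(m, ctr, w))
    })
    expect_equal(out$got, out$want)
  }
})

test_that("regional HSV histograms bin and normalise correctly", {
  px <- array(0, c(60, 60, 3))
  px[, , 1] <- 0.1 * 255; px[, , 2] <- 0.1 * 255; px[, , 3] <- 0.1 * 255
  hsv <- toHSV(RGBPatch(px))
  h1 <- regionalHSVHistograms(hsv, c(30, 30), 30)
  expect_equal(h1$hist_v, c(1, 0, 0, 0))

  # window of 30 centred at x = 30 (0-based) spans columns 16..45
  # (1-based): 15 bright columns, 15 dark ones
  px[, 1:30, ] <- 0.9 * 255
  hsv2 <- toHSV(RGBPatch(px))
  h2 <- regionalHSVHistograms(hsv2, c(30, 30), 30)
  expect_equal(h2$hist_v, c(0.5, 0, 0, 0.5))
  expect_equal(sum(h2$hist_h), 1)
  expect_equal(sum(h2$hist_s), 1)
})

test_that("duct clusters are detected with their member nuclei", {
  ph <- generatePhantom(testSpec(size = 192, nBenign = 0, nMalignant = 0,
                                 nDucts = 1, ductCells = c(12, 12),
                                 fatFraction = 0, seed = 21))
  expect_equal(nNuclei(ph), 12L)
  planes <- kmeansColorSeparation(ph@patch, seed = 0)
  res <- detectClusters(planes, ph@labels)
  expect_equal(nrow(res$clusters), 1)
  expect_equal(res$clusters$n_cells_inside, 12)
  expect_gt(res$clusters$cluster_area, 2000)

  blank <- generatePhantom(testSpec(nBenign = 0, nMalignant = 0,
                                    fatFraction = 0, seed = 22))
  planes2 <- kmeansColorSeparation(blank@patch, seed = 0)
  res2 <- detectClusters(planes2, blank@labels)
  expect_equal(nrow(res2$clusters), 0)
})

test_that("cells on a ring report their distance to the cluster centroid", {
  px <- array(0, c(120, 120, 3))
  for (ch in 1:3) px[, , ch] <- c(230, 160, 200)[ch]
  px[1:20, 100:120, ] <- 245   # a white corner so all three roles exist
  lab <- matrix(0L, 120, 120)
  for (k in 0:7) {
    cy <- round(60 + 15 * sin(k * pi / 4)); cx <- round(60 + 15 * cos(k * pi / 4))
    px <- paintDisc(px, cy, cx, 4, c(60, 40, 120))
    for (i in (cy - 4):(cy + 4)) for (j in (cx - 4):(cx + 4))
      if ((i - cy)^2 + (j - cx)^2 <= 16 && lab[i, j] == 0L)
        lab[i, j] <- k + 1L
  }
  p <- RGBPatch(px)
  planes <- kmeansColorSeparation(p, seed = 0)
  res <- detectClusters(planes, NucleiLabelMap(lab), minArea = 500,
                        minCells = 5)
  expect_equal(nrow(res$clusters), 1)
  expect_equal(res$clusters$mean_cell_to_centroid_distance, 15,
               tolerance = 2 / 15)
})

test_that("global concentrations partition and match construction", {
  px <- array(0, c(64, 64, 3))
  for (ch in 1:3) {
    px[, , ch] <- c(245, 245, 245)[ch]
    px[1:32, 1:32, ch] <- c(240, 150, 200)[ch]   # exactly one quarter pink
    px[33:64, 1:32, ch] <- c(60, 40, 120)[ch]
  }
  p <- RGBPatch(px)
  planes <- kmeansColorSeparation(p, seed = 0)
  g <- globalFeatures(p, planes, stromaPinkFilter(p))
  expect_equal(g$global_conc_stroma + g$global_conc_background +
                 g$global_conc_nuclei, 1)
  expect_equal(g$global_conc_stroma, 0.25)
  hsv <- toHSV(p)
  expect_equal(g$global_mean_v, mean(hsv@v))
})

test_that("the feature table has one complete row per nucleus", {
  ph <- generatePhantom(testSpec(nBenign = 8, nMalignant = 4, seed = 31))
  tab <- extractFeatureTable(ph@patch, patchId = "t31", tcLabel = 0.4)
  expect_equal(nrow(tab), nNuclei(segmentNuclei(ph@patch)))
  expect_gte(nrow(tab), 10)   # segmentability of the phantom
  featCols <- setdiff(names(tab), c("patch_id", "nucleus", "tc_label"))
  expect_gte(length(featCols), 102)
  expect_false(anyNA(tab[, featCols]))
  expect_true(all(tab$tc_label == 0.4))
  # concentrations and histogram bins are fractions
  concCols <- grep("^conc_|^hist_|^global_conc", featCols, value = TRUE)
  expect_true(all(tab[, concCols] >= 0 & tab[, concCols] <= 1))
  hsums <- rowSums(tab[, paste0("hist_h_b", 1:4, "_w30")])
  expect_equal(hsums, rep(1, nrow(tab)), tolerance = 1e-9)
})

test_that("an empty patch yields an empty but well-formed table", {
  blank <- generatePhantom(testSpec(nBenign = 0, nMalignant = 0,
                                    fatFraction = 0.05, seed = 32))
  tab <- extractFeatureTable(blank@patch)
  expect_equal(nrow(tab), 0)
  expect_true(all(c("area", "conc_nuclei_w30", "global_conc_stroma",
                    "stroma_filter_mean") %in% names(tab)))
})

test_that("small windows track local structure better than large ones", {
  ph <- generatePhantom(testSpec(size = 192, nBenign = 0, nMalignant = 0,
                                 nDucts = 1, ductCells = c(12, 12),
                                 fatFraction = 0, seed = 33))
  nucMask <- labelMatrix(ph) > 0
  cents <- which(ph@ductLabels > 0, arr.ind = TRUE)
  ctr <- c(mean(cents[, 2]) - 1, mean(cents[, 1]) - 1)
  r30 <- regionalConcentration(nucMask, ctr, 30)
  r120 <- regionalConcentration(nucMask, ctr, 120)
  expect_gt(r30, r120)
})
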