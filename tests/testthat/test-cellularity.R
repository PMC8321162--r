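test_that("TC from masks is the dilated coverage fraction", {
  empty <- computeTCFromMasks(matrix(FALSE, 50, 50), 10)
  expect_equal(tcValue(empty), 0)
  full <- computeTCFromMasks(matrix(TRUE, 50, 50), 5)
  expect_equal(tcValue(full), 1)

  seed <- matrix(FALSE, 100, 100); seed[50, 50] <- TRUE
  res <- computeTCFromMasks(seed, 10)
  want <- bruteDilate(seed, 10)
  expect_equal(tcValue(res), mean(want))
  expect_identical(unname(malignantMask(res)), unname(want))
  expect_equal(sum(want), 317)   # lattice points of a radius-10 disc
})

test_that("dilation-based TC matches brute force on random masks", {
  for (seed in 1:3) {
    m <- withr::with_seed(seed, matrix(runif(40 * 40) < 0.02, 40, 40))
    for (r in c(0, 3, 6)) {
      expect_equal(tcValue(computeTCFromMasks(m, r)),
                   mean(bruteDilate(m, r)))
    }
  }
})

test_that("TC is monotone in the dilation radius", {
  m <- withr::with_seed(5, matrix(runif(60 * 60) < 0.01, 60, 60))
  tcs <- vapply(0:8, function(r) tcValue(computeTCFromMasks(m, r)), 0)
  expect_true(all(diff(tcs) >= 0))
})

test_that("oracle-classified phantoms recover the planted TC", {
  ph <- generatePhantom(testSpec(size = 192, nBenign = 10, nMalignant = 8,
                                 seed = 61))
  seg <- segmentNuclei(ph@patch)
  m <- matchToGroundTruth(seg, ph)
  res <- estimateCellularity(ph@patch, classes = m$class, patchId = "x")
  expect_lt(abs(tcValue(res) - tcValue(ph)), 0.03)
  expect_equal(res@nNuclei, nNuclei(seg))

  benignOnly <- generatePhantom(testSpec(nBenign = 15, nMalignant = 0,
                                         seed = 62))
  seg2 <- segmentNuclei(benignOnly@patch)
  m2 <- matchToGroundTruth(seg2, benignOnly)
  expect_equal(tcValue(estimateCellularity(benignOnly@patch,
                                           classes = m2$class)), 0)
})

test_that("a patch without nuclei scores zero cellularity", {
  blank <- generatePhantom(testSpec(nBenign = 0, nMalignant = 0, seed = 63))
  res <- estimateCellularity(blank@patch, classes = character())
  expect_equal(tcValue(res), 0)
  expect_equal(res@nNuclei, 0L)
  expect_equal(res@nMalignant, 0L)
})

test_that("batch processing is robust and byte-reproducible", {
  dir <- file.path(tempdir(), "batchTC")
  dir.create(dir, showWarnings = FALSE)
  on.exit(unlink(dir, recursive = TRUE))
  phs <- lapply(1:4, function(i)
    generatePhantom(testSpec(size = 128, nBenign = 6, nMalignant = 3,
                             seed = 70 + i)))
  for (i in seq_along(phs))
    writePatch(phs[[i]]@patch, file.path(dir, sprintf("p%02d.png", i)))
  writeLines("not an image", file.path(dir, "p99.png"))   # corrupt file

  train <- phantomTrainingData(phs[1:2])
  mod <- trainClassifier(train$table, train$classes, "knn", seed = 1,
                         cvFolds = 0)
  out1 <- file.path(dir, "run1.csv"); out2 <- file.path(dir, "run2.csv")
  expect_message(batchProcess(dir, mod, outFile = out1), "skipping")
  res <- read.csv(out1)
  expect_equal(nrow(res), 4)
  expect_equal(res$patch_id, sort(res$patch_id))
  suppressMessages(batchProcess(dir, mod, outFile = out2))
  expect_identical(readBin(out1, "raw", file.size(out1)),
                   readBin(out2, "raw", file.size(out2)))
})

test_that("an empty directory warns and returns an empty table", {
  dir <- file.path(tempdir(), "emptyTC")
  dir.create(dir, showWarnings = FALSE)
  on.exit(unlink(dir, recursive = TRUE))
  expect_warning(out <- batchProcess(dir, NULL), "empty")
  expect_equal(nrow(out), 0)
})

test_that("evaluation reports MSE and intraclass correlation", {
  x <- seq(0, 1, length.out = 50)
  perfect <- evaluateAgainstReference(x, x)
  expect_equal(perfect$mse, 0)
  expect_equal(perfect$icc, 1)

  ref <- rep(seq(0, 1, by = 0.1), length.out = 500)
  pred <- withr::with_seed(82, ref + rnorm(500, 0, 0.05))
  ev <- evaluateAgainstReference(pred, ref)
  expect_equal(ev$mse, 0.0025, tolerance = 0.2)
  expect_gt(ev$icc, 0.9)
  expect_true(all(c("level", "median") %in% names(ev$byLevel)))

  perm <- withr::with_seed(83, sample(ref))
  expect_lt(abs(evaluateAgainstReference(perm, ref)$icc), 0.15)
  expect_error(evaluateAgainstReference(1, 1), "insufficient")
})

test_that("ICC(2,1) and its bounds match an independent implementation", {
  # frozen from the pingouin ICC(A,1) implementation on this fixture
  x <- c(0.05, 0.12, 0.23, 0.31, 0.38, 0.52, 0.58, 0.67, 0.74, 0.81,
         0.93, 0.99)
  y <- c(0.10, 0.08, 0.30, 0.25, 0.45, 0.49, 0.50, 0.72, 0.70, 0.88,
         0.86, 1.00)
  icc <- patchCellularity:::.icc21(x, y)
  expect_equal(unname(icc["icc"]), 0.983201, tolerance = 1e-6)
  expect_equal(unname(icc["lower"]), 0.9427279, tolerance = 1e-6)
  expect_equal(unname(icc["upper"]), 0.9951376, tolerance = 1e-6)
})

test_that("predictions merge with references by patch id", {
  pred <- data.frame(patch_id = c("a", "b", "c"), tc = c(0.1, 0.5, 0.9))
  ref <- data.frame(patch_id = c("c", "b", "a"), tc = c(0.8, 0.5, 0.2))
  ev <- evaluateAgainstReference(pred, ref)
  expect_equal(ev$n, 3)
  expect_equal(ev$mse, mean(c(0.1 - 0.2, 0, 0.9 - 0.8)^2))
})
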