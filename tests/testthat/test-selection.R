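test_that("aggregation summarises each cellularity level", {
  tc <- rep(seq(0, 1, by = 0.1), each = 5)
  tab <- data.frame(patch_id = "a", nucleus = seq_along(tc),
                    f_const = 5, f_ident = tc, tc_label = tc)
  agg <- aggregateByTC(tab)
  cst <- agg[agg$feature == "f_const", ]
  expect_true(all(cst$mean == 5) && all(cst$sd == 0))
  idf <- agg[agg$feature == "f_ident", ]
  expect_equal(idf$mean, sort(unique(round(tc * 10) / 10)))
  expect_error(aggregateByTC(data.frame(
    patch_id = "a", nucleus = 1:4, f = 1:4,
    tc_label = c(0, 0, 0.1, 0.1))), "insufficient")
})

test_that("level means of a noisy linear feature stay near the truth", {
  tab <- selectionTable(101, nInfo = 1, nNoise = 0, rowsPerLevel = 100)
  agg <- aggregateByTC(tab, "info_1")
  expect_true(all(abs(agg$mean - 10 * agg$level) < 0.3))
})

test_that("correlation and slope are exact for linear features", {
  tc <- rep(seq(0, 1, by = 0.1), each = 3)
  tab <- data.frame(patch_id = "a", nucleus = seq_along(tc),
                    up = 2 * tc + 1, down = -3 * tc, flat = 7,
                    tc_label = tc)
  corr <- correlateFeaturesToTC(aggregateByTC(tab))
  expect_equal(corr$r[corr$feature == "up"], 1)
  expect_equal(corr$slope[corr$feature == "up"], 2)
  expect_equal(corr$r[corr$feature == "down"], -1)
  expect_equal(corr$r[corr$feature == "flat"], 0)
  expect_true(corr$zero_variance[corr$feature == "flat"])
})

test_that("level-mean correlation matches the Pearson formula to 1e-12", {
  tab <- selectionTable(55, nInfo = 2, nNoise = 2, rowsPerLevel = 10)
  agg <- aggregateByTC(tab)
  corr <- correlateFeaturesToTC(agg)
  for (f in corr$feature) {
    s <- agg[agg$feature == f, ]
    x <- s$level; y <- s$mean
    rBrute <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(corr$r[corr$feature == f], rBrute, tolerance = 1e-12)
  }
})

test_that("a permuted feature rarely correlates strongly over 11 levels", {
  tab <- selectionTable(77, nInfo = 1, nNoise = 0, rowsPerLevel = 30)
  tab$info_1 <- withr::with_seed(78, sample(tab$info_1))
  corr <- correlateFeaturesToTC(aggregateByTC(tab))
  expect_lt(abs(corr$r), 0.7)
})

test_that("the lasso finds the informative needle among noise", {
  tab <- selectionTable(5, nInfo = 1, nNoise = 49, rowsPerLevel = 20,
                        slope = 1, noiseSd = 0.05)
  sel <- lassoSelect(tab, seed = 3)
  expect_true("info_1" %in% sel)

  noise <- selectionTable(6, nInfo = 0, nNoise = 30, rowsPerLevel = 20)
  expect_lte(length(lassoSelect(noise, seed = 3)), 3)
})

test_that("exactly the planted linear features are selected", {
  tab <- selectionTable(11)
  res <- selectKeyParameters(tab, seed = 2)
  kept <- res@perFeature$feature[res@perFeature$kept]
  expect_setequal(kept, paste0("info_", 1:5))
  expect_equal(res@nSelected, 5L)
  # ordering is by decreasing |r|
  expect_true(all(diff(abs(res@perFeature$r)) <= 1e-12))
  # every kept feature satisfies both rules
  pf <- res@perFeature
  expect_true(all(abs(pf$r[pf$kept]) >= 0.80 & pf$lasso[pf$kept]))
})

test_that("the 0.80 threshold is enforced exactly", {
  # craft a feature whose level-mean correlation sits just under 0.80
  lv <- seq(0, 1, by = 0.1)
  bump <- c(0, 1, -1, 1, -1, 1, -1, 1, -1, 1, 0)
  f <- function(amp) cor(lv, lv + amp * bump)
  amp <- uniroot(function(a) f(a) - 0.79, c(0, 2), tol = 1e-12)$root
  tc <- rep(lv, each = 3)
  tab <- data.frame(patch_id = "a", nucleus = seq_along(tc),
                    borderline = rep(lv + amp * bump, each = 3),
                    strong = tc, tc_label = tc)
  res <- suppressWarnings(selectKeyParameters(tab, seed = 1))
  pf <- res@perFeature
  expect_equal(pf$r[pf$feature == "borderline"], 0.79, tolerance = 1e-9)
  expect_false(pf$kept[pf$feature == "borderline"])
  expect_true(pf$kept[pf$feature == "strong"])
})

test_that("an exact duplicate feature is pruned as redundant", {
  tab <- selectionTable(13, nInfo = 1, nNoise = 10, rowsPerLevel = 30)
  tab$info_copy <- tab$info_1
  res <- selectKeyParameters(tab, seed = 4)
  pf <- res@perFeature
  expect_lte(sum(pf$kept[pf$feature %in% c("info_1", "info_copy")]), 1)
})

test_that("selection is invariant to affine feature rescaling", {
  tab <- selectionTable(17)
  res1 <- selectKeyParameters(tab, seed = 9)
  tab2 <- tab
  tab2$info_2 <- 1000 * tab2$info_2 + 50
  tab2$noise_3 <- -0.001 * tab2$noise_3
  res2 <- selectKeyParameters(tab2, seed = 9)
  expect_identical(res1@perFeature$kept, res2@perFeature$kept)
  expect_equal(res1@perFeature$r, res2@perFeature$r *
                 ifelse(res2@perFeature$feature == "noise_3", -1, 1),
               tolerance = 1e-9)
})

test_that("the canonical manifest names 22 feature-table columns", {
  ks <- keyParameterSet()
  expect_length(ks, 22)
  expect_length(unique(ks), 22)
  expect_true(all(ks %in% patchCellularity:::.featureColumnNames(
    c(30, 60, 90, 120))))
})

test_that("selection results round-trip through CSV and manifest", {
  tab <- selectionTable(19, nInfo = 2, nNoise = 5)
  res <- selectKeyParameters(tab, seed = 1)
  csv <- tempfile(fileext = ".csv"); man <- tempfile()
  writeSelection(res, csv, man)
  back <- read.csv(csv)
  expect_equal(back$feature, res@perFeature$feature)
  expect_equal(readLines(man),
               res@perFeature$feature[res@perFeature$kept])
})
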