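test_that("background and tissue brightness strictly straddle 220", {
  # noiseless case: the contract is exact
  spec <- syntheticSpec(imageSize = c(448, 448), backgroundFraction = 0.3,
                        noiseSd = 0, seed = 2)
  sim <- generateSyntheticSlide(spec, grade = 2)
  b <- brightness(sim$image)
  expect_true(all(b[sim$truth$backgroundMask] > 220))
  expect_true(all(b[!sim$truth$backgroundMask] <= 220))

  # and it still holds under noise by construction (clamped fields)
  spec8 <- syntheticSpec(imageSize = c(448, 448), backgroundFraction = 0.3,
                         noiseSd = 8, seed = 2)
  sim8 <- generateSyntheticSlide(spec8, grade = 2)
  b8 <- brightness(sim8$image)
  expect_true(all(b8[sim8$truth$backgroundMask] > 220))
  expect_true(all(b8[!sim8$truth$backgroundMask] <= 220))
})

test_that("all-background and all-tissue edge cases behave as specified", {
  zeroEffect <- matrix(0, 4, 12)
  allBg <- syntheticSpec(imageSize = c(448, 448), backgroundFraction = 1,
                         featureEffect = zeroEffect, seed = 5)
  sim <- generateSyntheticSlide(allBg, grade = 0)
  expect_true(all(sim$truth$backgroundMask))
  fg <- filterForeground(tileImage(sim$image, 224))
  expect_equal(length(fg), 0L)

  # demanding planted features with no tissue is an error
  withFx <- syntheticSpec(imageSize = c(448, 448), backgroundFraction = 1,
                          seed = 5)
  expect_error(generateSyntheticSlide(withFx, grade = 3), "no tissue")

  allTissue <- syntheticSpec(imageSize = c(448, 448), backgroundFraction = 0,
                             noiseSd = 0, seed = 5)
  sim2 <- generateSyntheticSlide(allTissue, grade = 1)
  expect_true(all(brightness(sim2$image) <= 220))
  expect_equal(length(filterForeground(tileImage(sim2$image, 224))), 4L)
})

test_that("patch exclusion matches brute-force pixel counting on the mask", {
  spec <- syntheticSpec(imageSize = c(1120, 1120), patchSize = 224,
                        backgroundFraction = 0.25, seed = 7)
  sim <- generateSyntheticSlide(spec, grade = 1)
  ps <- tileImage(sim$image, 224, "s7")
  expect_equal(length(ps), 25L)
  # oracle: per-patch pixel count on the returned truth mask
  m <- manifest(ps)
  oracleFrac <- vapply(seq_len(nrow(m)), function(i) {
    ys <- m$y0[i] + 1:224; xs <- m$x0[i] + 1:224
    mean(sim$truth$backgroundMask[ys, xs])
  }, numeric(1))
  expect_equal(m$background_fraction, oracleFrac)
  keptOracle <- which(oracleFrac <= 0.5)
  kept <- which(m$background_fraction <= 0.5)
  expect_equal(kept, keptOracle)
  expect_equal(length(filterForeground(ps)), length(keptOracle))
})

test_that("generator is deterministic under identical spec and seed", {
  spec <- syntheticSpec(imageSize = c(448, 448), seed = 13)
  a <- generateSyntheticSlide(spec, grade = 3)
  b <- generateSyntheticSlide(spec, grade = 3)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)

  p1 <- generateFeaturePatch(4, present = TRUE, seed = 99)
  p2 <- generateFeaturePatch(4, present = TRUE, seed = 99)
  expect_identical(p1, p2)
  expect_error(generateFeaturePatch(13, TRUE, 1), "1..12")
})

test_that("motif statistic separates present from absent patches", {
  # absent case sits far below the planted amplitude
  expect_lt(motifStatistic(generateFeaturePatch(2, FALSE, 11), 2), 15)

  nEach <- 200
  present <- vapply(seq_len(nEach), function(i)
    motifStatistic(generateFeaturePatch(7, TRUE, 3000 + i, size = 96), 7),
    numeric(1))
  absent <- vapply(seq_len(nEach), function(i)
    motifStatistic(generateFeaturePatch(7, FALSE, 6000 + i, size = 96), 7),
    numeric(1))
  acc <- (sum(present > 15) + sum(absent <= 15)) / (2 * nEach)
  expect_gte(acc, 0.95)
})

test_that("annotated patch pool carries per-feature flags it plants", {
  pool <- generateAnnotatedPatchPool(30, prevalence = 0.5, seed = 8,
                                     size = 96)
  expect_equal(dim(pool$flags), c(30L, 12L))
  # demodulated amplitude tracks the flag for a mid-frequency feature
  stats <- vapply(seq_len(30), function(i)
    motifStatistic(pool$images[[i]], 5), numeric(1))
  expect_true(all(stats[pool$flags[, 5] == 1] >
                  max(stats[pool$flags[, 5] == 0])))
})

test_that("score tables are drawn from the exact cumulative-logit law", {
  # score-independent model: grades uniform
  m0 <- ordinalFusionModel(qlogis(c(0.25, 0.5, 0.75)), rep(0, 12))
  tab <- generateScoreTable(m0, 10000, seed = 3)
  freq <- tabulate(tab$grades + 1L, 4) / 10000
  expect_true(all(abs(freq - 0.25) < 3 * sqrt(0.25 * 0.75 / 10000) + 0.005))

  # single draw reproducible
  one <- generateScoreTable(m0, 1, seed = 9)
  two <- generateScoreTable(m0, 1, seed = 9)
  expect_identical(one, two)

  # single informative feature: empirical cumulative frequencies by score
  # bin agree with the closed-form probabilities
  m1 <- ordinalFusionModel(c(-1, 0, 1), c(-0.04, rep(0, 11)))
  tab1 <- generateScoreTable(m1, 10000, seed = 4)
  bins <- cut(tab1$scores[, 1], c(0, 25, 50, 75, 100), include.lowest = TRUE)
  for (lev in levels(bins)) {
    sel <- bins == lev
    if (sum(sel) < 100) next
    midScore <- mean(tab1$scores[sel, 1])
    for (n in 0:2) {
      closed <- plogis(m1@alphas[n + 1] - 0.04 * midScore)
      emp <- mean(tab1$grades[sel] <= n)
      expect_lt(abs(emp - closed), 0.06)  # Monte-Carlo + binning slack
    }
  }
  expect_error(generateScoreTable(m0, 0, seed = 1), "nSlides")
})

test_that("synthetic slides round-trip to disk as PNG + JSON truth", {
  dir <- withr::local_tempdir()
  sim <- generateSyntheticSlide(
    syntheticSpec(imageSize = c(448, 448), seed = 6), grade = 2)
  paths <- writeSyntheticSlide(sim, dir, "s1")
  expect_true(all(file.exists(paths)))
  back <- readImageFile(paths[["image"]])
  expect_equal(back, sim$image)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$grade, 2L)
  expect_equal(dim(truth$patch_feature_flags), dim(sim$truth$patchFeatureFlags))
})
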