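test_that("dataset splitting uses largest-remainder sizes and is seeded", {
  sp <- splitDataset(seq_len(100), c(0.6, 0.15, 0.25), seed = 1)
  expect_equal(lengths(sp), c(train = 60L, val = 15L, test = 25L))
  all3 <- sort(unname(unlist(sp)))
  expect_equal(all3, 1:100)   # exhaustive and disjoint

  sp3 <- splitDataset(1:3, c(0.6, 0.15, 0.25), seed = 2)
  expect_equal(lengths(sp3), c(train = 2L, val = 0L, test = 1L))
  expect_setequal(unlist(sp3), 1:3)

  a <- splitDataset(1:1000, seed = 7)
  b <- splitDataset(1:1000, seed = 7)
  expect_identical(a, b)
  c <- splitDataset(1:1000, seed = 8)
  expect_false(identical(attr(a, "indices"), attr(c, "indices")))

  expect_error(splitDataset(1:2), "at least 3")
})

test_that("training selects the minimum-validation-loss epoch", {
  tr <- toyDataset(24, 100)
  va <- toyDataset(8, 900)
  cfg <- trainConfig(learningRate = 0.05, batchSize = 16, maxEpochs = 20,
                     seed = 5)
  h <- trainClassifier(tr, va, cfg)
  hist <- h@metadata$history
  expect_equal(nrow(hist), 20L)
  # selection rule: reported snapshot's val loss is the history minimum,
  # earliest epoch on ties
  expect_equal(h@metadata$selected_epoch,
               which(hist$val_loss == min(hist$val_loss))[1])
  # a learnable toy improves on the first epoch
  expect_lt(min(hist$val_loss), hist$val_loss[1])

  # single-epoch budget selects epoch 1
  h1 <- trainClassifier(tr, va, trainConfig(learningRate = 0.05,
                                            batchSize = 16, maxEpochs = 1,
                                            seed = 5))
  expect_equal(h1@metadata$selected_epoch, 1L)

  # degenerate single-class training set is rejected
  bad <- patchDataset(tr$images[1:10], rep(1L, 10))
  expect_error(trainClassifier(bad, va, cfg), "degenerate")
})

test_that("the feature-detector protocol variant is config-only", {
  cfg <- trainConfig(learningRate = 1e-6, maxEpochs = 200)
  expect_equal(cfg$learningRate, 1e-6)
  expect_equal(cfg$maxEpochs, 200L)
  expect_error(trainConfig(optimizer = "adam"), "rmsprop")
  expect_error(trainConfig(splitFractions = c(0.5, 0.5, 0.5)))
})

test_that("prediction is deterministic, ordered and normalized", {
  tr <- toyDataset(16, 300)
  va <- toyDataset(6, 700)
  h <- trainClassifier(tr, va, trainConfig(learningRate = 0.05,
                                           batchSize = 16, maxEpochs = 10,
                                           seed = 9))
  p1 <- toyPatch(TRUE, 1); p2 <- toyPatch(FALSE, 2)
  P <- predictScores(h, list(p1, p2, p1))
  expect_equal(dim(P), c(3L, 2L))
  expect_equal(rowSums(P), rep(1, 3), tolerance = 1e-9)
  expect_identical(P[1, ], P[3, ])    # duplicated patch, identical rows
  expect_equal(nrow(predictScores(h, list())), 0L)

  # stub contract: constant model emits its fixed vector for every patch
  stub <- constantClassifier(c(0.2, 0.3, 0.5))
  Ps <- predictScores(stub, list(p1, p2))
  expect_equal(Ps, matrix(c(0.2, 0.3, 0.5), 2, 3, byrow = TRUE))
})

test_that("trained detectors beat chance by a wide margin on 4 grades", {
  # grade-labeled multi-motif patches: prevalence row of the grade
  eff <- defaultFeatureEffect()
  images <- list(); labels <- integer(0); k <- 0L
  for (g in 0:3) {
    pool <- generateAnnotatedPatchPool(60, prevalence = eff[g + 1, ],
                                       seed = 50 + g, size = 128)
    for (i in seq_len(60)) { k <- k + 1L; images[[k]] <- pool$images[[i]] }
    labels <- c(labels, rep(g, 60))
  }
  sp <- splitDataset(seq_along(images), c(0.6, 0.15, 0.25), seed = 4)
  h <- trainClassifier(patchDataset(images[sp$train], labels[sp$train]),
                       patchDataset(images[sp$val], labels[sp$val]),
                       trainConfig(learningRate = 0.02, batchSize = 40,
                                   maxEpochs = 30, seed = 6))
  P <- predictScores(h, images[sp$test])
  acc <- mean(max.col(P, ties.method = "last") - 1L == labels[sp$test])
  expect_gte(acc, 0.50)   # chance is 0.25
})

test_that("grid search ranks a planted-better configuration first", {
  tr <- toyDataset(30, 4000)
  oneCfg <- trainConfig(learningRate = 0.05, batchSize = 16,
                        maxEpochs = 8, seed = 3)
  tab1 <- gridSearch(tr$images, tr$labels, list(oneCfg))
  expect_equal(nrow(tab1), 1L)
  expect_true(is.na(tab1$error[1]))

  # an untrainable configuration (tiny learning rate) cannot beat a
  # trainable one; both rows must be populated and ordering correct
  cfgGood <- trainConfig(learningRate = 0.05, batchSize = 16,
                         maxEpochs = 10, seed = 3)
  cfgBad <- trainConfig(learningRate = 1e-9, batchSize = 16,
                        maxEpochs = 10, seed = 3)
  tab <- gridSearch(tr$images, tr$labels, list(cfgGood, cfgBad))
  expect_equal(nrow(tab), 2L)
  expect_false(any(is.na(tab$test_accuracy)))
  expect_equal(tab$learning_rate[1], 0.05)
  expect_true(all(diff(tab$test_accuracy) <= 0))

  # determinism of the whole sweep
  tabR <- gridSearch(tr$images, tr$labels, list(cfgGood, cfgBad))
  expect_equal(tab$test_accuracy, tabR$test_accuracy)
})

test_that("classifier checkpoints round-trip through a text directory", {
  tr <- toyDataset(16, 600)
  va <- toyDataset(6, 800)
  h <- trainClassifier(tr, va, trainConfig(learningRate = 0.05,
                                           batchSize = 16, maxEpochs = 5,
                                           seed = 2))
  dir <- withr::local_tempdir()
  saveClassifier(h, dir)
  back <- loadClassifier(dir)
  probe <- list(toyPatch(TRUE, 42), toyPatch(FALSE, 43))
  expect_equal(predictScores(back, probe), predictScores(h, probe),
               tolerance = 1e-12)
  expect_equal(back@metadata$selected_epoch, h@metadata$selected_epoch)
})
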