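test_that("macro metrics match exhaustive confusion and rank oracles", {
  # perfect calibrated predictor
  yT <- rep(0:3, each = 5)
  probsPerfect <- matrix(0, 20, 4)
  probsPerfect[cbind(1:20, yT + 1)] <- 1
  rp <- macroMetrics(yT, yT, probsPerfect)
  expect_equal(unname(metrics(rp)), rep(1, 4))

  # constant predictor on balanced data: macro sensitivity 0.25
  rc <- macroMetrics(yT, rep(2L, 20), NULL)
  expect_equal(metrics(rc)[["sensitivity"]], 0.25)

  # random instance vs independent brute force
  set.seed(77)
  n <- 50
  yTrue <- sample(0:3, n, replace = TRUE)
  yPred <- sample(0:3, n, replace = TRUE)
  probs <- matrix(rgamma(n * 4, 1), n); probs <- probs / rowSums(probs)
  rep <- macroMetrics(yTrue, yPred, probs)
  accs <- sens <- specs <- aucs <- numeric(4)
  for (c in 0:3) {
    tp <- sum(yTrue == c & yPred == c); fn <- sum(yTrue == c & yPred != c)
    fp <- sum(yTrue != c & yPred == c); tn <- sum(yTrue != c & yPred != c)
    accs[c + 1] <- (tp + tn) / n
    sens[c + 1] <- tp / (tp + fn)
    specs[c + 1] <- tn / (tn + fp)
    # exhaustive pairwise rank comparison with midrank ties
    pos <- which(yTrue == c); neg <- which(yTrue != c)
    wins <- 0
    for (i in pos) for (j in neg) {
      wins <- wins + (probs[i, c + 1] > probs[j, c + 1]) +
        0.5 * (probs[i, c + 1] == probs[j, c + 1])
    }
    aucs[c + 1] <- wins / (length(pos) * length(neg))
  }
  expect_equal(metrics(rep)[["accuracy"]], mean(accs), tolerance = 1e-12)
  expect_equal(metrics(rep)[["sensitivity"]], mean(sens), tolerance = 1e-12)
  expect_equal(metrics(rep)[["specificity"]], mean(specs), tolerance = 1e-12)
  expect_equal(metrics(rep)[["auc"]], mean(aucs), tolerance = 1e-12)
})

test_that("per-class AUC agrees with pROC and negation symmetry holds", {
  skip_if_not_installed("pROC")
  set.seed(5)
  y <- rbinom(80, 1, 0.4)
  s <- runif(80)
  mine <- oedgrader:::midrankAUC(s, y == 1)
  ref <- suppressMessages(as.numeric(pROC::auc(y, s, direction = "<")))
  expect_equal(mine, ref, tolerance = 1e-12)
  expect_equal(oedgrader:::midrankAUC(-s, y == 1), 1 - mine,
               tolerance = 1e-12)
})

test_that("macro metrics are invariant under joint class relabeling", {
  set.seed(19)
  yT <- sample(0:3, 60, replace = TRUE)
  yP <- sample(0:3, 60, replace = TRUE)
  base <- macroMetrics(yT, yP, NULL)
  perm <- c(2L, 0L, 3L, 1L)
  rel <- macroMetrics(perm[yT + 1], perm[yP + 1], NULL)
  expect_equal(metrics(rel)[["accuracy"]], metrics(base)[["accuracy"]])
  expect_equal(metrics(rel)[["sensitivity"]], metrics(base)[["sensitivity"]])
  expect_equal(metrics(rel)[["specificity"]], metrics(base)[["specificity"]])
})

test_that("absent classes are excluded from the macro with a warning", {
  yT <- rep(c(0L, 1L), 10)    # grades 2 and 3 never occur
  yP <- rep(c(0L, 1L), 10)
  expect_warning(rep <- macroMetrics(yT, yP, NULL), "absent")
  expect_equal(metrics(rep)[["sensitivity"]], 1)  # over present classes only
})

test_that("bootstrap percentile interval matches the closed-form SE", {
  withr::with_seed(2, x <- rbinom(1000, 1, 0.37))
  ci <- bootstrapCI(mean, x, nBoot = 2000, seed = 11)
  phat <- mean(x)
  se <- sqrt(phat * (1 - phat) / 1000)
  expect_lt(abs(ci[1] - (phat - 1.96 * se)), 0.02)
  expect_lt(abs(ci[2] - (phat + 1.96 * se)), 0.02)

  # constant statistic collapses the interval
  cc <- bootstrapCI(function(s) 0.5, x, nBoot = 200, seed = 1)
  expect_equal(cc, c(0.5, 0.5))

  # determinism under the seed
  expect_identical(bootstrapCI(mean, x, nBoot = 500, seed = 3),
                   bootstrapCI(mean, x, nBoot = 500, seed = 3))
  expect_error(bootstrapCI(mean, numeric(0)), "empty")
  expect_error(bootstrapCI(mean, x, nBoot = 10), "100")
})

test_that("bootstrap intervals cover a known accuracy at nominal rate", {
  # 200 simulated balanced datasets with true accuracy 0.7
  hits <- 0L
  withr::with_seed(4, {
    for (r in 1:200) {
      correct <- rbinom(100, 1, 0.7)
      ci <- bootstrapCI(mean, correct, nBoot = 200, seed = r)
      if (ci[1] <= 0.7 && 0.7 <= ci[2]) hits <- hits + 1L
    }
  })
  expect_gte(hits / 200, 0.90)   # nominal 95% with Monte-Carlo slack
})

test_that("prediction evaluation attaches intervals containing the point", {
  set.seed(9)
  yT <- rep(0:3, each = 15)
  yP <- ifelse(runif(60) < 0.7, yT, sample(0:3, 60, replace = TRUE))
  probs <- matrix(rgamma(240, 1), 60); probs <- probs / rowSums(probs)
  for (i in 1:60) probs[i, yP[i] + 1] <- probs[i, yP[i] + 1] + 1
  probs <- probs / rowSums(probs)
  repE <- evaluatePredictions(yT, yP, probs, nBoot = 200, seed = 21)
  ci <- metricCI(repE)
  expect_setequal(names(ci),
                  c("accuracy", "sensitivity", "specificity", "auc"))
  for (nm in names(ci)) {
    expect_lte(ci[[nm]][1], metrics(repE)[[nm]])
    expect_gte(ci[[nm]][2], metrics(repE)[[nm]])
  }
})

test_that("feature-model summary takes the even-count median", {
  reports <- featurePerformanceReports()
  s <- summarizeFeatureModels(reports)
  # middle-two means of the bundled table
  accs <- sort(vapply(reports, function(r) metrics(r)[["accuracy"]],
                      numeric(1)))
  expect_equal(s$median_accuracy, mean(accs[6:7]))

  same <- lapply(1:12, function(i) evalReport(accuracy = 0.5, auc = 0.5))
  s2 <- summarizeFeatureModels(same)
  expect_equal(s2$median_accuracy, 0.5)
  expect_equal(s2$median_auc, 0.5)

  expect_error(summarizeFeatureModels(same[1:11]), "12")
  missing <- c(same[1:11], list(evalReport(accuracy = 0.5)))
  expect_error(summarizeFeatureModels(missing), "missing")
})
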