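test_that("cumulative probabilities match hand-computed inverse logits", {
  # threshold-only model: scores are irrelevant
  m0 <- ordinalFusionModel(qlogis(c(0.25, 0.5, 0.75)), rep(0, 12))
  expect_equal(cumulativeProbs(m0, runif(12, 0, 100)), rep(0.25, 4),
               tolerance = 1e-12)

  # hand oracle: alpha = (-1, 0, 1), beta_1 = 0.02, score_1 = 50 -> eta = 1
  m1 <- ordinalFusionModel(c(-1, 0, 1), c(0.02, rep(0, 11)))
  p <- cumulativeProbs(m1, c(50, rep(0, 11)))
  cum <- plogis(c(0, 1, 2))
  expect_equal(p, c(cum[1], diff(cum), 1 - cum[3]), tolerance = 1e-12)

  # sign convention: beta . scores -> +Inf pushes all mass to grade 0
  mBig <- ordinalFusionModel(c(-1, 0, 1), c(0.5, rep(0, 11)))
  pBig <- cumulativeProbs(mBig, c(100, rep(0, 11)))
  expect_gt(pBig[1], 0.999999)

  expect_error(ordinalFusionModel(c(1, 0, 2), rep(0, 12)), "increasing")
})

test_that("grade probabilities normalize and respect proportional odds", {
  set.seed(41)
  for (i in 1:1000) {
    m <- randomFusionModel()
    p <- cumulativeProbs(m, runif(12, 0, 100))
    expect_true(all(p >= 0))
    expect_lt(abs(sum(p) - 1), 1e-9)
  }

  # monotonicity: raising a score with beta_j > 0 never lowers any
  # cumulative probability
  set.seed(42)
  for (i in 1:50) {
    m <- randomFusionModel()
    j <- which.max(m@betas)
    s <- runif(12, 0, 100)
    s2 <- s; s2[j] <- s2[j] + runif(1, 1, 30)
    cum1 <- cumsum(cumulativeProbs(m, s))[1:3]
    cum2 <- cumsum(cumulativeProbs(m, s2))[1:3]
    expect_true(all(cum2 >= cum1 - 1e-12))
  }
})

test_that("log-likelihood equals the brute-force per-slide product", {
  m <- ordinalFusionModel(c(-1.5, 0.2, 1.7), rnorm(12, 0, 0.02))
  expect_equal(ordinalLoglik(ordinalFusionModel(qlogis(c(.25, .5, .75)),
                                                rep(0, 12)),
                             matrix(runif(12, 0, 100), 1), 1L),
               log(0.25), tolerance = 1e-12)

  set.seed(7)
  scores <- matrix(runif(10 * 12, 0, 100), 10)
  grades <- sample(0:3, 10, replace = TRUE)
  # independent oracle: per-slide plogis computation and product
  oracle <- 0
  for (i in 1:10) {
    eta <- sum(m@betas * scores[i, ])
    cum <- c(plogis(m@alphas + eta), 1)
    pAll <- c(cum[1], diff(cum))
    oracle <- oracle + log(pAll[grades[i] + 1])
  }
  expect_equal(ordinalLoglik(m, scores, grades), oracle, tolerance = 1e-9)

  # additivity under dataset duplication
  ll <- ordinalLoglik(m, scores, grades)
  expect_equal(ordinalLoglik(m, rbind(scores, scores), c(grades, grades)),
               2 * ll, tolerance = 1e-9)

  # zero-probability observation is an error
  mSat <- ordinalFusionModel(c(-900, -800, -700), rep(0, 12))
  expect_error(ordinalLoglik(mSat, matrix(rep(0, 12), 1), 0L),
               "zero-probability")
})

test_that("analytic gradient matches central finite differences", {
  set.seed(11)
  scores <- matrix(runif(40 * 12, 0, 100), 40)
  grades <- sample(0:3, 40, replace = TRUE)
  for (rep in 1:5) {
    theta <- c(rnorm(1), log(runif(2, 0.2, 1)), rnorm(12, 0, 0.02))
    obj <- oedgrader:::ordObjective(theta, scores, grades, lambda = 1e-6)
    h <- 1e-6
    fd <- vapply(seq_along(theta), function(j) {
      tp <- theta; tp[j] <- tp[j] + h
      tm <- theta; tm[j] <- tm[j] - h
      (oedgrader:::ordObjective(tp, scores, grades, 1e-6)$value -
       oedgrader:::ordObjective(tm, scores, grades, 1e-6)$value) / (2 * h)
    }, numeric(1))
    expect_equal(obj$gradient, fd, tolerance = 1e-5)
  }
})

test_that("fitting recovers generative parameters and matches polr", {
  truth <- recoveryTruthModel()
  tab <- generateScoreTable(truth, 2000, seed = 31)
  fit <- fitOrdinal(tab$scores, tab$grades)
  expect_lt(fit@fit$gradient_norm, 1e-8)

  # deterministic refit
  fit2 <- fitOrdinal(tab$scores, tab$grades)
  expect_identical(alphas(fit), alphas(fit2))
  expect_identical(betas(fit), betas(fit2))

  # independent maximum-likelihood cross-check: MASS::polr uses
  # logit P(Y <= k) = zeta_k - eta, so zeta = alphas, -coef = betas
  skip_if_not_installed("MASS")
  df <- data.frame(g = factor(tab$grades, levels = 0:3, ordered = TRUE),
                   tab$scores)
  pf <- MASS::polr(g ~ ., data = df, method = "logistic")
  expect_equal(unname(alphas(fit)), unname(pf$zeta), tolerance = 1e-3)
  expect_equal(unname(betas(fit)), unname(-coef(pf)), tolerance = 1e-3)
})

test_that("null-effect data shrink coefficients toward zero", {
  m0 <- ordinalFusionModel(qlogis(c(0.2, 0.5, 0.8)), rep(0, 12))
  tab <- generateScoreTable(m0, 1500, seed = 17)
  fit <- fitOrdinal(tab$scores, tab$grades)
  expect_true(all(abs(betas(fit)) < 0.01))
  # the fitted model beats coefficient perturbations on held-out data
  held <- generateScoreTable(m0, 1500, seed = 18)
  llFit <- ordinalLoglik(fit, held$scores, held$grades)
  set.seed(3)
  for (i in 1:5) {
    pert <- ordinalFusionModel(alphas(fit), betas(fit) + rnorm(12, 0, 0.02))
    expect_gte(llFit, ordinalLoglik(pert, held$scores, held$grades))
  }
})

test_that("fit preconditions are enforced", {
  scores <- matrix(runif(30 * 12, 0, 100), 30)
  expect_error(fitOrdinal(scores[1:10, ], rep(0:1, 5)), "at least 20")
  expect_error(fitOrdinal(scores, rep(2L, 30)), "single-grade")
})

test_that("grade prediction is the exhaustive argmax with high-tie rule", {
  m <- ordinalFusionModel(qlogis(c(0.25, 0.5, 0.75)), rep(0, 12))
  # exact four-way tie resolves to the highest grade
  expect_equal(predictGrade(m, rep(0, 12)), 3L)

  m2 <- ordinalFusionModel(c(2, 3, 4), rep(0, 12))  # mass at grade 0
  expect_equal(predictGrade(m2, runif(12, 0, 100)), 0L)

  set.seed(23)
  mr <- randomFusionModel()
  S <- matrix(runif(100 * 12, 0, 100), 100)
  pred <- predictGrade(mr, S)
  oracle <- vapply(1:100, function(i) {
    p <- cumulativeProbs(mr, S[i, ])
    max(which(p == max(p))) - 1L
  }, integer(1))
  expect_equal(pred, oracle)
})

test_that("fusion models serialize to JSON and back", {
  m <- ordinalFusionModel(c(-1, 0.5, 2), rnorm(12, 0, 0.05),
                          featureNames = dysplasiaFeatureNames())
  path <- withr::local_tempfile(fileext = ".json")
  writeOrdinalModel(m, path)
  back <- readOrdinalModel(path)
  expect_equal(alphas(back), alphas(m))
  expect_equal(betas(back), betas(m))
  expect_equal(featureNames(back), featureNames(m))
})
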