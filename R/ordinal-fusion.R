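# Cumulative-logit (proportional-odds) fusion of the 12 slide-level
# feature scores into a 4-class ordinal grade.  Sign convention (fixed,
# and deliberately non-standard relative to most ordinal-regression
# texts): covariates enter the cumulative logit POSITIVELY,
#   logit P(grade <= n) = alpha_n + sum_j beta_j * Score_j,
# so a positive coefficient pushes probability toward LOWER grades.

#' Construct a cumulative-logit fusion model
#'
#' @param alphas strictly increasing thresholds (logit scale), length K-1
#'   (K = 4 grades).
#' @param betas per-feature coefficients (per unit score on the 0--100
#'   scale).
#' @param featureNames optional score column names.
#' @param fit optional list of fitting diagnostics.
#' @return An [OrdinalFusionModel-class].
#' @examples
#' ordinalFusionModel(alphas = c(-1, 0, 1), betas = c(0.02, rep(0, 11)))
#' @export
ordinalFusionModel <- function(alphas, betas,
                               featureNames = character(0), fit = list()) {
  new("OrdinalFusionModel", alphas = as.numeric(alphas),
      betas = as.numeric(betas),
      featureNames = as.character(featureNames), fit = fit)
}

#' Grade probabilities under the fusion model
#'
#' Computes `P(grade <= n) = plogis(alpha_n + beta . scores)` for
#' n = 0..2 and returns the four grade probabilities as successive
#' differences (with `P(grade <= 3) = 1`).
#'
#' @param model an [OrdinalFusionModel-class].
#' @param scores numeric score vector matching `betas` in length.
#' @return Numeric length-4 probability vector (sums to 1).
#' @examples
#' m <- ordinalFusionModel(qlogis(c(.25, .5, .75)), rep(0, 12))
#' cumulativeProbs(m, rep(50, 12))  # 0.25 each
#' @export
cumulativeProbs <- function(model, scores) {
  stopifnot(is(model, "OrdinalFusionModel"))
  if (length(scores) != length(model@betas))
    stop("scores length must match betas")
  eta <- sum(model@betas * scores)
  cum <- plogis(model@alphas + eta)
  p <- c(cum[1], diff(cum), 1 - cum[length(cum)])
  pmax(p, 0)   # guard sub-eps negatives from differencing
}

# Vectorized cumulative probabilities: n x 4 matrix for an n x p score
# matrix.  Internal workhorse for the likelihood and batch prediction.
gradeProbMatrix <- function(model, scores) {
  scores <- as.matrix(scores)
  eta <- drop(scores %*% model@betas)
  cum <- vapply(model@alphas, function(a) plogis(a + eta),
                numeric(length(eta)))
  cum <- matrix(cum, ncol = length(model@alphas))
  p <- cbind(cum[, 1], cum[, 2] - cum[, 1], cum[, 3] - cum[, 2],
             1 - cum[, 3])
  pmax(p, 0)
}

#' Log-likelihood of graded slides under a fusion model
#'
#' Sum over slides of `log P(grade_i | scores_i)`.  An observation with
#' zero probability under the model makes the log-likelihood `-Inf` and is
#' treated as an error.
#'
#' @param model an [OrdinalFusionModel-class].
#' @param scores n x p score matrix (or length-p vector for one slide).
#' @param grades integer grades 0..3, length n.
#' @return Scalar log-likelihood (<= 0).
#' @export
ordinalLoglik <- function(model, scores, grades) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  if (nrow(scores) != length(grades))
    stop("scores and grades lengths differ")
  if (any(!grades %in% 0:3)) stop("grades must be in 0..3")
  P <- gradeProbMatrix(model, scores)
  p <- P[cbind(seq_along(grades), grades + 1L)]
  if (any(p <= 0))
    stop("zero-probability observation: log-likelihood is -Inf")
  sum(log(p))
}

# ---- maximum-likelihood fitting -----------------------------------------
# Parameterization enforcing ordered thresholds:
#   theta = (a1, d2, d3, beta_1..beta_p),
#   alpha = (a1, a1 + exp(d2), a1 + exp(d2) + exp(d3)).
# Objective: mean penalized negative log-likelihood,
#   f(theta) = -(1/n) [ loglik - lambda * ||beta||^2 ].

thetaToModel <- function(theta, p, featureNames = character(0),
                         fit = list()) {
  alphas <- c(theta[1],
              theta[1] + exp(theta[2]),
              theta[1] + exp(theta[2]) + exp(theta[3]))
  ordinalFusionModel(alphas, theta[-(1:3)], featureNames, fit)
}

# Mean penalized negative loglik and its analytic gradient.
ordObjective <- function(theta, scores, grades, lambda) {
  n <- nrow(scores); p <- ncol(scores)
  a1 <- theta[1]; e2 <- exp(theta[2]); e3 <- exp(theta[3])
  alphas <- c(a1, a1 + e2, a1 + e2 + e3)
  beta <- theta[-(1:3)]
  eta <- drop(scores %*% beta)

  # z-upper (alpha_{g+1} + eta) defined for g < 3, z-lower for g > 0
  gUp <- grades + 1L            # threshold index used as upper bound
  hasUp <- grades < 3L
  hasLo <- grades > 0L
  zUp <- ifelse(hasUp, alphas[pmin(gUp, 3L)] + eta, Inf)
  zLo <- ifelse(hasLo, alphas[pmax(grades, 1L)] + eta, -Inf)
  Fup <- ifelse(hasUp, plogis(zUp), 1)
  Flo <- ifelse(hasLo, plogis(zLo), 0)
  prob <- pmax(Fup - Flo, 1e-300)

  dens <- function(z) { f <- plogis(z); f * (1 - f) }
  fUp <- ifelse(hasUp, dens(zUp), 0)
  fLo <- ifelse(hasLo, dens(zLo), 0)

  # d logp / d alpha_k : +fUp/p at k = g+1, -fLo/p at k = g
  wUp <- fUp / prob
  wLo <- -fLo / prob
  dAlpha <- numeric(3)
  for (k in 1:3) {
    dAlpha[k] <- sum(wUp[hasUp & gUp == k]) + sum(wLo[hasLo & grades == k])
  }
  dEta <- wUp * hasUp + wLo * hasLo

  gradLog <- c(
    sum(dAlpha),                      # a1 enters every alpha
    (dAlpha[2] + dAlpha[3]) * e2,     # d2 enters alpha_2, alpha_3
    dAlpha[3] * e3,                   # d3 enters alpha_3
    drop(crossprod(scores, dEta))     # beta
  )
  penGrad <- c(0, 0, 0, 2 * lambda * beta)
  list(value = -(sum(log(prob)) - lambda * sum(beta^2)) / n,
       gradient = -(gradLog - penGrad) / n)
}

#' Fit the cumulative-logit fusion model by maximum likelihood
#'
#' Maximizes the log-likelihood of [cumulativeProbs()] minus a small ridge
#' penalty `lambda * ||beta||^2` (the penalty guarantees a finite optimum
#' under quasi-separation on small cohorts).  Thresholds are parameterized
#' as `alpha_1` plus cumulative positive increments so the ordering
#' constraint is built in.  Optimization is BFGS with the analytic
#' gradient followed by damped Newton polishing; convergence requires the
#' max-norm of the mean-scale gradient to fall below `tol`.
#'
#' @param scores n x p numeric score matrix (0--100 scale, n >= 20).
#' @param grades integer grades 0..3 (at least two distinct values).
#' @param lambda ridge penalty on the coefficients (default 1e-6).
#' @param maxit total iteration budget (default 500).
#' @param tol gradient max-norm convergence tolerance (default 1e-8).
#' @return An [OrdinalFusionModel-class] with fitting diagnostics in
#'   `@fit` (penalized loglik, iterations, gradient norm, lambda).
#' @examples
#' truth <- ordinalFusionModel(c(-2, 0, 2), c(-0.05, rep(0, 11)))
#' tab <- generateScoreTable(truth, 400, seed = 8)
#' fit <- fitOrdinal(tab$scores, tab$grades)
#' @export
fitOrdinal <- function(scores, grades, lambda = 1e-6, maxit = 500L,
                       tol = 1e-8) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  n <- nrow(scores); p <- ncol(scores)
  if (n < 20) stop("need at least 20 slides to fit")
  if (length(grades) != n) stop("scores and grades lengths differ")
  if (any(!grades %in% 0:3)) stop("grades must be in 0..3")
  if (length(unique(grades)) < 2)
    stop("single-grade data: the ordinal model is not identifiable")

  # start at the covariate-free model implied by empirical cumulative freqs
  cumFreq <- cumsum(tabulate(grades + 1L, 4L) / n)[1:3]
  cumFreq <- clamp(cumFreq, 1 / (2 * n), 1 - 1 / (2 * n))
  a0 <- qlogis(cumFreq)
  a0 <- cummax(a0 + (0:2) * 1e-6)  # ensure strict increase
  theta <- c(a0[1], log(max(a0[2] - a0[1], 1e-4)),
             log(max(a0[3] - a0[2], 1e-4)), rep(0, p))

  fn <- function(th) ordObjective(th, scores, grades, lambda)$value
  gr <- function(th) ordObjective(th, scores, grades, lambda)$gradient

  opt <- optim(theta, fn, gr, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-14))
  theta <- opt$par
  iter <- opt$counts[["gradient"]]

  # damped Newton polish with finite-difference Hessian of the analytic
  # gradient, to drive the gradient norm to the requested tolerance
  g <- gr(theta)
  newtonSteps <- 0L
  while (max(abs(g)) >= tol && newtonSteps < 100L) {
    m <- length(theta)
    Hm <- matrix(0, m, m)
    hstep <- pmax(1e-6, 1e-6 * abs(theta))
    for (j in seq_len(m)) {
      tp <- theta; tp[j] <- tp[j] + hstep[j]
      tm <- theta; tm[j] <- tm[j] - hstep[j]
      Hm[, j] <- (gr(tp) - gr(tm)) / (2 * hstep[j])
    }
    Hm <- (Hm + t(Hm)) / 2
    step <- tryCatch(solve(Hm + diag(1e-10, m), g),
                     error = function(e) g)  # gradient fallback
    lam <- 1
    f0 <- fn(theta)
    repeat {
      thetaNew <- theta - lam * step
      if (is.finite(fn(thetaNew)) && fn(thetaNew) <= f0 + 1e-12) break
      lam <- lam / 2
      if (lam < 1e-8) { thetaNew <- theta; break }
    }
    if (identical(thetaNew, theta)) break
    theta <- thetaNew
    g <- gr(theta)
    newtonSteps <- newtonSteps + 1L
  }

  gnorm <- max(abs(g))
  if (gnorm >= tol)
    stop(sprintf(paste0("fitOrdinal did not converge: gradient max-norm ",
                        "%.3g >= %.3g after %d iterations ",
                        "(objective %.6g); consider a larger ridge lambda"),
                 gnorm, tol, iter + newtonSteps, fn(theta)))

  model <- thetaToModel(theta, p,
                        featureNames = colnames(scores) %||% character(0))
  model@fit <- list(
    loglik = ordinalLoglik(model, scores, grades),
    penalized_objective = fn(theta),
    iterations = iter + newtonSteps,
    gradient_norm = gnorm,
    lambda = lambda,
    n = n
  )
  model
}

#' Predict the slide grade from a fusion model
#'
#' Argmax of the grade probabilities; exact ties break toward the higher
#' grade (screening favours sensitivity for severe disease).
#'
#' @param model an [OrdinalFusionModel-class].
#' @param scores length-p vector or n x p matrix of slide scores.
#' @return Integer grade 0..3 (vector for matrix input).
#' @export
predictGrade <- function(model, scores) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  P <- gradeProbMatrix(model, scores)
  apply(P, 1, function(p) max(which(p == max(p))) - 1L)
}

#' Serialize / read a fusion model as JSON
#'
#' @param model an [OrdinalFusionModel-class].
#' @param path JSON path.
#' @return `path` invisibly; the reader returns the model.
#' @export
writeOrdinalModel <- function(model, path) {
  jsonlite::write_json(
    list(alphas = model@alphas, betas = model@betas,
         feature_names = model@featureNames,
         convention = "cumulative-logit; covariates enter positively",
         fit = model@fit),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeOrdinalModel
#' @export
readOrdinalModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ordinalFusionModel(x$alphas, x$betas,
                     featureNames = x$feature_names %||% character(0),
                     fit = as.list(x$fit %||% list()))
}
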