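# Macro-averaged multiclass metrics (unweighted one-vs-rest over the four
# grades) with percentile-bootstrap confidence intervals, and the summary
# of the 12 per-feature detector reports.

#' Construct an evaluation report
#'
#' @param accuracy,sensitivity,specificity,auc point metrics in [0, 1]
#'   (NA allowed for undefined metrics).
#' @param ci named list of length-2 (lo, hi) intervals.
#' @param nBoot bootstrap replicate count (0 = none).
#' @param seed bootstrap seed.
#' @param n evaluated sample size.
#' @return An [EvalReport-class].
#' @export
evalReport <- function(accuracy = NA_real_, sensitivity = NA_real_,
                       specificity = NA_real_, auc = NA_real_,
                       ci = list(), nBoot = 0L, seed = NA_integer_,
                       n = NA_integer_) {
  new("EvalReport",
      metrics = c(accuracy = accuracy, sensitivity = sensitivity,
                  specificity = specificity, auc = auc),
      ci = ci, nBoot = as.integer(nBoot), seed = as.integer(seed),
      n = as.integer(n))
}

# Midrank (Mann-Whitney) AUC of scores for positives vs negatives.
midrankAUC <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)             # midranks for ties
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Macro-averaged point metrics for 4-class grading
#'
#' For each grade class the task is binarized one-vs-rest: per-class
#' accuracy, sensitivity, specificity from the confusion tallies, and
#' per-class AUC as the midrank statistic on that class's probability
#' column.  The macro value is the unweighted mean over the four classes.
#' A class absent from the truth leaves its sensitivity and AUC undefined;
#' such classes are excluded from those macro averages with a warning.
#'
#' @param yTrue,yPred integer grades 0..3.
#' @param yProbs n x 4 probability matrix (rows sum to 1); NULL leaves
#'   AUC undefined.
#' @return An [EvalReport-class] (point estimates only).
#' @export
macroMetrics <- function(yTrue, yPred, yProbs = NULL) {
  n <- length(yTrue)
  if (length(yPred) != n) stop("yTrue and yPred lengths differ")
  if (!is.null(yProbs)) {
    yProbs <- as.matrix(yProbs)
    if (nrow(yProbs) != n || ncol(yProbs) != 4L)
      stop("yProbs must be n x 4")
    if (any(abs(rowSums(yProbs) - 1) > 1e-6))
      stop("probability rows must sum to 1")
  }
  acc <- sens <- spec <- auc <- rep(NA_real_, 4)
  for (c in 0:3) {
    pos <- yTrue == c; predPos <- yPred == c
    tp <- sum(pos & predPos); fn <- sum(pos & !predPos)
    fp <- sum(!pos & predPos); tn <- sum(!pos & !predPos)
    acc[c + 1] <- (tp + tn) / n
    if (tp + fn > 0) sens[c + 1] <- tp / (tp + fn)
    if (tn + fp > 0) spec[c + 1] <- tn / (tn + fp)
    if (!is.null(yProbs)) auc[c + 1] <- midrankAUC(yProbs[, c + 1], pos)
  }
  absent <- setdiff(0:3, unique(yTrue))
  if (length(absent))
    warning("class(es) ", paste(absent, collapse = ", "),
            " absent from truth: sensitivity/AUC excluded from macro")
  evalReport(accuracy = mean(acc, na.rm = TRUE),
             sensitivity = mean(sens, na.rm = TRUE),
             specificity = mean(spec, na.rm = TRUE),
             auc = if (is.null(yProbs)) NA_real_ else mean(auc, na.rm = TRUE),
             n = n)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples the sample with replacement `nBoot` times, applies
#' `statistic` to each resample and returns the central `level` percentile
#' interval.  Resamples on which the statistic is undefined (error or NA)
#' are redrawn, with the total number of draws capped at `10 * nBoot`.
#'
#' @param statistic function mapping a sample (same container type) to a
#'   scalar.
#' @param sample vector or list of observations (slides are the resampling
#'   unit).
#' @param nBoot number of bootstrap replicates (>= 100).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed (deterministic intervals).
#' @return Numeric length-2 `(lo, hi)`.
#' @examples
#' bootstrapCI(mean, rbinom(200, 1, 0.3), nBoot = 500, seed = 1)
#' @export
bootstrapCI <- function(statistic, sample, nBoot = 1000L, level = 0.95,
                        seed = 1L) {
  if (!length(sample)) stop("empty sample")
  if (nBoot < 100) stop("nBoot must be >= 100")
  n <- length(sample)
  withSeed(seed, {
    stats <- numeric(nBoot)
    got <- 0L; attempts <- 0L
    while (got < nBoot) {
      if (attempts >= 10L * nBoot)
        stop("statistic undefined on too many bootstrap resamples")
      attempts <- attempts + 1L
      idx <- sample.int(n, n, replace = TRUE)
      val <- tryCatch(statistic(sample[idx]), error = function(e) NA_real_)
      if (is.na(val)) next
      got <- got + 1L
      stats[got] <- val
    }
    a <- (1 - level) / 2
    unname(quantile(stats, c(a, 1 - a), type = 7))
  })
}

#' Evaluate slide predictions with bootstrap confidence intervals
#'
#' Point macro metrics plus percentile-bootstrap 95% intervals obtained by
#' resampling slides (truth, prediction and probability rows jointly).
#' Resamples on which a metric is undefined are redrawn (capped at
#' `10 * nBoot` attempts).
#'
#' @inheritParams macroMetrics
#' @param nBoot bootstrap replicates (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed.
#' @return An [EvalReport-class] with per-metric intervals.
#' @export
evaluatePredictions <- function(yTrue, yPred, yProbs = NULL,
                                nBoot = 1000L, level = 0.95, seed = 1L) {
  point <- suppressWarnings(macroMetrics(yTrue, yPred, yProbs))
  n <- length(yTrue)
  metricNames <- names(metrics(point))
  withSeed(seed, {
    draws <- matrix(NA_real_, nBoot, length(metricNames),
                    dimnames = list(NULL, metricNames))
    got <- 0L; attempts <- 0L
    while (got < nBoot) {
      if (attempts >= 10L * nBoot)
        stop("metrics undefined on too many bootstrap resamples")
      attempts <- attempts + 1L
      idx <- sample.int(n, n, replace = TRUE)
      rep <- tryCatch(
        suppressWarnings(macroMetrics(yTrue[idx], yPred[idx],
                                      if (!is.null(yProbs))
                                        yProbs[idx, , drop = FALSE])),
        error = function(e) NULL)
      if (is.null(rep)) next
      m <- metrics(rep)
      if (any(is.na(m[!is.na(metrics(point))]))) next
      got <- got + 1L
      draws[got, ] <- m
    }
    a <- (1 - level) / 2
    ci <- list()
    for (nm in metricNames) {
      if (!is.na(metrics(point)[[nm]]))
        ci[[nm]] <- unname(quantile(draws[, nm], c(a, 1 - a), type = 7))
    }
    new("EvalReport", metrics = metrics(point), ci = ci,
        nBoot = as.integer(nBoot), seed = as.integer(seed),
        n = as.integer(n))
  })
}

#' Summarize the 12 per-feature detector reports
#'
#' Medians (mean of the middle two for even counts) of the 12 per-feature
#' accuracies and AUCs.
#'
#' @param reports list of 12 [EvalReport-class] objects, roster order.
#' @return List with `median_accuracy` and `median_auc` (same scale as
#'   the inputs).
#' @export
summarizeFeatureModels <- function(reports) {
  if (length(reports) != 12L) stop("exactly 12 feature reports required")
  accs <- vapply(reports, function(r) metrics(r)[["accuracy"]], numeric(1))
  aucs <- vapply(reports, function(r) metrics(r)[["auc"]], numeric(1))
  if (any(is.na(accs)) || any(is.na(aucs)))
    stop("missing accuracy or AUC in a feature report")
  list(median_accuracy = median(accs), median_auc = median(aucs))
}

#' Published per-feature detector performance table
#'
#' Loads the bundled summary table of the 12 dysplasia-feature detection
#' models (per-feature test accuracy in percent and AUC, with 95%
#' bootstrap CIs) used by the worked summary example.
#'
#' @return data.frame with columns `feature`, `accuracy_pct`, `auc` and
#'   CI bounds.
#' @export
featureModelPerformance <- function() {
  path <- system.file("extdata", "feature_model_performance.tsv",
                      package = "oedgrader", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
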