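# Shared fixture builders: everything is generated in code at test time.

# Solid-color RGB image.
solidImage <- function(h, w, rgb = c(255, 255, 255)) {
  img <- array(0, dim = c(h, w, 3L))
  for (ch in 1:3) img[, , ch] <- rgb[ch]
  img
}

# Image whose top half is white (background) and bottom half gray tissue.
halfBackgroundImage <- function(h, w) {
  img <- solidImage(h, w, c(100, 100, 100))
  img[seq_len(h %/% 2), , ] <- 255
  img
}

# Tiny toy patches for classifier tests: "dark" vs "bright" class.
toyPatch <- function(bright, seed, size = 64L) {
  withr_seed <- function(code) code
  set.seed(seed)
  base <- if (bright) 190 else 60
  g <- matrix(base + rnorm(size * size, sd = 10), size, size)
  img <- array(0, dim = c(size, size, 3L))
  for (ch in 1:3) img[, , ch] <- pmin(pmax(g, 0), 215)
  img
}

toyDataset <- function(n, seedBase) {
  images <- c(lapply(seq_len(n), function(i) toyPatch(TRUE, seedBase + i)),
              lapply(seq_len(n), function(i) toyPatch(FALSE, seedBase + 5000 + i)))
  patchDataset(images, c(rep(1L, n), rep(0L, n)))
}

# The well-conditioned truth model used in recovery experiments: six
# informative negative coefficients (scores push toward higher grades),
# thresholds centered on the induced linear predictor.
recoveryTruthModel <- function() {
  ordinalFusionModel(
    alphas = c(24.5, 26.5, 28.5),
    betas = c(-0.08, -0.09, -0.10, -0.08, -0.09, -0.10, rep(0, 6)),
    featureNames = dysplasiaFeatureNames())
}

# Published per-feature detector performance as EvalReports (proportion
# scale).
featurePerformanceReports <- function() {
  tab <- featureModelPerformance()
  lapply(seq_len(nrow(tab)), function(i)
    evalReport(accuracy = tab$accuracy_pct[i] / 100, auc = tab$auc[i]))
}

# Random valid fusion model for property tests.
randomFusionModel <- function() {
  a1 <- rnorm(1, 0, 2)
  ordinalFusionModel(alphas = a1 + c(0, cumsum(runif(2, 0.1, 2))),
                     betas = rnorm(12, 0, 0.03))
}
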