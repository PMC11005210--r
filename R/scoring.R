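# Feature roster management and the amplified 12-dimensional score stage:
# patch-level activation scores (0-1) x 100, averaged over a slide's
# foreground patches.

#' Exclude rarely annotated features from the roster
#'
#' Features whose positive annotation count is below `minPositive`
#' (strictly less than; a count of exactly `minPositive` is retained) are
#' removed from the active roster and recorded with their counts.  The
#' full 16-feature candidate list with four rare features removed yields
#' the working 12-feature roster.
#'
#' @param annotationCounts named integer vector: positive annotation count
#'   per candidate feature.
#' @param minPositive minimum positive count to keep a feature (default 5).
#' @return List with `names` (retained, in input order) and `excluded`
#'   (data.frame name/positives/reason).
#' @examples
#' excludeRareFeatures(c(a = 10, b = 3, c = 5))
#' @export
excludeRareFeatures <- function(annotationCounts, minPositive = 5L) {
  stopifnot(!is.null(names(annotationCounts)), all(annotationCounts >= 0))
  keep <- annotationCounts >= minPositive
  if (!any(keep))
    stop("fewer than 1 surviving feature after rare-feature exclusion")
  excluded <- data.frame(
    name = names(annotationCounts)[!keep],
    positives = as.integer(annotationCounts[!keep]),
    reason = sprintf("positive frequency %d < %d",
                     as.integer(annotationCounts[!keep]), minPositive),
    stringsAsFactors = FALSE)
  if (sum(keep) == 1L)
    warning("only one feature survives the exclusion rule")
  list(names = names(annotationCounts)[keep], excluded = excluded)
}

#' Amplified feature score of one patch
#'
#' `100 x` the positive-class softmax probability of a binary feature
#' detector, giving the 0--100 amplified activation score.
#'
#' @param model a binary (K = 2) [ClassifierHandle-class]; class 2 is the
#'   positive class.
#' @param patch an RGB array.
#' @return Scalar in [0, 100].
#' @examples
#' patchFeatureScore(constantClassifier(c(0.73, 0.27)),
#'                   array(0, c(8, 8, 3)))  # 27
#' @export
patchFeatureScore <- function(model, patch) {
  stopifnot(is(model, "ClassifierHandle"))
  if (model@nClasses != 2L)
    stop("feature scoring requires a binary (K = 2) model")
  P <- predictScores(model, list(patch))
  100 * P[1, 2]
}

#' Patch-by-feature score matrix for a set of patches
#'
#' Applies the 12 binary feature detectors to every patch.  When all
#' detectors share the package's reference featurizer, patches are
#' featurized once and scored through each model's feature-space path.
#'
#' @param patches list of RGB arrays or a [PatchSet-class].
#' @param featureModels list of 12 binary [ClassifierHandle-class]
#'   objects, roster order.
#' @return n x 12 matrix of amplified scores in [0, 100].
#' @export
scorePatchFeatures <- function(patches, featureModels) {
  if (is(patches, "PatchSet")) patches <- patchImages(patches)
  stopifnot(length(featureModels) == 12L)
  for (m in featureModels)
    if (m@nClasses != 2L) stop("feature models must be binary")
  n <- length(patches)
  out <- matrix(0, n, 12L, dimnames = list(NULL, dysplasiaFeatureNames()))
  if (!n) return(out)
  archTags <- vapply(featureModels, function(m)
    m@metadata$architecture %||% "", character(1))
  fastOK <- length(unique(archTags)) == 1L &&
    !is.null(featureModels[[1]]@metadata$scoreFeatures) &&
    !is.null(featureModels[[1]]@metadata$featurizer)
  if (fastOK) {
    X <- featurizePatches(patches, featureModels[[1]]@metadata$featurizer)
    for (j in 1:12) out[, j] <- 100 * featureModels[[j]]@metadata$scoreFeatures(X)[, 2]
  } else {
    for (j in 1:12) out[, j] <- 100 * predictScores(featureModels[[j]], patches)[, 2]
  }
  out
}

#' Slide-level feature scores
#'
#' Component-wise arithmetic mean of the patch-level amplified scores over
#' a slide's foreground patches.  A slide with zero foreground patches is
#' an error ("empty slide").
#'
#' @param patchScores for one slide, an n x 12 matrix of patch scores; or
#'   a named list of such matrices for several slides.
#' @return Named length-12 numeric (one slide) or a slides x 12 matrix.
#' @examples
#' slideScores(rbind(rep(0, 12), rep(100, 12)))  # all 50
#' @export
slideScores <- function(patchScores) {
  if (is.list(patchScores) && !is.data.frame(patchScores)) {
    out <- t(vapply(patchScores, slideScores, numeric(12)))
    return(out)
  }
  m <- as.matrix(patchScores)
  if (nrow(m) == 0) stop("empty slide: no foreground patch scores")
  if (ncol(m) != 12L) stop("patch scores must have 12 feature columns")
  s <- colMeans(m)
  names(s) <- colnames(m) %||% dysplasiaFeatureNames()
  s
}
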