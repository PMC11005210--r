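# Slide-level grading paths and heatmap rendering.  Two paths are
# computed for every slide: the patch-majority grade (maximum proportion
# of patch-level grade predictions) and the ordinal-fusion grade over the
# 12 slide-level feature scores.  The fusion grade is the authoritative
# output; the majority grade is reported alongside.

#' Majority (maximum-proportion) slide grade
#'
#' The grade with the largest share of patch-level predictions; exact
#' ties break toward the higher grade.
#'
#' @param patchPredictions integer vector of patch grades (0..3), >= 1
#'   long.
#' @return List with `grade` (integer) and `fractions` (length-4 vote
#'   proportions summing to 1).
#' @examples
#' majorityGrade(c(0, 0, 0, 1))
#' @export
majorityGrade <- function(patchPredictions) {
  if (!length(patchPredictions)) stop("no patch predictions")
  if (any(!patchPredictions %in% 0:3)) stop("grades must be in 0..3")
  counts <- tabulate(patchPredictions + 1L, 4L)
  fractions <- counts / sum(counts)
  grade <- max(which(counts == max(counts))) - 1L
  list(grade = grade, fractions = fractions)
}

#' Grade one slide end-to-end
#'
#' Runs the full per-slide chain: tile, filter foreground, per-patch grade
#' probabilities and feature scores, slide-level score averaging, and both
#' grading paths.  The reported grade is the ordinal-fusion output.
#'
#' @param image slide RGB array.
#' @param gradeModel 4-class [ClassifierHandle-class] for patch grades.
#' @param featureModels list of 12 binary feature detectors.
#' @param fusion an [OrdinalFusionModel-class].
#' @param slideId identifier.
#' @param patchSize patch edge (default 224).
#' @param maxBackground foreground rule (default 0.5).
#' @param magnificationFactor 1 or 2, applied before tiling.
#' @return A [SlidePrediction-class].  A slide with no foreground patches
#'   is an error ("no tissue").
#' @export
gradeSlide <- function(image, gradeModel, featureModels, fusion,
                       slideId = "slide", patchSize = 224L,
                       maxBackground = 0.5, magnificationFactor = 1L) {
  stopifnot(is(gradeModel, "ClassifierHandle"),
            is(fusion, "OrdinalFusionModel"))
  if (gradeModel@nClasses != 4L) stop("grade model must have 4 classes")
  image <- rescaleMagnification(image, magnificationFactor)
  patches <- filterForeground(tileImage(image, patchSize, slideId),
                              maxBackground)
  if (length(patches) == 0L) stop("no tissue: every patch is background")

  # featurize once when every model shares the reference front end
  tags <- vapply(c(list(gradeModel), featureModels), function(m)
    m@metadata$architecture %||% "", character(1))
  sharedFeaturizer <- length(unique(tags)) == 1L &&
    !is.null(gradeModel@metadata$scoreFeatures)
  if (sharedFeaturizer) {
    X <- featurizePatches(patches, gradeModel@metadata$featurizer)
    gradeProbs <- gradeModel@metadata$scoreFeatures(X)
    patchFeat <- vapply(featureModels, function(m)
      100 * m@metadata$scoreFeatures(X)[, 2], numeric(nrow(X)))
    patchFeat <- matrix(patchFeat, nrow = nrow(X))
  } else {
    gradeProbs <- predictScores(gradeModel, patches)
    patchFeat <- scorePatchFeatures(patches, featureModels)
  }
  patchGrades <- max.col(gradeProbs, ties.method = "last") - 1L
  maj <- majorityGrade(patchGrades)

  featScores <- slideScores(patchFeat)
  probs <- cumulativeProbs(fusion, featScores)
  fused <- predictGrade(fusion, featScores)

  new("SlidePrediction", slideId = slideId,
      emodGrade = as.integer(maj$grade),
      emodplusGrade = as.integer(fused),
      gradeProbs = as.numeric(probs / sum(probs)),
      featureScores = as.numeric(featScores),
      patchGradeFractions = maj$fractions)
}

#' Render a slide heatmap from per-patch grade probabilities
#'
#' Reassembles the foreground patches on a white canvas at their original
#' spatial coordinates.  Each foreground patch is painted one solid color
#' whose intensity is monotone in the expected grade
#' `sum(i * p_i) / 3` — brighter marks higher dysplasia — on a dark-olive
#' to bright-yellow ramp (never white, so foreground geometry is exactly
#' the non-white pixel set).
#'
#' @param patches a foreground [PatchSet-class].
#' @param gradeProbsPerPatch n x 4 matrix of grade probabilities (rows sum
#'   to 1, same order as the manifest).
#' @param slideDims (height, width); defaults to the patch set's recorded
#'   slide size.
#' @return RGB array of the slide dimensions.
#' @export
renderHeatmap <- function(patches, gradeProbsPerPatch, slideDims = NULL) {
  stopifnot(is(patches, "PatchSet"))
  man <- manifest(patches)
  P <- as.matrix(gradeProbsPerPatch)
  if (nrow(P) != nrow(man)) stop("one probability row per patch required")
  if (nrow(P) && any(abs(rowSums(P) - 1) > 1e-6))
    stop("grade probabilities must sum to 1")
  if (is.null(slideDims)) slideDims <- patches@slideDims
  H <- slideDims[1]; W <- slideDims[2]
  if (nrow(man) && any(man$y0 + man$size > H | man$x0 + man$size > W))
    stop("patch coordinates exceed slide dimensions")

  canvas <- array(255, dim = c(H, W, 3L))
  painted <- matrix(FALSE, H, W)
  for (i in seq_len(nrow(man))) {
    ys <- man$y0[i] + seq_len(man$size[i])
    xs <- man$x0[i] + seq_len(man$size[i])
    if (any(painted[ys, xs]))
      stop("overlapping patches: the tiler must produce a disjoint grid")
    painted[ys, xs] <- TRUE
    v <- sum((0:3) * P[i, ]) / 3
    canvas[ys, xs, 1] <- round(64 + 191 * v)
    canvas[ys, xs, 2] <- round(64 + 191 * v)
    canvas[ys, xs, 3] <- 0
  }
  canvas
}
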