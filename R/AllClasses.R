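#' Specification of a synthetic slide
#'
#' Parameters of the synthetic-slide generator.  Slides carry a fraction of
#' bright background (brightness > 220/255), pink tissue elsewhere, and
#' per-feature texture motifs planted per tile with a probability that
#' depends on the slide grade through `featureEffect`.
#'
#' @slot imageSize integer length-2, (height, width) in pixels.
#' @slot patchSize integer, tile edge in pixels (the motif-planting grid).
#' @slot backgroundFraction proportion of pixels that are background.
#' @slot nGrades number of ordered grade classes (fixed at 4).
#' @slot nFeatures number of dysplasia features (fixed at 12).
#' @slot featureEffect numeric matrix (grade x feature) in [0, 1]: the
#'   probability that a tissue tile of a slide of that grade carries the
#'   motif of that feature.
#' @slot noiseSd pixel noise standard deviation in brightness units.
#' @slot labelNoise probability that a planted per-patch feature flag is
#'   flipped in the reported truth (emulates noisy parent labels; 0 default).
#' @slot seed integer RNG seed.
#' @export
setClass("SyntheticSpec",
  representation(
    imageSize = "integer",
    patchSize = "integer",
    backgroundFraction = "numeric",
    nGrades = "integer",
    nFeatures = "integer",
    featureEffect = "matrix",
    noiseSd = "numeric",
    labelNoise = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- character(0)
  if (length(object@imageSize) != 2L || any(object@imageSize < 1L))
    msg <- c(msg, "imageSize must be two positive integers (H, W)")
  if (length(object@patchSize) != 1L || object@patchSize < 1L)
    msg <- c(msg, "patchSize must be a positive integer")
  if (object@backgroundFraction < 0 || object@backgroundFraction > 1)
    msg <- c(msg, "backgroundFraction must be in [0, 1]")
  if (object@nGrades != 4L) msg <- c(msg, "nGrades is fixed at 4")
  if (object@nFeatures != 12L) msg <- c(msg, "nFeatures is fixed at 12")
  if (!all(dim(object@featureEffect) == c(object@nGrades, object@nFeatures)))
    msg <- c(msg, "featureEffect must be nGrades x nFeatures")
  if (any(object@featureEffect < 0) || any(object@featureEffect > 1))
    msg <- c(msg, "featureEffect entries must be in [0, 1]")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@labelNoise < 0 || object@labelNoise > 1)
    msg <- c(msg, "labelNoise must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Tiled patches of one slide
#'
#' Result of tiling a slide image into a disjoint, row-major grid of
#' square patches, together with the per-patch manifest (grid indices,
#' pixel offsets, background fraction, inherited slide label).
#'
#' @slot slideId character slide identifier.
#' @slot patchSize integer patch edge in pixels.
#' @slot slideDims integer length-2 (height, width) of the source image.
#' @slot manifest data.frame with columns `slide_id, row, col, x0, y0,
#'   size, background_fraction, label`.
#' @slot images list of RGB arrays, one per manifest row.
#' @export
setClass("PatchSet",
  representation(
    slideId = "character",
    patchSize = "integer",
    slideDims = "integer",
    manifest = "data.frame",
    images = "list"
  )
)

setValidity("PatchSet", function(object) {
  m <- object@manifest
  need <- c("slide_id", "row", "col", "x0", "y0", "size",
            "background_fraction", "label")
  if (!all(need %in% names(m)))
    return(paste("manifest must have columns:", paste(need, collapse = ", ")))
  if (length(object@images) != nrow(m))
    return("one image per manifest row required")
  if (nrow(m)) {
    if (any(m$x0 != m$col * m$size) || any(m$y0 != m$row * m$size))
      return("pixel offsets must equal grid index times size")
    bf <- m$background_fraction
    if (any(!is.na(bf) & (bf < 0 | bf > 1)))
      return("background_fraction must be in [0, 1]")
  }
  TRUE
})

#' A trained (or stub) patch classifier
#'
#' The pluggable classifier contract used by every downstream stage: a
#' `predict` function mapping a list of RGB patches to an n x K matrix of
#' class probabilities (rows sum to 1), the number of classes, and free-form
#' metadata (architecture tag, per-epoch training history, selected epoch).
#' Any object honouring this contract — including a constant stub — is
#' accepted by scoring, grading and evaluation.
#'
#' @slot predict function(list of RGB arrays) -> numeric matrix n x K.
#' @slot nClasses integer number of classes K.
#' @slot metadata list; for trained models includes `architecture`,
#'   `history` (data.frame epoch/train_loss/val_loss) and `selected_epoch`.
#' @export
setClass("ClassifierHandle",
  representation(
    predict = "function",
    nClasses = "integer",
    metadata = "list"
  )
)

setValidity("ClassifierHandle", function(object) {
  if (length(object@nClasses) != 1L || object@nClasses < 2L)
    return("nClasses must be a single integer >= 2")
  TRUE
})

#' Cumulative-logit (proportional-odds) grade fusion model
#'
#' The ordinal fusion model mapping a 12-feature slide score vector to
#' grade probabilities over the four ordered classes
#' hyperplasia(0) < mild(1) < moderate(2) < severe(3):
#' \deqn{\mathrm{logit}\, P(\mathrm{grade} \le n) = \alpha_n + \sum_j \beta_j \mathrm{Score}_j}
#' Covariates enter the cumulative logit positively, so a positive
#' coefficient pushes probability mass toward lower grades.
#'
#' @slot alphas numeric K-1 strictly increasing thresholds (logit scale).
#' @slot betas numeric coefficients, one per feature (per unit score,
#'   0--100 scale).
#' @slot featureNames character names of the score columns.
#' @slot fit list with fitting diagnostics (loglik, iterations,
#'   gradient norm, ridge lambda); empty for hand-built models.
#' @export
setClass("OrdinalFusionModel",
  representation(
    alphas = "numeric",
    betas = "numeric",
    featureNames = "character",
    fit = "list"
  )
)

setValidity("OrdinalFusionModel", function(object) {
  if (any(!is.finite(object@alphas)) || any(!is.finite(object@betas)))
    return("alphas and betas must be finite")
  if (length(object@alphas) < 1L || any(diff(object@alphas) <= 0))
    return("alphas must be strictly increasing")
  if (length(object@featureNames) &&
      length(object@featureNames) != length(object@betas))
    return("featureNames must match betas in length")
  TRUE
})

#' Macro-averaged evaluation report
#'
#' Point estimates and 95% bootstrap percentile confidence intervals for
#' macro-averaged (unweighted one-vs-rest) accuracy, sensitivity,
#' specificity and AUC over the four grade classes.
#'
#' @slot metrics named numeric: accuracy, sensitivity, specificity, auc.
#' @slot ci named list of length-2 numeric (lo, hi) per metric; empty if
#'   no bootstrap was run.
#' @slot nBoot integer bootstrap replicate count (0 if none).
#' @slot seed integer bootstrap seed.
#' @slot n integer number of evaluated slides/instances.
#' @export
setClass("EvalReport",
  representation(
    metrics = "numeric",
    ci = "list",
    nBoot = "integer",
    seed = "integer",
    n = "integer"
  )
)

setValidity("EvalReport", function(object) {
  m <- object@metrics
  if (any(!is.na(m) & (m < 0 | m > 1)))
    return("point metrics must lie in [0, 1]")
  TRUE
})

#' Slide-level prediction from both grading paths
#'
#' Holds the patch-majority grade (maximum proportion of patch-level grade
#' predictions), the ordinal-fusion grade (the authoritative output), the
#' fused grade probabilities, the 12 amplified slide-level feature scores
#' and the patch grade-vote fractions.
#'
#' @slot slideId character.
#' @slot emodGrade integer 0..3, patch-majority grade.
#' @slot emodplusGrade integer 0..3, ordinal-fusion grade (authoritative).
#' @slot gradeProbs numeric length-4 grade probabilities (sums to 1).
#' @slot featureScores numeric length-12 slide scores in [0, 100].
#' @slot patchGradeFractions numeric length-4 vote proportions (sums to 1).
#' @export
setClass("SlidePrediction",
  representation(
    slideId = "character",
    emodGrade = "integer",
    emodplusGrade = "integer",
    gradeProbs = "numeric",
    featureScores = "numeric",
    patchGradeFractions = "numeric"
  )
)

setValidity("SlidePrediction", function(object) {
  if (!object@emodGrade %in% 0:3 || !object@emodplusGrade %in% 0:3)
    return("grades must be in 0..3")
  if (abs(sum(object@gradeProbs) - 1) > 1e-6)
    return("gradeProbs must sum to 1")
  if (abs(sum(object@patchGradeFractions) - 1) > 1e-6)
    return("patchGradeFractions must sum to 1")
  TRUE
})
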