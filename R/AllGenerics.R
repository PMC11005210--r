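#' @rdname PatchSet-class
#' @param object,x a package object.
#' @export
setGeneric("manifest", function(x) standardGeneric("manifest"))

#' @rdname PatchSet-class
#' @export
setMethod("manifest", "PatchSet", function(x) x@manifest)

#' @rdname PatchSet-class
#' @export
setGeneric("patchImages", function(x) standardGeneric("patchImages"))

#' @rdname PatchSet-class
#' @export
setMethod("patchImages", "PatchSet", function(x) x@images)

#' @rdname PatchSet-class
#' @export
setGeneric("slideId", function(x) standardGeneric("slideId"))

#' @rdname PatchSet-class
#' @export
setMethod("slideId", "PatchSet", function(x) x@slideId)

#' @rdname PatchSet-class
#' @export
setMethod("length", "PatchSet", function(x) nrow(x@manifest))

setMethod("show", "PatchSet", function(object) {
  cat("PatchSet for slide '", object@slideId, "': ",
      nrow(object@manifest), " patches of ", object@patchSize, " px (slide ",
      object@slideDims[1], "x", object@slideDims[2], ")\n", sep = "")
  if (nrow(object@manifest)) {
    bf <- object@manifest$background_fraction
    cat("  background fraction: ",
        sprintf("%.3f-%.3f", min(bf), max(bf)), "\n", sep = "")
  }
})

#' @rdname OrdinalFusionModel-class
#' @param x an `OrdinalFusionModel`.
#' @export
setGeneric("alphas", function(x) standardGeneric("alphas"))

#' @rdname OrdinalFusionModel-class
#' @export
setMethod("alphas", "OrdinalFusionModel", function(x) x@alphas)

#' @rdname OrdinalFusionModel-class
#' @export
setGeneric("betas", function(x) standardGeneric("betas"))

#' @rdname OrdinalFusionModel-class
#' @export
setMethod("betas", "OrdinalFusionModel", function(x) x@betas)

#' @rdname OrdinalFusionModel-class
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname OrdinalFusionModel-class
#' @export
setMethod("featureNames", "OrdinalFusionModel", function(x) x@featureNames)

setMethod("show", "OrdinalFusionModel", function(object) {
  cat("OrdinalFusionModel (cumulative logit, covariates enter positively)\n")
  cat("  alphas:", paste(sprintf("%.4g", object@alphas), collapse = ", "), "\n")
  cat("  betas: ", paste(sprintf("%.4g", object@betas), collapse = ", "), "\n")
  if (length(object@fit))
    cat("  fit: loglik ", sprintf("%.4f", object@fit$loglik),
        ", ", object@fit$iterations, " iterations, |grad| ",
        sprintf("%.3g", object@fit$gradient_norm), "\n", sep = "")
})

#' @rdname EvalReport-class
#' @param x an `EvalReport`.
#' @export
setGeneric("metrics", function(x) standardGeneric("metrics"))

#' @rdname EvalReport-class
#' @export
setMethod("metrics", "EvalReport", function(x) x@metrics)

#' @rdname EvalReport-class
#' @export
setGeneric("metricCI", function(x) standardGeneric("metricCI"))

#' @rdname EvalReport-class
#' @export
setMethod("metricCI", "EvalReport", function(x) x@ci)

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport (macro one-vs-rest over 4 grades, n = ", object@n,
      ")\n", sep = "")
  for (nm in names(object@metrics)) {
    line <- sprintf("  %-12s %.4f", nm, object@metrics[[nm]])
    if (nm %in% names(object@ci))
      line <- paste0(line, sprintf("  (95%% CI %.4f-%.4f)",
                                   object@ci[[nm]][1], object@ci[[nm]][2]))
    cat(line, "\n")
  }
  if (object@nBoot > 0L)
    cat("  bootstrap: ", object@nBoot, " replicates, seed ",
        object@seed, "\n", sep = "")
})

setMethod("show", "SlidePrediction", function(object) {
  lab <- c("hyperplasia", "mild", "moderate", "severe")
  cat("SlidePrediction for '", object@slideId, "'\n", sep = "")
  cat("  fused grade (authoritative): ", object@emodplusGrade, " (",
      lab[object@emodplusGrade + 1L], ")\n", sep = "")
  cat("  patch-majority grade:        ", object@emodGrade, " (",
      lab[object@emodGrade + 1L], ")\n", sep = "")
  cat("  grade probs:", paste(sprintf("%.3f", object@gradeProbs),
                              collapse = " "), "\n")
})

setMethod("show", "ClassifierHandle", function(object) {
  tag <- object@metadata$architecture %||% "unspecified"
  cat("ClassifierHandle: ", object@nClasses, "-class, architecture '",
      tag, "'\n", sep = "")
  if (!is.null(object@metadata$selected_epoch))
    cat("  selected epoch ", object@metadata$selected_epoch, " of ",
        nrow(object@metadata$history), " (min validation CE)\n", sep = "")
})

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec: ", object@imageSize[1], "x", object@imageSize[2],
      " px, patch ", object@patchSize, " px, background ",
      object@backgroundFraction, ", noise sd ", object@noiseSd,
      ", seed ", object@seed, "\n", sep = "")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
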