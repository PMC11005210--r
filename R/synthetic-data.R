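# Synthetic slides, feature patches and score tables with known ground
# truth.  The generator emulates the data regime of the grading problem:
# bright glass background (brightness > 220/255), pink tissue, and one
# fixed oriented-grating texture motif per dysplasia feature whose
# per-tile planting probability increases with the slide grade.

TISSUE_BASE <- 156       # tissue brightness baseline (0-255)
BACKGROUND_BASE <- 242   # background brightness baseline
MOTIF_AMPLITUDE <- 30    # grating amplitude in brightness units
# Channel offsets around the brightness field; they sum to zero so the
# mean channel equals the constructed brightness exactly.
TISSUE_OFFSETS <- c(34, -26, -8)

#' The twelve dysplasia feature names
#'
#' Fixed roster order used everywhere scores are indexed: irregular
#' epithelial stratification; loss of polarity of basal cells; drop-shaped
#' rete ridges; increased number of mitotic figures; premature
#' keratinization in single cells; loss of epithelial cell cohesion;
#' abnormal variation in nuclear size; abnormal variation in nuclear
#' shape; abnormal variation in cell size; abnormal variation in cell
#' shape; increased N:C ratio; hyperchromasia.
#'
#' @return Character vector of length 12.
#' @export
dysplasiaFeatureNames <- function() {
  c("irregular_epithelial_stratification",
    "loss_of_polarity_of_basal_cells",
    "drop_shaped_rete_ridges",
    "increased_number_of_mitotic_figures",
    "premature_keratinization_in_single_cells",
    "loss_of_epithelial_cell_cohesion",
    "abnormal_variation_in_nuclear_size",
    "abnormal_variation_in_nuclear_shape",
    "abnormal_variation_in_cell_size",
    "abnormal_variation_in_cell_shape",
    "increased_nc_ratio",
    "hyperchromasia")
}

# One fixed motif per feature index: oriented sinusoidal gratings with
# distinct (orientation, period) pairs.  Features 1-8: 8 orientations at
# period 16 px; features 9-12: 4 orientations at period 32 px.
motifParams <- function(featureIndex) {
  if (!featureIndex %in% 1:12) stop("featureIndex must be in 1..12")
  if (featureIndex <= 8L) {
    list(theta = (featureIndex - 1L) * pi / 8, lambda = 16)
  } else {
    list(theta = (featureIndex - 9L) * pi / 4, lambda = 32)
  }
}

# Grating field over local pixel coordinates (1-based rows/cols).
# Deterministic, so cached per (h, w, feature).
.motifCache <- new.env(parent = emptyenv())

motifField <- function(h, w, featureIndex) {
  key <- paste(h, w, featureIndex, sep = "|")
  hit <- .motifCache[[key]]
  if (!is.null(hit)) return(hit)
  p <- motifParams(featureIndex)
  xs <- matrix(rep(seq_len(w) - 1L, each = h), nrow = h)
  ys <- matrix(rep(seq_len(h) - 1L, times = w), nrow = h)
  out <- sin(2 * pi * (xs * cos(p$theta) + ys * sin(p$theta)) / p$lambda)
  .motifCache[[key]] <- out
  out
}

#' Planted-motif statistic of a patch
#'
#' Quadrature demodulation of the patch brightness at the motif frequency
#' of `featureIndex`: the returned value estimates the amplitude (in
#' brightness units) of the oriented grating planted for that feature, and
#' is near zero for plain tissue.  Used as the independent oracle for the
#' feature-patch generator and its detectors.
#'
#' @param patchImage RGB array.
#' @param featureIndex feature in 1..12.
#' @return Nonnegative amplitude estimate.
#' @export
motifStatistic <- function(patchImage, featureIndex) {
  p <- motifParams(featureIndex)
  g <- (patchImage[, , 1] + patchImage[, , 2] + patchImage[, , 3]) / 3
  h <- nrow(g); w <- ncol(g)
  xs <- matrix(rep(seq_len(w) - 1L, each = h), nrow = h)
  ys <- matrix(rep(seq_len(h) - 1L, times = w), nrow = h)
  arg <- 2 * pi * (xs * cos(p$theta) + ys * sin(p$theta)) / p$lambda
  a <- 2 * mean(g * sin(arg))
  b <- 2 * mean(g * cos(arg))
  sqrt(a^2 + b^2)
}

#' Default grade-to-feature planting probabilities
#'
#' Rows are grades 0..3, columns the 12 features.  The default plants each
#' motif in a tissue tile with probability 0.05, 0.35, 0.65 and 0.95 for
#' hyperplasia, mild, moderate and severe slides: a strong, strictly
#' ordinal prevalence signal, the regime the grading system is designed
#' for.
#'
#' @return 4 x 12 numeric matrix.
#' @export
defaultFeatureEffect <- function() {
  matrix(rep(c(0.05, 0.35, 0.65, 0.95), 12), nrow = 4,
         dimnames = list(paste0("grade", 0:3), dysplasiaFeatureNames()))
}

#' Construct a synthetic-slide specification
#'
#' @param imageSize (height, width) in pixels.
#' @param patchSize tile edge in pixels (motif-planting grid).
#' @param backgroundFraction proportion of background pixels in [0, 1].
#' @param featureEffect grade x feature planting probabilities.
#' @param noiseSd pixel noise sd in brightness units.
#' @param labelNoise per-flag flip probability for the reported truth.
#' @param seed RNG seed.
#' @return A [SyntheticSpec-class] object.
#' @examples
#' syntheticSpec(imageSize = c(448, 448), seed = 3)
#' @export
syntheticSpec <- function(imageSize = c(1120L, 1120L), patchSize = 224L,
                          backgroundFraction = 0.25,
                          featureEffect = defaultFeatureEffect(),
                          noiseSd = 8, labelNoise = 0, seed = 1L) {
  new("SyntheticSpec",
      imageSize = as.integer(imageSize), patchSize = as.integer(patchSize),
      backgroundFraction = backgroundFraction,
      nGrades = 4L, nFeatures = 12L,
      featureEffect = featureEffect,
      noiseSd = noiseSd, labelNoise = labelNoise, seed = as.integer(seed))
}

# Smooth random field used to carve the background region: a sum of
# low-frequency cosines, thresholded at the background quantile.
smoothField <- function(h, w, nWaves = 6L) {
  xs <- matrix(rep(seq_len(w), each = h), nrow = h)
  ys <- matrix(rep(seq_len(h), times = w), nrow = h)
  f <- matrix(0, h, w)
  scale <- max(h, w)
  for (k in seq_len(nWaves)) {
    p <- runif(1, 0.5, 3) / scale
    q <- runif(1, 0.5, 3) / scale
    sx <- sample(c(-1, 1), 1); sy <- sample(c(-1, 1), 1)
    phi <- runif(1, 0, 2 * pi)
    f <- f + runif(1, 0.5, 1) * cos(2 * pi * (sx * p * xs + sy * q * ys) + phi)
  }
  f
}

#' Generate a synthetic slide with known ground truth
#'
#' Builds an RGB slide image of the requested grade: a smooth random
#' region of bright background (every background pixel has mean-channel
#' brightness > 220), pink tissue elsewhere (brightness <= 220), and, on
#' the tile grid of `spec@patchSize`, one oriented-grating motif per
#' feature planted in tissue with probability
#' `featureEffect[grade + 1, feature]`.
#'
#' @param spec a [SyntheticSpec-class].
#' @param grade slide grade in 0..3.
#' @return A list with `image` (RGB array), and `truth`: `slideGrade`,
#'   `patchFeatureFlags` (tile x 12 binary matrix, row-major tile order),
#'   `backgroundMask` (logical H x W matrix).
#' @examples
#' sim <- generateSyntheticSlide(syntheticSpec(imageSize = c(448, 448),
#'                                             seed = 11), grade = 2)
#' dim(sim$image)
#' @export
generateSyntheticSlide <- function(spec, grade) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  if (!grade %in% 0:3) stop("grade must be in 0..3")
  effects <- spec@featureEffect[grade + 1L, ]
  if (spec@backgroundFraction >= 1 && any(effects > 0))
    stop("no tissue area")
  h <- spec@imageSize[1]; w <- spec@imageSize[2]
  ps <- spec@patchSize

  withSeed(spec@seed, {
    bf <- spec@backgroundFraction
    mask <- if (bf <= 0) {
      matrix(FALSE, h, w)
    } else if (bf >= 1) {
      matrix(TRUE, h, w)
    } else {
      f <- smoothField(h, w)
      f <= quantile(f, bf)
    }

    t <- matrix(TISSUE_BASE, h, w)
    if (spec@noiseSd > 0)
      t <- t + matrix(rnorm(h * w, sd = spec@noiseSd), h, w)

    nr <- h %/% ps; nc <- w %/% ps
    nTiles <- nr * nc
    flags <- matrix(0L, nTiles, 12L,
                    dimnames = list(NULL, dysplasiaFeatureNames()))
    if (nTiles > 0L) {
      planted <- matrix(rbinom(nTiles * 12L, 1L, rep(effects, each = nTiles)),
                        nTiles, 12L)
      k <- 0L
      for (r in seq_len(nr) - 1L) {
        for (cc in seq_len(nc) - 1L) {
          k <- k + 1L
          ys <- r * ps + seq_len(ps)
          xs <- cc * ps + seq_len(ps)
          tileTissue <- !mask[ys, xs]
          if (!any(tileTissue)) next
          for (j in which(planted[k, ] == 1L)) {
            field <- MOTIF_AMPLITUDE * motifField(ps, ps, j)
            tile <- t[ys, xs]
            tile[tileTissue] <- tile[tileTissue] + field[tileTissue]
            t[ys, xs] <- tile
            flags[k, j] <- 1L
          }
        }
      }
    }
    t <- clamp(t, 30, 220)

    bg <- matrix(BACKGROUND_BASE, h, w)
    if (spec@noiseSd > 0)
      bg <- bg + matrix(rnorm(h * w, sd = spec@noiseSd), h, w)
    bg <- clamp(bg, 225, 255)

    image <- array(0, dim = c(h, w, 3L))
    for (ch in 1:3) {
      plane <- t + TISSUE_OFFSETS[ch]
      plane[mask] <- bg[mask]
      image[, , ch] <- round(clamp(plane, 0, 255))   # 8-bit channels
    }

    if (spec@labelNoise > 0 && nTiles > 0L) {
      flip <- matrix(rbinom(nTiles * 12L, 1L, spec@labelNoise), nTiles, 12L)
      flags <- abs(flags - flip)
    }

    list(image = image,
         truth = list(slideGrade = as.integer(grade),
                      patchFeatureFlags = flags,
                      backgroundMask = mask))
  })
}

#' Generate an annotated feature patch
#'
#' A 224 x 224 tissue patch with (`present = TRUE`) or without the fixed
#' texture motif of one dysplasia feature.  Deterministic under a fixed
#' seed; the planted motif raises [motifStatistic()] far above its
#' absent-case distribution.
#'
#' @param featureIndex feature in 1..12.
#' @param present logical, plant the motif?
#' @param seed RNG seed.
#' @param size patch edge in pixels (default 224).
#' @param noiseSd pixel noise sd (default 8).
#' @return RGB array `size` x `size` x 3.
#' @examples
#' p <- generateFeaturePatch(3, present = TRUE, seed = 5)
#' motifStatistic(p, 3) > 15
#' @export
generateFeaturePatch <- function(featureIndex, present, seed,
                                 size = 224L, noiseSd = 8) {
  if (!featureIndex %in% 1:12) stop("featureIndex must be in 1..12")
  withSeed(seed, {
    t <- matrix(TISSUE_BASE, size, size)
    if (noiseSd > 0)
      t <- t + matrix(rnorm(size * size, sd = noiseSd), size, size)
    if (isTRUE(present))
      t <- t + MOTIF_AMPLITUDE * motifField(size, size, featureIndex)
    t <- clamp(t, 30, 220)
    image <- array(0, dim = c(size, size, 3L))
    for (ch in 1:3)
      image[, , ch] <- round(clamp(t + TISSUE_OFFSETS[ch], 0, 255))
    image
  })
}

#' Generate a pool of multi-feature annotated patches
#'
#' Emulates an annotation campaign in which the same patches are
#' annotated yes/no for every feature: each tissue patch carries an
#' independent random subset of the 12 motifs, so the absent class for
#' any one feature includes patches bearing other features — the regime a
#' specific detector must handle.
#'
#' @param nPatches pool size.
#' @param prevalence per-feature planting probability (scalar or
#'   length 12, default 0.35).
#' @param seed RNG seed.
#' @param size patch edge (default 224).
#' @param noiseSd pixel noise sd (default 8).
#' @return List with `images` (list of RGB arrays) and `flags`
#'   (nPatches x 12 binary matrix).
#' @export
generateAnnotatedPatchPool <- function(nPatches, prevalence = 0.35,
                                       seed = 1L, size = 224L,
                                       noiseSd = 8) {
  prevalence <- rep_len(prevalence, 12L)
  withSeed(seed, {
    flags <- matrix(rbinom(nPatches * 12L, 1L, rep(prevalence, each = nPatches)),
                    nPatches, 12L,
                    dimnames = list(NULL, dysplasiaFeatureNames()))
    images <- vector("list", nPatches)
    for (i in seq_len(nPatches)) {
      t <- matrix(TISSUE_BASE, size, size)
      if (noiseSd > 0)
        t <- t + matrix(rnorm(size * size, sd = noiseSd), size, size)
      for (j in which(flags[i, ] == 1L))
        t <- t + MOTIF_AMPLITUDE * motifField(size, size, j)
      t <- clamp(t, 30, 220)
      img <- array(0, dim = c(size, size, 3L))
      for (ch in 1:3)
        img[, , ch] <- round(clamp(t + TISSUE_OFFSETS[ch], 0, 255))
      images[[i]] <- img
    }
    list(images = images, flags = flags)
  })
}

#' Draw a slide-score table from a known ordinal model
#'
#' Samples `nSlides` 12-feature score vectors from `scoreDistribution` and
#' draws each grade from the exact cumulative-logit probabilities implied
#' by `model` at that score vector — the generative counterpart of the
#' fusion model, used for calibration and parameter-recovery checks.
#'
#' @param model an [OrdinalFusionModel-class].
#' @param nSlides number of slides (>= 1).
#' @param scoreDistribution list: `type` `"uniform"` (default; `min`, `max`
#'   within [0, 100]) or `"beta"` (`shape1`, `shape2`, scaled to 0--100).
#' @param seed RNG seed.
#' @return List with `scores` (nSlides x 12 matrix, [0, 100]) and `grades`
#'   (integer vector, 0..3).
#' @examples
#' m <- ordinalFusionModel(alphas = qlogis(c(.25, .5, .75)),
#'                         betas = rep(0, 12))
#' tab <- generateScoreTable(m, nSlides = 50, seed = 2)
#' table(tab$grades)
#' @export
generateScoreTable <- function(model, nSlides,
                               scoreDistribution = list(type = "uniform",
                                                        min = 0, max = 100),
                               seed = 1L) {
  stopifnot(is(model, "OrdinalFusionModel"))
  validObject(model)
  if (nSlides < 1) stop("nSlides must be >= 1")
  p <- length(model@betas)
  withSeed(seed, {
    scores <- switch(scoreDistribution$type,
      uniform = matrix(runif(nSlides * p,
                             scoreDistribution$min %||% 0,
                             scoreDistribution$max %||% 100), nSlides, p),
      beta = 100 * matrix(stats::rbeta(nSlides * p,
                                       scoreDistribution$shape1,
                                       scoreDistribution$shape2),
                          nSlides, p),
      stop("unknown score distribution: ", scoreDistribution$type)
    )
    colnames(scores) <- if (length(model@featureNames)) model@featureNames
                        else paste0("score_", seq_len(p))
    u <- runif(nSlides)
    grades <- integer(nSlides)
    for (i in seq_len(nSlides)) {
      cum <- cumulativeProbs(model, scores[i, ])
      grades[i] <- findInterval(u[i], cumsum(cum)[1:3]) # 0..3
    }
    list(scores = scores, grades = grades)
  })
}

#' Write / read a slide-score table TSV
#'
#' Header `slide_id, score_1..score_12, grade`; scores written at full
#' precision.
#'
#' @param scores n x 12 matrix of slide scores.
#' @param grades integer grades 0..3 (NA allowed).
#' @param path TSV path.
#' @param slideIds optional identifiers (default `slide_1..n`).
#' @return `path` invisibly; the reader returns a list
#'   `(scores, grades, slideIds)`.
#' @export
writeScoreTable <- function(scores, grades, path, slideIds = NULL) {
  n <- nrow(scores)
  if (is.null(slideIds)) slideIds <- paste0("slide_", seq_len(n))
  out <- data.frame(slide_id = slideIds, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(scores)))
    out[[paste0("score_", j)]] <- formatNumeric(scores[, j])
  out$grade <- as.integer(grades)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeScoreTable
#' @export
readScoreTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(slide_id = "character"))
  scoreCols <- grep("^score_", names(tab), value = TRUE)
  scores <- as.matrix(tab[, scoreCols])
  storage.mode(scores) <- "double"
  list(scores = scores, grades = as.integer(tab$grade),
       slideIds = tab$slide_id)
}

#' Write a synthetic slide and its ground truth to disk
#'
#' The slide is written as 8-bit PNG, the background mask as a PNG
#' (white = background) and the remaining truth (grade, per-tile feature
#' flags) as JSON.
#'
#' @param sim result of [generateSyntheticSlide()].
#' @param dir output directory (created if needed).
#' @param id slide identifier used in the file names.
#' @return Named character vector of written paths, invisibly.
#' @export
writeSyntheticSlide <- function(sim, dir, id) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  imgPath <- file.path(dir, paste0(id, ".png"))
  maskPath <- file.path(dir, paste0(id, "_mask.png"))
  truthPath <- file.path(dir, paste0(id, "_truth.json"))
  writeImageFile(sim$image, imgPath)
  png::writePNG(sim$truth$backgroundMask * 1, maskPath)
  jsonlite::write_json(
    list(slide_id = id,
         grade = sim$truth$slideGrade,
         patch_feature_flags = sim$truth$patchFeatureFlags),
    truthPath, auto_unbox = TRUE, digits = NA)
  invisible(c(image = imgPath, mask = maskPath, truth = truthPath))
}
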