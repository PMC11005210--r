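# Pipeline orchestration: YAML configuration, per-stage seeds, JSON-line
# logging, and the subcommands wiring the modules into the full
# simulate -> tile -> train -> score -> fuse -> predict -> evaluate chain.
# All artifacts are plain text or PNG under config$paths$workdir.

PIPELINE_SUBCOMMANDS <- c("simulate", "tile", "train-grade",
                          "train-feature", "grid-search", "score",
                          "fuse-fit", "predict", "evaluate", "heatmap")

#' Default pipeline configuration
#'
#' Protocol defaults (224-px patches at working magnification, background
#' brightness 220, over-50% exclusion, 60/15/25 splits, RMSprop batch 80)
#' with desk-scale synthetic-cohort sizes.  Values can be overridden by a
#' YAML file read with [readPipelineConfig()].
#'
#' @param workdir artifact directory.
#' @param seed global seed (fans out per stage via [deriveStageSeed()]).
#' @return Nested configuration list.
#' @export
defaultPipelineConfig <- function(workdir = "oedgrader-out", seed = 1L) {
  list(
    seed = as.integer(seed),
    paths = list(workdir = workdir),
    tiling = list(patch_size = 224L, magnification_factor = 1L,
                  brightness_threshold = 220L, max_background = 0.5,
                  write_patches = FALSE),
    simulate = list(n_train_per_grade = 6L, n_test_per_grade = 4L,
                    image_size = c(672L, 672L), background_fraction = 0.25,
                    noise_sd = 8, n_feature_patches = 200L),
    train = list(learning_rate = 0.02, batch_size = 80L, max_epochs = 30L,
                 split_fractions = c(0.60, 0.15, 0.25)),
    fusion = list(lambda = 0.5, maxit = 500L, tol = 1e-8),
    evaluation = list(n_boot = 200L, level = 0.95)
  )
}

#' Read and validate a YAML pipeline configuration
#'
#' Missing fields are filled from [defaultPipelineConfig()]; the merged
#' configuration is validated against the schema.
#'
#' @param path YAML file.
#' @return Validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  merge2 <- function(base, upd) {
    for (nm in names(upd)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(upd[[nm]]))
        merge2(base[[nm]], upd[[nm]]) else upd[[nm]]
    }
    base
  }
  cfg <- merge2(defaultPipelineConfig(), user)
  validatePipelineConfig(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' @param config configuration list.
#' @return `config` invisibly; schema violations raise errors.
#' @export
validatePipelineConfig <- function(config) {
  fail <- function(...) stop("config schema: ", sprintf(...), call. = FALSE)
  if (is.null(config$paths$workdir)) fail("paths.workdir missing")
  t <- config$tiling
  if (is.null(t$patch_size) || t$patch_size < 1) fail("tiling.patch_size must be >= 1")
  if (!t$magnification_factor %in% c(1, 2))
    fail("tiling.magnification_factor must be 1 or 2")
  if (t$max_background < 0 || t$max_background > 1)
    fail("tiling.max_background must be in [0, 1]")
  if (t$brightness_threshold < 0 || t$brightness_threshold > 255)
    fail("tiling.brightness_threshold must be in [0, 255]")
  s <- config$simulate
  if (s$background_fraction < 0 || s$background_fraction > 1)
    fail("simulate.background_fraction must be in [0, 1]")
  if (any(unlist(s[c("n_train_per_grade", "n_test_per_grade",
                     "n_feature_patches")]) < 1))
    fail("simulate cohort sizes must be >= 1")
  tr <- config$train
  if (tr$learning_rate <= 0) fail("train.learning_rate must be > 0")
  if (tr$batch_size < 1 || tr$max_epochs < 1)
    fail("train.batch_size and max_epochs must be >= 1")
  if (abs(sum(tr$split_fractions) - 1) > 1e-8)
    fail("train.split_fractions must sum to 1")
  if (config$fusion$lambda < 0) fail("fusion.lambda must be >= 0")
  if (config$evaluation$n_boot < 100) fail("evaluation.n_boot must be >= 100")
  invisible(config)
}

logStage <- function(stage, ..., logFile = NULL) {
  entry <- c(list(stage = stage,
                  package_version = as.character(utils::packageVersion("oedgrader")),
                  time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             list(...))
  line <- jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA)
  message(line)
  if (!is.null(logFile)) cat(line, "\n", file = logFile, append = TRUE)
}

cohortPath <- function(cfg) file.path(cfg$paths$workdir, "cohort.tsv")

readCohort <- function(cfg) {
  read.delim(cohortPath(cfg), stringsAsFactors = FALSE,
             colClasses = c(slide_id = "character"))
}

trainCfgFromPipeline <- function(cfg, seed) {
  trainConfig(learningRate = cfg$train$learning_rate,
              batchSize = cfg$train$batch_size,
              maxEpochs = cfg$train$max_epochs,
              splitFractions = cfg$train$split_fractions,
              seed = seed, patchSize = cfg$tiling$patch_size)
}

loadFeatureModels <- function(cfg) {
  lapply(1:12, function(j)
    loadClassifier(file.path(cfg$paths$workdir, "models",
                             sprintf("feature_%02d", j))))
}

foregroundPatchesForSlide <- function(cfg, id) {
  img <- readImageFile(file.path(cfg$paths$workdir, "slides",
                                 paste0(id, ".png")))
  img <- rescaleMagnification(img, cfg$tiling$magnification_factor)
  filterForeground(
    tileImage(img, cfg$tiling$patch_size, slideId = id,
              brightnessThreshold = cfg$tiling$brightness_threshold),
    cfg$tiling$max_background)
}

# ---- subcommands ---------------------------------------------------------

cmdSimulate <- function(cfg, log) {
  wd <- cfg$paths$workdir
  dir.create(file.path(wd, "slides"), recursive = TRUE, showWarnings = FALSE)
  seed0 <- deriveStageSeed(cfg$seed, "simulate")
  s <- cfg$simulate
  rows <- list(); k <- 0L
  for (split in c("train", "test")) {
    nPer <- if (split == "train") s$n_train_per_grade else s$n_test_per_grade
    for (g in 0:3) {
      for (i in seq_len(nPer)) {
        k <- k + 1L
        id <- sprintf("%s_g%d_%02d", split, g, i)
        spec <- syntheticSpec(imageSize = s$image_size,
                              patchSize = cfg$tiling$patch_size,
                              backgroundFraction = s$background_fraction,
                              noiseSd = s$noise_sd,
                              seed = deriveStageSeed(seed0, id))
        sim <- generateSyntheticSlide(spec, g)
        writeSyntheticSlide(sim, file.path(wd, "slides"), id)
        rows[[k]] <- data.frame(slide_id = id, grade = g, split = split,
                                stringsAsFactors = FALSE)
      }
    }
  }
  write.table(do.call(rbind, rows), cohortPath(cfg), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # annotated patch pool for detector training: every patch is annotated
  # yes/no for all 12 features, as in a shared annotation campaign
  fpDir <- file.path(wd, "feature_patches")
  dir.create(fpDir, recursive = TRUE, showWarnings = FALSE)
  pool <- generateAnnotatedPatchPool(
    s$n_feature_patches, seed = deriveStageSeed(seed0, "annotation-pool"),
    size = cfg$tiling$patch_size, noiseSd = s$noise_sd)
  ids <- sprintf("pool_%04d", seq_len(s$n_feature_patches))
  for (i in seq_along(ids))
    writeImageFile(pool$images[[i]], file.path(fpDir, paste0(ids[i], ".png")))
  man <- data.frame(patch_id = ids, stringsAsFactors = FALSE)
  for (j in 1:12) man[[sprintf("f%02d", j)]] <- pool$flags[, j]
  write.table(man, file.path(fpDir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  logStage("simulate", n_slides = nrow(readCohort(cfg)),
           n_feature_patches = s$n_feature_patches, seed = seed0,
           logFile = log)
  invisible(0L)
}

cmdTile <- function(cfg, log) {
  wd <- cfg$paths$workdir
  cohort <- readCohort(cfg)
  dir.create(file.path(wd, "tiles"), recursive = TRUE, showWarnings = FALSE)
  nFg <- 0L
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$slide_id[i]
    img <- readImageFile(file.path(wd, "slides", paste0(id, ".png")))
    img <- rescaleMagnification(img, cfg$tiling$magnification_factor)
    ps <- tileImage(img, cfg$tiling$patch_size, slideId = id,
                    label = cohort$grade[i],
                    brightnessThreshold = cfg$tiling$brightness_threshold)
    fg <- filterForeground(ps, cfg$tiling$max_background)
    writePatchManifest(fg, file.path(wd, "tiles", paste0(id, ".tsv")))
    if (isTRUE(cfg$tiling$write_patches)) {
      pdir <- file.path(wd, "tiles", id)
      dir.create(pdir, showWarnings = FALSE)
      m <- manifest(fg)
      for (p in seq_len(nrow(m)))
        writeImageFile(patchImages(fg)[[p]],
                       file.path(pdir, sprintf("r%02d_c%02d.png",
                                               m$row[p], m$col[p])))
    }
    nFg <- nFg + length(fg)
  }
  logStage("tile", n_slides = nrow(cohort), n_foreground_patches = nFg,
           logFile = log)
  invisible(0L)
}

cmdTrainFeature <- function(cfg, log, featureIndex = NULL) {
  wd <- cfg$paths$workdir
  fpDir <- file.path(wd, "feature_patches")
  man <- read.delim(file.path(fpDir, "manifest.tsv"),
                    stringsAsFactors = FALSE)
  images <- lapply(man$patch_id, function(id)
    readImageFile(file.path(fpDir, paste0(id, ".png"))))
  # the split is shared across features (same annotated pool)
  splitSeed <- deriveStageSeed(cfg$seed, "train-feature-split")
  sp <- splitDataset(seq_along(images), cfg$train$split_fractions, splitSeed)
  idxs <- if (is.null(featureIndex)) 1:12 else featureIndex
  for (j in idxs) {
    labels <- man[[sprintf("f%02d", j)]]
    seed <- deriveStageSeed(cfg$seed, sprintf("train-feature-%02d", j))
    tc <- trainCfgFromPipeline(cfg, seed)
    h <- trainClassifier(patchDataset(images[sp$train], labels[sp$train]),
                         patchDataset(images[sp$val], labels[sp$val]), tc)
    saveClassifier(h, file.path(wd, "models", sprintf("feature_%02d", j)))
    logStage("train-feature", feature = j, seed = seed,
             selected_epoch = h@metadata$selected_epoch,
             val_loss = min(h@metadata$history$val_loss), logFile = log)
  }
  invisible(0L)
}

trainGradePatchData <- function(cfg) {
  cohort <- readCohort(cfg)
  cohort <- cohort[cohort$split == "train", ]
  images <- list(); labels <- integer(0)
  for (i in seq_len(nrow(cohort))) {
    fg <- foregroundPatchesForSlide(cfg, cohort$slide_id[i])
    images <- c(images, patchImages(fg))
    labels <- c(labels, rep(cohort$grade[i], length(fg)))
  }
  list(images = images, labels = labels)
}

cmdTrainGrade <- function(cfg, log) {
  dat <- trainGradePatchData(cfg)
  seed <- deriveStageSeed(cfg$seed, "train-grade")
  tc <- trainCfgFromPipeline(cfg, seed)
  sp <- splitDataset(seq_along(dat$images), tc$splitFractions, seed)
  h <- trainClassifier(
    patchDataset(dat$images[sp$train], dat$labels[sp$train]),
    patchDataset(dat$images[sp$val], dat$labels[sp$val]), tc)
  saveClassifier(h, file.path(cfg$paths$workdir, "models", "grade"))
  logStage("train-grade", n_patches = length(dat$images), seed = seed,
           selected_epoch = h@metadata$selected_epoch, logFile = log)
  invisible(0L)
}

cmdGridSearch <- function(cfg, log) {
  dat <- trainGradePatchData(cfg)
  seed <- deriveStageSeed(cfg$seed, "grid-search")
  grid <- cfg$grid %||% list(list(learning_rate = cfg$train$learning_rate,
                                  max_epochs = cfg$train$max_epochs))
  configs <- lapply(seq_along(grid), function(i) {
    g <- grid[[i]]
    trainConfig(
      learningRate = g$learning_rate %||% cfg$train$learning_rate,
      batchSize = g$batch_size %||% cfg$train$batch_size,
      maxEpochs = g$max_epochs %||% cfg$train$max_epochs,
      splitFractions = cfg$train$split_fractions,
      seed = deriveStageSeed(seed, paste0("cell", i)),
      patchSize = cfg$tiling$patch_size,
      magnification = g$magnification %||% "20x")
  })
  tab <- gridSearch(dat$images, dat$labels, configs)
  write.table(tab, file.path(cfg$paths$workdir, "grid.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  logStage("grid-search", n_cells = nrow(tab), logFile = log)
  invisible(0L)
}

cmdScore <- function(cfg, log) {
  wd <- cfg$paths$workdir
  cohort <- readCohort(cfg)
  featureModels <- loadFeatureModels(cfg)
  scores <- matrix(0, nrow(cohort), 12L,
                   dimnames = list(NULL, dysplasiaFeatureNames()))
  for (i in seq_len(nrow(cohort))) {
    fg <- foregroundPatchesForSlide(cfg, cohort$slide_id[i])
    if (length(fg) == 0L) stop("empty slide: ", cohort$slide_id[i])
    scores[i, ] <- slideScores(scorePatchFeatures(fg, featureModels))
  }
  for (split in unique(cohort$split)) {
    sel <- cohort$split == split
    writeScoreTable(scores[sel, , drop = FALSE], cohort$grade[sel],
                    file.path(wd, sprintf("scores_%s.tsv", split)),
                    slideIds = cohort$slide_id[sel])
  }
  logStage("score", n_slides = nrow(cohort), logFile = log)
  invisible(0L)
}

cmdFuseFit <- function(cfg, log) {
  wd <- cfg$paths$workdir
  tab <- readScoreTable(file.path(wd, "scores_train.tsv"))
  model <- fitOrdinal(tab$scores, tab$grades,
                      lambda = cfg$fusion$lambda,
                      maxit = cfg$fusion$maxit, tol = cfg$fusion$tol)
  writeOrdinalModel(model, file.path(wd, "fusion.json"))
  logStage("fuse-fit", n_slides = length(tab$grades),
           loglik = model@fit$loglik,
           gradient_norm = model@fit$gradient_norm, logFile = log)
  invisible(0L)
}

cmdPredict <- function(cfg, log) {
  wd <- cfg$paths$workdir
  cohort <- readCohort(cfg)
  test <- cohort[cohort$split == "test", ]
  fusion <- readOrdinalModel(file.path(wd, "fusion.json"))
  gradeModel <- loadClassifier(file.path(wd, "models", "grade"))
  featureModels <- loadFeatureModels(cfg)
  dir.create(file.path(wd, "predictions"), showWarnings = FALSE)
  rows <- list()
  for (i in seq_len(nrow(test))) {
    id <- test$slide_id[i]
    img <- readImageFile(file.path(wd, "slides", paste0(id, ".png")))
    pred <- gradeSlide(img, gradeModel, featureModels, fusion,
                       slideId = id, patchSize = cfg$tiling$patch_size,
                       maxBackground = cfg$tiling$max_background,
                       magnificationFactor = cfg$tiling$magnification_factor)
    jsonlite::write_json(
      list(slide_id = id, emodplus_grade = pred@emodplusGrade,
           emod_grade = pred@emodGrade, grade_probs = pred@gradeProbs,
           feature_scores = pred@featureScores,
           patch_grade_fractions = pred@patchGradeFractions),
      file.path(wd, "predictions", paste0(id, ".json")),
      auto_unbox = TRUE, digits = NA)
    rows[[i]] <- data.frame(
      slide_id = id, true_grade = test$grade[i],
      emodplus_grade = pred@emodplusGrade, emod_grade = pred@emodGrade,
      p0 = pred@gradeProbs[1], p1 = pred@gradeProbs[2],
      p2 = pred@gradeProbs[3], p3 = pred@gradeProbs[4],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  write.table(out, file.path(wd, "predictions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  logStage("predict", n_slides = nrow(out), logFile = log)
  invisible(0L)
}

cmdEvaluate <- function(cfg, log) {
  wd <- cfg$paths$workdir
  pred <- read.delim(file.path(wd, "predictions.tsv"),
                     stringsAsFactors = FALSE)
  probs <- as.matrix(pred[, c("p0", "p1", "p2", "p3")])
  probs <- probs / rowSums(probs)
  report <- evaluatePredictions(pred$true_grade, pred$emodplus_grade,
                                probs, nBoot = cfg$evaluation$n_boot,
                                level = cfg$evaluation$level,
                                seed = deriveStageSeed(cfg$seed, "evaluate"))
  jsonlite::write_json(
    list(metrics = as.list(metrics(report)),
         ci = metricCI(report), n_boot = report@nBoot, n = report@n),
    file.path(wd, "report.json"), auto_unbox = TRUE, digits = NA)
  logStage("evaluate", accuracy = metrics(report)[["accuracy"]],
           auc = metrics(report)[["auc"]], logFile = log)
  invisible(0L)
}

cmdHeatmap <- function(cfg, log) {
  wd <- cfg$paths$workdir
  cohort <- readCohort(cfg)
  test <- cohort[cohort$split == "test", ]
  gradeModel <- loadClassifier(file.path(wd, "models", "grade"))
  dir.create(file.path(wd, "heatmaps"), showWarnings = FALSE)
  for (id in test$slide_id) {
    fg <- foregroundPatchesForSlide(cfg, id)
    P <- predictScores(gradeModel, fg)
    writeImageFile(renderHeatmap(fg, P),
                   file.path(wd, "heatmaps", paste0(id, ".png")))
  }
  logStage("heatmap", n_slides = nrow(test), logFile = log)
  invisible(0L)
}

#' Run one pipeline subcommand
#'
#' Dispatches the named stage of the grading pipeline against a validated
#' configuration.  Every stage reads and writes only the documented
#' plain-text/PNG formats under `config$paths$workdir` and appends a JSON
#' log line (stage, seeds, counts) to stderr and to
#' `workdir/pipeline.log`.
#'
#' @param name one of `simulate`, `tile`, `train-grade`, `train-feature`,
#'   `grid-search`, `score`, `fuse-fit`, `predict`, `evaluate`, `heatmap`.
#' @param config configuration list (see [defaultPipelineConfig()]).
#' @param featureIndex optional single feature for `train-feature`.
#' @return 0 invisibly on success; errors propagate.
#' @export
runSubcommand <- function(name, config, featureIndex = NULL) {
  name <- match.arg(name, PIPELINE_SUBCOMMANDS)
  validatePipelineConfig(config)
  dir.create(config$paths$workdir, recursive = TRUE, showWarnings = FALSE)
  log <- file.path(config$paths$workdir, "pipeline.log")
  switch(name,
    "simulate" = cmdSimulate(config, log),
    "tile" = cmdTile(config, log),
    "train-grade" = cmdTrainGrade(config, log),
    "train-feature" = cmdTrainFeature(config, log, featureIndex),
    "grid-search" = cmdGridSearch(config, log),
    "score" = cmdScore(config, log),
    "fuse-fit" = cmdFuseFit(config, log),
    "predict" = cmdPredict(config, log),
    "evaluate" = cmdEvaluate(config, log),
    "heatmap" = cmdHeatmap(config, log))
}
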