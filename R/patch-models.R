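# Pluggable patch-classifier stage: splitting, training protocol (RMSprop,
# cross-entropy, mini-batches, min-validation-loss snapshot selection),
# grid search and score extraction.  The reference architecture is the
# fixed Gabor convolutional front end (featurizer.R) with a trainable
# softmax layer.

#' Training configuration
#'
#' Defaults mirror the study protocol: RMSprop, cross-entropy,
#' mini-batch 80, 100 epochs, learning rate 1e-4, 60/15/25 splits, 224-px
#' patches at 20x.  The feature-detector variant (200 epochs, learning
#' rate 1e-6) is expressed purely through these fields — there is no
#' separate code path.  For the package's small softmax head a larger
#' learning rate (~0.02) is appropriate; see the methods vignette.
#'
#' @param learningRate RMSprop learning rate.
#' @param batchSize mini-batch size.
#' @param maxEpochs maximum training epochs.
#' @param optimizer only `"rmsprop"` is implemented.
#' @param loss only `"crossentropy"` is implemented.
#' @param splitFractions (train, val, test) proportions summing to 1.
#' @param seed seed for initialization and shuffling.
#' @param patchSize nominal patch edge (224 or 512), recorded in metadata.
#' @param magnification `"20x"` or `"10x"`, recorded in metadata.
#' @return A named list of class `trainConfig`.
#' @export
trainConfig <- function(learningRate = 1e-4, batchSize = 80L,
                        maxEpochs = 100L, optimizer = "rmsprop",
                        loss = "crossentropy",
                        splitFractions = c(0.60, 0.15, 0.25),
                        seed = 1L, patchSize = 224L,
                        magnification = "20x") {
  stopifnot(length(splitFractions) == 3, all(splitFractions > 0),
            abs(sum(splitFractions) - 1) < 1e-8)
  if (!identical(optimizer, "rmsprop")) stop("optimizer must be 'rmsprop'")
  if (!identical(loss, "crossentropy")) stop("loss must be 'crossentropy'")
  structure(list(learningRate = learningRate,
                 batchSize = as.integer(batchSize),
                 maxEpochs = as.integer(maxEpochs),
                 optimizer = optimizer, loss = loss,
                 splitFractions = splitFractions, seed = as.integer(seed),
                 patchSize = as.integer(patchSize),
                 magnification = magnification),
            class = "trainConfig")
}

#' Split items into train / validation / test sets
#'
#' Random exhaustive disjoint partition with largest-remainder rounding of
#' the target sizes (so 100 items at 0.6/0.15/0.25 give exactly
#' 60/15/25), reproducible under `seed`.
#'
#' @param items a list or vector.
#' @param fractions (train, val, test) proportions summing to 1.
#' @param seed RNG seed.
#' @return List with `train`, `val`, `test` (same container type), plus an
#'   `indices` attribute with the index partition.
#' @export
splitDataset <- function(items, fractions = c(0.60, 0.15, 0.25), seed = 1L) {
  n <- length(items)
  if (n < 3) stop("need at least 3 items to split")
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  target <- n * fractions
  sizes <- floor(target)
  rem <- target - sizes
  short <- n - sum(sizes)
  if (short > 0) {
    give <- order(rem, decreasing = TRUE)[seq_len(short)]
    sizes[give] <- sizes[give] + 1
  }
  perm <- withSeed(seed, sample.int(n))
  idx <- list(train = perm[seq_len(sizes[1])],
              val = perm[sizes[1] + seq_len(sizes[2])],
              test = perm[sizes[1] + sizes[2] + seq_len(sizes[3])])
  out <- lapply(idx, function(i) items[sort(i)])
  attr(out, "indices") <- lapply(idx, sort)
  out
}

#' Bundle patch images and labels into a dataset
#'
#' @param images list of RGB arrays.
#' @param labels integer class labels, 0-based.
#' @return A list `(images, labels)` of class `patchDataset`.
#' @export
patchDataset <- function(images, labels) {
  stopifnot(length(images) == length(labels))
  structure(list(images = images, labels = as.integer(labels)),
            class = "patchDataset")
}

softmaxRows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

crossEntropy <- function(P, labels) {
  -mean(log(pmax(P[cbind(seq_along(labels), labels + 1L)], 1e-300)))
}

#' Train a patch classifier
#'
#' Trains the softmax layer of the reference convolutional classifier with
#' RMSprop on mini-batched cross-entropy, from seeded random initial
#' weights.  After every epoch the validation cross-entropy is recorded;
#' the returned model is the epoch snapshot with the lowest validation
#' loss (ties broken toward the earliest epoch).  The full per-epoch
#' train/validation loss history is kept in the handle metadata.
#'
#' @param trainSet,valSet `patchDataset` objects (non-empty; the training
#'   set must contain at least two classes).
#' @param config a [trainConfig()].
#' @param architecture featurizer description from [gaborArchitecture()].
#' @return A [ClassifierHandle-class].
#' @export
trainClassifier <- function(trainSet, valSet, config = trainConfig(),
                            architecture = gaborArchitecture()) {
  stopifnot(inherits(trainSet, "patchDataset"),
            inherits(valSet, "patchDataset"))
  if (!length(trainSet$images) || !length(valSet$images))
    stop("train and validation sets must be non-empty")
  if (length(unique(trainSet$labels)) < 2)
    stop("degenerate labels: training set contains a single class")
  K <- max(c(trainSet$labels, valSet$labels)) + 1L

  Xtr <- featurizePatches(trainSet$images, architecture)
  Xva <- featurizePatches(valSet$images, architecture)
  mu <- colMeans(Xtr)
  sg <- apply(Xtr, 2, sd)
  sg[sg < 1e-12] <- 1
  std <- function(X) sweep(sweep(X, 2, mu), 2, sg, "/")
  Xtr <- cbind(1, std(Xtr))
  Xva <- cbind(1, std(Xva))
  D <- ncol(Xtr)
  ytr <- trainSet$labels; yva <- valSet$labels
  n <- nrow(Xtr)
  Ytr <- matrix(0, n, K); Ytr[cbind(seq_len(n), ytr + 1L)] <- 1

  rho <- 0.9; eps <- 1e-8
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  withSeed(config$seed, {
    W <- matrix(rnorm(D * K, sd = 0.01), D, K)
    ms <- matrix(0, D, K)
    bestW <- W; bestVal <- Inf; bestEpoch <- 0L
    for (epoch in seq_len(config$maxEpochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batchSize)
      for (s in starts) {
        idx <- ord[s:min(s + config$batchSize - 1L, n)]
        Xb <- Xtr[idx, , drop = FALSE]
        Pb <- softmaxRows(Xb %*% W)
        G <- crossprod(Xb, Pb - Ytr[idx, , drop = FALSE]) / length(idx)
        ms <- rho * ms + (1 - rho) * G^2
        W <- W - config$learningRate * G / (sqrt(ms) + eps)
      }
      trLoss <- crossEntropy(softmaxRows(Xtr %*% W), ytr)
      vaLoss <- crossEntropy(softmaxRows(Xva %*% W), yva)
      history[epoch, ] <- list(epoch, trLoss, vaLoss)
      if (vaLoss < bestVal) {   # strict: earliest epoch wins ties
        bestVal <- vaLoss; bestW <- W; bestEpoch <- epoch
      }
    }
    makeSoftmaxHandle(bestW, mu, sg, K, architecture,
                      history = history, selectedEpoch = bestEpoch,
                      config = config)
  })
}

# Build a ClassifierHandle around trained softmax weights.  The handle
# carries a feature-space scorer (metadata$scoreFeatures) so pipelines
# that featurize once can score many models cheaply; predict() remains
# the image-level contract.
makeSoftmaxHandle <- function(W, mu, sg, K, architecture, history = NULL,
                              selectedEpoch = NULL, config = NULL) {
  scoreFeatures <- function(X) {
    X <- sweep(sweep(as.matrix(X), 2, mu), 2, sg, "/")
    softmaxRows(cbind(1, X) %*% W)
  }
  predict <- function(patches) {
    if (is(patches, "PatchSet")) patches <- patchImages(patches)
    if (!length(patches)) return(matrix(numeric(0), 0, K))
    scoreFeatures(featurizePatches(patches, architecture))
  }
  new("ClassifierHandle", predict = predict, nClasses = as.integer(K),
      metadata = list(architecture = architecture$tag,
                      featurizer = architecture,
                      weights = W, feature_mean = mu, feature_sd = sg,
                      history = history, selected_epoch = selectedEpoch,
                      config = config, scoreFeatures = scoreFeatures))
}

#' A constant stub classifier
#'
#' Emits the same probability vector for every patch.  Satisfies the full
#' classifier contract; used to exercise downstream stages independently
#' of training.
#'
#' @param probs probability vector (nonnegative, sums to 1).
#' @return A [ClassifierHandle-class].
#' @examples
#' stub <- constantClassifier(c(0.73, 0.27))
#' @export
constantClassifier <- function(probs) {
  stopifnot(all(probs >= 0), abs(sum(probs) - 1) < 1e-6)
  K <- length(probs)
  predict <- function(patches) {
    if (is(patches, "PatchSet")) patches <- patchImages(patches)
    matrix(probs, nrow = length(patches), ncol = K, byrow = TRUE)
  }
  new("ClassifierHandle", predict = predict, nClasses = as.integer(K),
      metadata = list(architecture = "constant-stub"))
}

#' Softmax score matrix for a set of patches
#'
#' @param model a [ClassifierHandle-class].
#' @param patches list of RGB arrays or a [PatchSet-class].
#' @return n x K probability matrix (rows sum to 1, order preserved);
#'   empty input gives a 0 x K matrix.
#' @export
predictScores <- function(model, patches) {
  stopifnot(is(model, "ClassifierHandle"))
  P <- model@predict(patches)
  if (nrow(P) && any(abs(rowSums(P) - 1) > 1e-6))
    stop("classifier emitted non-normalized probabilities")
  P
}

#' Grid search over training configurations and architectures
#'
#' Trains one model per (architecture, config) cell on the given labeled
#' patches — each cell splits the data with its own config fractions and
#' seed — and ranks cells by held-out test accuracy, then macro one-vs-rest
#' AUC.  Training errors in a cell are recorded and the sweep continues.
#'
#' @param images list of RGB patches.
#' @param labels integer labels (0-based).
#' @param configs list of [trainConfig()] objects (>= 1).
#' @param architectures list of [gaborArchitecture()] descriptions.
#' @return data.frame ranked best-first: architecture, config fields, test
#'   accuracy, test AUC, error message (NA when trained), plus the trained
#'   handles in the `models` attribute (in table order).
#' @export
gridSearch <- function(images, labels, configs,
                       architectures = list(gaborArchitecture())) {
  if (!length(configs)) stop("need at least one config")
  rows <- list(); models <- list(); r <- 0L
  for (arch in architectures) {
    for (cf in configs) {
      r <- r + 1L
      res <- tryCatch({
        sp <- splitDataset(seq_along(images), cf$splitFractions, cf$seed)
        tr <- patchDataset(images[sp$train], labels[sp$train])
        va <- patchDataset(images[sp$val], labels[sp$val])
        te <- patchDataset(images[sp$test], labels[sp$test])
        h <- trainClassifier(tr, va, cf, arch)
        P <- predictScores(h, te$images)
        pred <- max.col(P, ties.method = "last") - 1L
        acc <- mean(pred == te$labels)
        present <- intersect(unique(te$labels), seq_len(ncol(P)) - 1L)
        auc <- mean(vapply(present, function(k)
          midrankAUC(P[, k + 1], te$labels == k), numeric(1)),
          na.rm = TRUE)
        list(handle = h, acc = acc, auc = auc, err = NA_character_)
      }, error = function(e) list(handle = NULL, acc = NA_real_,
                                  auc = NA_real_, err = conditionMessage(e)))
      rows[[r]] <- data.frame(
        architecture = arch$tag,
        learning_rate = cf$learningRate, batch_size = cf$batchSize,
        max_epochs = cf$maxEpochs, patch_size = cf$patchSize,
        magnification = cf$magnification, seed = cf$seed,
        test_accuracy = res$acc, test_auc = res$auc,
        error = res$err, stringsAsFactors = FALSE)
      models[[r]] <- res$handle
    }
  }
  tab <- do.call(rbind, rows)
  ord <- order(-ifelse(is.na(tab$test_accuracy), -Inf, tab$test_accuracy),
               -ifelse(is.na(tab$test_auc), -Inf, tab$test_auc))
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "models") <- models[ord]
  tab
}

#' Save / load a trained classifier checkpoint directory
#'
#' The checkpoint is a directory holding the architecture description and
#' training history as JSON and the softmax weights and feature
#' standardization as TSV — all plain text.
#'
#' @param model a trained [ClassifierHandle-class] (from
#'   [trainClassifier()]).
#' @param dir checkpoint directory.
#' @return `dir` invisibly; the loader returns the handle.
#' @export
saveClassifier <- function(model, dir) {
  md <- model@metadata
  if (is.null(md$weights)) stop("only trained softmax handles can be saved")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(architecture = md$featurizer, n_classes = model@nClasses,
         selected_epoch = md$selected_epoch,
         config = md$config[setdiff(names(md$config), "splitFractions")]),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  write.table(md$history, file.path(dir, "history.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(md$weights, file.path(dir, "weights.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(data.frame(mean = md$feature_mean, sd = md$feature_sd),
              file.path(dir, "standardization.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname saveClassifier
#' @export
loadClassifier <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  arch <- gaborArchitecture(meta$architecture$orientations,
                            unlist(meta$architecture$wavelengths),
                            meta$architecture$pool,
                            meta$architecture$kernelSize)
  W <- as.matrix(read.delim(file.path(dir, "weights.tsv"), header = FALSE))
  dimnames(W) <- NULL
  stdz <- read.delim(file.path(dir, "standardization.tsv"))
  history <- read.delim(file.path(dir, "history.tsv"))
  makeSoftmaxHandle(W, stdz$mean, stdz$sd, as.integer(meta$n_classes),
                    arch, history = history,
                    selectedEpoch = meta$selected_epoch)
}
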