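# Reference patch featurizer: a fixed bank of oriented Gabor kernels whose
# response energies are computed in the frequency domain (Parseval), plus
# global intensity statistics.  This is the convolutional front end of the
# package's small reference classifier; the convolution weights are fixed,
# only the softmax layer on top is trained.

#' Describe the reference convolutional featurizer
#'
#' A compound-scalable description of the fixed front end: `orientations`
#' Gabor orientations crossed with `wavelengths` (in pixels at the pooled
#' resolution), pooling factor `pool`, kernel edge `kernelSize`.  The
#' feature vector is the per-kernel RMS response energy plus 8 global
#' intensity statistics.
#'
#' @param orientations number of evenly spaced orientations (default 8).
#' @param wavelengths Gabor wavelengths at pooled resolution (default 4, 8
#'   px, matching 8 and 16 px at full resolution with `pool = 2`).
#' @param pool mean-pooling factor applied before filtering (default 2).
#' @param kernelSize Gabor kernel edge (default 11).
#' @return A list describing the architecture (tag, parameters).
#' @export
gaborArchitecture <- function(orientations = 8L, wavelengths = c(4, 8),
                              pool = 2L, kernelSize = 11L) {
  list(tag = sprintf("gabor-energy(%do x %dw, pool %d)",
                     orientations, length(wavelengths), pool),
       orientations = as.integer(orientations),
       wavelengths = wavelengths,
       pool = as.integer(pool),
       kernelSize = as.integer(kernelSize))
}

gaborKernel <- function(theta, lambda, size) {
  half <- (size - 1) / 2
  xs <- matrix(rep(-half:half, each = size), nrow = size)
  ys <- matrix(rep(-half:half, times = size), nrow = size)
  sigma <- 0.6 * lambda
  k <- exp(-(xs^2 + ys^2) / (2 * sigma^2)) *
    cos(2 * pi * (xs * cos(theta) + ys * sin(theta)) / lambda)
  k <- k - mean(k)
  k / sqrt(sum(k^2))
}

# Cache of |FFT(kernel)|^2 stacks per (architecture tag, pooled dims).
.kernelCache <- new.env(parent = emptyenv())

kernelPowerStack <- function(arch, h, w) {
  key <- paste(arch$tag, h, w, sep = "|")
  hit <- .kernelCache[[key]]
  if (!is.null(hit)) return(hit)
  thetas <- (seq_len(arch$orientations) - 1) * pi / arch$orientations
  stack <- list()
  i <- 0L
  for (lam in arch$wavelengths) {
    for (th in thetas) {
      i <- i + 1L
      k <- gaborKernel(th, lam, arch$kernelSize)
      pad <- matrix(0, h, w)
      pad[seq_len(nrow(k)), seq_len(ncol(k))] <- k
      stack[[i]] <- Mod(stats::fft(pad))^2
    }
  }
  .kernelCache[[key]] <- stack
  stack
}

meanPool <- function(g, f) {
  if (f <= 1L) return(g)
  h <- nrow(g) %/% f; w <- ncol(g) %/% f
  g <- g[seq_len(h * f), seq_len(w * f), drop = FALSE]
  # block means via row then column aggregation
  g <- matrix(colMeans(matrix(g, nrow = f)), nrow = h)
  t(matrix(colMeans(matrix(t(g), nrow = f)), nrow = w))
}

#' Featurize patches with the fixed convolutional front end
#'
#' Each RGB patch is reduced to grayscale, mean-pooled, and passed through
#' the Gabor bank; per-kernel RMS response energies (computed in the
#' frequency domain) are concatenated with global statistics (gray mean,
#' sd, 10/50/90% quantiles, per-channel means).
#'
#' @param patches list of RGB arrays (equal dimensions) or a
#'   [PatchSet-class].
#' @param arch architecture from [gaborArchitecture()].
#' @return Numeric matrix, one row per patch.
#' @export
featurizePatches <- function(patches, arch = gaborArchitecture()) {
  if (is(patches, "PatchSet")) patches <- patchImages(patches)
  if (!length(patches)) return(matrix(numeric(0), 0, 0))
  nK <- arch$orientations * length(arch$wavelengths)
  out <- matrix(0, length(patches), nK + 8L)
  for (i in seq_along(patches)) {
    img <- patches[[i]]
    gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3 / 255
    pooled <- meanPool(gray, arch$pool)
    h <- nrow(pooled); w <- ncol(pooled)
    stack <- kernelPowerStack(arch, h, w)
    G2 <- Mod(stats::fft(pooled - mean(pooled)))^2
    energies <- vapply(stack, function(K2) sqrt(sum(G2 * K2)) / (h * w),
                       numeric(1))
    stats8 <- c(mean(gray), sd(gray),
                quantile(gray, c(0.1, 0.5, 0.9), names = FALSE),
                mean(img[, , 1]) / 255, mean(img[, , 2]) / 255,
                mean(img[, , 3]) / 255)
    out[i, ] <- c(energies, stats8)
  }
  colnames(out) <- c(paste0("gabor_", seq_len(nK)),
                     "gray_mean", "gray_sd", "q10", "q50", "q90",
                     "r_mean", "g_mean", "b_mean")
  out
}
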