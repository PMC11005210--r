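#' @import methods
#' @importFrom stats rnorm runif quantile sd median optim plogis qlogis rbinom
#' @importFrom utils read.delim write.table head
NULL

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
withSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a per-stage seed from one global seed
#'
#' One pipeline-level seed fans out to independent per-stage seeds so that
#' stages are individually reproducible without seed collisions.  The
#' derivation hashes the stage name (FNV-1a style, folded to 31 bits) and
#' mixes it with the global seed.
#'
#' @param seed integer global seed.
#' @param stage character stage name, e.g. `"tile"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @examples
#' deriveStageSeed(1L, "tile")
#' @export
deriveStageSeed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  m <- 2147483647  # 2^31 - 1, prime
  h <- 2166136261 %% m
  for (b in utf8ToInt(stage)) {
    h <- ((h + b) * 16777619) %% m
  }
  as.integer((as.numeric(seed) %% m * 131 + h) %% m)
}

# ---- image helpers -------------------------------------------------------
# Images are plain numeric arrays H x W x 3 with 8-bit values in [0, 255].

assertImage <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("expected an RGB array (H x W x 3)")
  if (dim(image)[1] < 1L || dim(image)[2] < 1L)
    stop("empty image")
  invisible(image)
}

#' Pixel brightness of an RGB image
#'
#' Brightness is the arithmetic mean of the R, G and B channels rounded to
#' the nearest integer.  This is the project-wide definition used by the
#' background rule (background pixel: brightness strictly greater than 220
#' on the 0--255 scale).
#'
#' @param image numeric RGB array (H x W x 3, values 0--255).
#' @return Integer matrix (H x W) of brightness values.
#' @examples
#' img <- array(255, dim = c(2, 2, 3))
#' brightness(img)
#' @export
brightness <- function(image) {
  assertImage(image)
  round((image[, , 1] + image[, , 2] + image[, , 3]) / 3)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Read an RGB image from PNG or TIFF
#'
#' Returns the package's working representation: numeric array H x W x 3
#' with 8-bit values 0--255.  Grayscale inputs are replicated across
#' channels; an alpha channel is dropped.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return Numeric RGB array.
#' @export
readImageFile <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("package 'tiff' required for TIFF input")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: ", ext)
  )
  if (length(dim(raw)) == 2L) raw <- array(raw, dim = c(dim(raw), 1L))
  if (dim(raw)[3] == 1L) raw <- raw[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(raw)[3] >= 4L) raw <- raw[, , 1:3, drop = FALSE]
  round(raw * 255)
}

#' Write an RGB image as 8-bit PNG
#'
#' @param image numeric RGB array (values 0--255).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeImageFile <- function(image, path) {
  assertImage(image)
  png::writePNG(clamp(image, 0, 255) / 255, path)
  invisible(path)
}

# Full-precision numeric formatting so TSV round-trips are bit-exact.
formatNumeric <- function(x) {
  vapply(x, function(v) sprintf("%.17g", v), character(1))
}
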