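# Tiling: non-overlapping patch grids, background filtering, magnification.
#
# Conventions (fixed project-wide): 0-based grid indices, origin top-left,
# x = column pixel offset, y = row pixel offset, half-open pixel intervals.
# Right/bottom remainders that do not fill a whole patch are dropped.

#' Split a slide image into non-overlapping patches
#'
#' Tiles the image into a disjoint row-major grid of square patches of
#' `patchSize` pixels.  Partial tiles at the right/bottom edge are dropped,
#' so exactly `floor(H/size) * floor(W/size)` patches are returned.  Each
#' patch's background fraction (proportion of pixels with mean-channel
#' brightness strictly above `brightnessThreshold`) is recorded in the
#' manifest.
#'
#' @param image RGB array (H x W x 3, 0--255).
#' @param patchSize patch edge in pixels (>= 1).
#' @param slideId identifier stored in the manifest.
#' @param label optional slide grade (0--3) inherited by every patch.
#' @param brightnessThreshold background brightness cut (default 220).
#' @return A [PatchSet-class] object.  When `patchSize` exceeds either
#'   image dimension the set is empty (not an error).
#' @examples
#' img <- array(100, dim = c(448, 448, 3))
#' length(tileImage(img, 224))  # 4
#' @export
tileImage <- function(image, patchSize, slideId = "slide",
                      label = NA_integer_, brightnessThreshold = 220L) {
  assertImage(image)
  patchSize <- as.integer(patchSize)
  if (patchSize < 1L) stop("patchSize must be >= 1")
  H <- dim(image)[1]; W <- dim(image)[2]
  nr <- H %/% patchSize
  nc <- W %/% patchSize
  rows <- integer(0); cols <- integer(0)
  images <- vector("list", nr * nc)
  bf <- numeric(nr * nc)
  k <- 0L
  if (nr > 0L && nc > 0L) {
    for (r in seq_len(nr) - 1L) {       # row-major: row varies slowest
      for (cc in seq_len(nc) - 1L) {
        k <- k + 1L
        ys <- r * patchSize + seq_len(patchSize)
        xs <- cc * patchSize + seq_len(patchSize)
        patch <- image[ys, xs, , drop = FALSE]
        images[[k]] <- patch
        bf[k] <- backgroundFraction(patch, brightnessThreshold)
        rows[k] <- r; cols[k] <- cc
      }
    }
  }
  man <- data.frame(
    slide_id = rep(slideId, k),
    row = rows, col = cols,
    x0 = cols * patchSize, y0 = rows * patchSize,
    size = rep(patchSize, k),
    background_fraction = bf[seq_len(k)],
    label = rep(as.integer(label), k),
    stringsAsFactors = FALSE
  )
  new("PatchSet", slideId = slideId, patchSize = patchSize,
      slideDims = c(H, W), manifest = man, images = images[seq_len(k)])
}

#' Background fraction of a patch
#'
#' Fraction of pixels whose brightness (mean of R, G, B, rounded) is
#' strictly greater than the threshold.  Background pixels on
#' hematoxylin-eosin slides are the bright glass regions; the project rule
#' is brightness > 220 on the 0--255 scale.
#'
#' @param patchImage RGB array.
#' @param brightnessThreshold integer threshold, default 220.
#' @return Proportion in [0, 1].
#' @examples
#' backgroundFraction(array(255, dim = c(4, 4, 3)))  # 1
#' @export
backgroundFraction <- function(patchImage, brightnessThreshold = 220L) {
  b <- brightness(patchImage)   # errors on empty/non-RGB input
  mean(b > brightnessThreshold)
}

#' Keep foreground patches
#'
#' Retains exactly the patches whose background fraction is less than or
#' equal to `maxBackground` ("over 50% background excluded" — a patch at
#' exactly the threshold is retained).  Order is preserved.
#'
#' @param patches a [PatchSet-class].
#' @param maxBackground maximum tolerated background fraction (default 0.5).
#' @return A `PatchSet` containing the retained patches.
#' @export
filterForeground <- function(patches, maxBackground = 0.5) {
  stopifnot(is(patches, "PatchSet"))
  keep <- patches@manifest$background_fraction <= maxBackground
  new("PatchSet",
      slideId = patches@slideId,
      patchSize = patches@patchSize,
      slideDims = patches@slideDims,
      manifest = patches@manifest[keep, , drop = FALSE],
      images = patches@images[keep])
}

#' Emulate a lower magnification by area downsampling
#'
#' Factor 1 keeps the working magnification (20x); factor 2 emulates 10x by
#' averaging disjoint 2x2 pixel blocks.  Odd trailing rows/columns are
#' cropped so output dimensions are `floor(dim / factor)`.
#'
#' @param image RGB array.
#' @param factor 1 (identity) or 2 (downsample).
#' @return RGB array of the reduced size.
#' @export
rescaleMagnification <- function(image, factor) {
  assertImage(image)
  if (!factor %in% c(1L, 2L)) stop("factor must be 1 or 2")
  if (factor == 1L) return(image)
  H <- dim(image)[1] %/% 2L; W <- dim(image)[2] %/% 2L
  if (H < 1L || W < 1L) stop("image too small to downsample")
  out <- array(0, dim = c(H, W, 3L))
  for (ch in 1:3) {
    x <- image[seq_len(2L * H), seq_len(2L * W), ch]
    out[, , ch] <- (x[seq(1, 2 * H, 2), seq(1, 2 * W, 2)] +
                    x[seq(2, 2 * H, 2), seq(1, 2 * W, 2)] +
                    x[seq(1, 2 * H, 2), seq(2, 2 * W, 2)] +
                    x[seq(2, 2 * H, 2), seq(2, 2 * W, 2)]) / 4
  }
  out
}

#' Write / read a patch manifest TSV
#'
#' The manifest columns are `slide_id, row, col, x0, y0, size,
#' background_fraction, label`; `background_fraction` is written with full
#' precision so the round-trip is bit-exact.
#'
#' @param patches a [PatchSet-class] (or a bare manifest data.frame).
#' @param path output TSV path.
#' @return `path` invisibly; `readPatchManifest` returns the data.frame.
#' @export
writePatchManifest <- function(patches, path) {
  man <- if (is(patches, "PatchSet")) patches@manifest else patches
  out <- man
  out$background_fraction <- formatNumeric(man$background_fraction)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePatchManifest
#' @export
readPatchManifest <- function(path) {
  man <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(slide_id = "character"))
  man$background_fraction <- as.numeric(man$background_fraction)
  man
}
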