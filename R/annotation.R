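## Annotation: rectangular region tags, labeled-pixel sampling and the
## patch dataset built around labeled pixels (the Patches-GT strategy:
## sparse labeled pixels are expanded into patches centered on them, on the
## assumption that the immediate neighborhood shares the label).

#' Rectangular region tag
#'
#' @param imageId character id of the tagged frame.
#' @param rect \code{c(row0, col0, row1, col1)}, 1-based inclusive.
#' @param status one of bloated, semi_bloated, non_bloated.
#' @export
regionTag <- function(imageId, rect, status) {
  stopifnot(length(rect) == 4L, rect[1] <= rect[3], rect[2] <= rect[4],
            all(rect >= 1))
  if (!status %in% CORAL_LEVELS)
    stop("status must be one of ", paste(CORAL_LEVELS, collapse = ", "))
  structure(list(imageId = as.character(imageId), rect = as.integer(rect),
                 status = status), class = "RegionTag")
}

#' Sample labeled pixels from a tagged region
#'
#' Within the region, foreground pixels (mask == 1) are sampled uniformly
#' without replacement and labeled with the region's status; background
#' pixels (mask == 0) are sampled likewise and labeled background. The
#' defaults (120 foreground + 40 background per tagged section) match the
#' data-preparation scheme the patch classifier is trained on.
#'
#' @param region a [regionTag()].
#' @param mask binary foreground mask of the whole frame.
#' @param nFg,nBg pixels to draw from each class.
#' @param seed RNG seed (same seed, same pixels).
#' @return data.frame with columns image_id, row, col, label.
#' @export
sampleRegionPixels <- function(region, mask, nFg = 120L, nBg = 40L, seed = 1L) {
  stopifnot(inherits(region, "RegionTag"))
  r <- region$rect
  if (r[3] > nrow(mask) || r[4] > ncol(mask))
    stop("region lies outside the mask")
  sub <- mask[r[1]:r[3], r[2]:r[4], drop = FALSE]
  fg <- which(sub == 1L, arr.ind = TRUE)
  bg <- which(sub == 0L, arr.ind = TRUE)
  if (nrow(fg) < nFg)
    stop(sprintf("region needs %d foreground pixels but has only %d",
                 nFg, nrow(fg)))
  if (nrow(bg) < nBg)
    stop(sprintf("region needs %d background pixels but has only %d",
                 nBg, nrow(bg)))
  withSeed(seed, {
    fi <- fg[sample.int(nrow(fg), nFg), , drop = FALSE]
    bi <- bg[sample.int(nrow(bg), nBg), , drop = FALSE]
    data.frame(
      image_id = region$imageId,
      row = c(fi[, 1], bi[, 1]) + r[1] - 1L,
      col = c(fi[, 2], bi[, 2]) + r[2] - 1L,
      label = c(rep(region$status, nFg), rep("background", nBg)),
      stringsAsFactors = FALSE)
  })
}

#' Extract a square patch centered on a pixel
#'
#' For even sizes the center sits at offset size/2 (so a 30-pixel patch
#' spans rows \code{center - 15 .. center + 14}). Out-of-bounds area is
#' filled by reflect padding, so every labeled pixel yields a patch.
#'
#' @param img RGB array in 0..255.
#' @param center \code{c(row, col)}, 1-based.
#' @param size patch side (default 30).
#' @return \code{size x size x 3} array.
#' @export
extractPatch <- function(img, center, size = 30L) {
  d <- dim(img)
  if (size > min(d[1], d[2])) stop("patch size exceeds image size")
  off0 <- floor(size / 2); off1 <- size - off0 - 1L
  rows <- (center[1] - off0):(center[1] + off1)
  cols <- (center[2] - off0):(center[2] + off1)
  ri <- reflectIndex(rows, d[1])
  ci <- reflectIndex(cols, d[2])
  img[ri, ci, , drop = FALSE]
}

## Map possibly out-of-range 1-based indices to in-range ones by symmetric
## (edge-inclusive) reflection.
reflectIndex <- function(idx, n) {
  idx <- idx - 1L                    # 0-based
  m <- 2L * n
  idx <- ((idx %% m) + m) %% m
  idx <- ifelse(idx >= n, m - 1L - idx, idx)
  idx + 1L
}

#' Build the labeled patch dataset from pixel labels
#'
#' One patch per labeled pixel, in input order; the label is copied
#' unchanged.
#'
#' @param labels data.frame with image_id, row, col, label (as produced by
#'   [sampleRegionPixels()]).
#' @param images named list of RGB arrays keyed by image_id.
#' @param size patch side.
#' @return a [LabeledPatchSet-class].
#' @export
buildPatchDataset <- function(labels, images, size = 30L) {
  stopifnot(is.data.frame(labels),
            all(c("image_id", "row", "col", "label") %in% names(labels)))
  n <- nrow(labels)
  arr <- array(0, c(n, size, size, 3))
  for (i in seq_len(n)) {
    id <- labels$image_id[i]
    img <- images[[id]]
    if (is.null(img)) stop("no image with id '", id, "'")
    arr[i, , , ] <- extractPatch(img, c(labels$row[i], labels$col[i]), size)
  }
  new("LabeledPatchSet", patches = arr,
      labels = factor(labels$label, levels = STATUS_LEVELS),
      source = labels[c("image_id", "row", "col")])
}

#' Randomly augment patches
#'
#' On-the-fly horizontal/vertical flips and integer translations up to
#' \code{round(shiftFrac * size)} pixels (reflect fill); labels are
#' untouched. With flips off and shiftFrac 0 this is the identity.
#'
#' @param x a [LabeledPatchSet-class] or a bare N x s x s x 3 array.
#' @param flips enable random horizontal and vertical flips.
#' @param shiftFrac maximum shift as a fraction of the patch side, in
#'   \code{[0, 0.5)}.
#' @param seed RNG seed.
#' @return object of the same kind as \code{x} with augmented pixels.
#' @export
augmentPatches <- function(x, flips = TRUE, shiftFrac = 0.1, seed = 1L) {
  if (shiftFrac < 0 || shiftFrac >= 0.5) stop("shiftFrac must be in [0, 0.5)")
  arr <- if (is(x, "LabeledPatchSet")) patches(x) else x
  n <- dim(arr)[1]; s <- dim(arr)[2]
  maxShift <- round(shiftFrac * s)
  out <- withSeed(seed, {
    doH <- if (flips) runif(n) < 0.5 else rep(FALSE, n)
    doV <- if (flips) runif(n) < 0.5 else rep(FALSE, n)
    dr <- if (maxShift > 0) sample(-maxShift:maxShift, n, TRUE) else integer(n)
    dc <- if (maxShift > 0) sample(-maxShift:maxShift, n, TRUE) else integer(n)
    o <- arr
    for (i in seq_len(n)) {
      p <- array(arr[i, , , ], c(s, s, 3))
      if (doH[i]) p <- p[, s:1, , drop = FALSE]
      if (doV[i]) p <- p[s:1, , , drop = FALSE]
      if (dr[i] != 0L || dc[i] != 0L) {
        ri <- reflectIndex(seq_len(s) + dr[i], s)
        ci <- reflectIndex(seq_len(s) + dc[i], s)
        p <- p[ri, ci, , drop = FALSE]
      }
      o[i, , , ] <- p
    }
    o
  })
  if (is(x, "LabeledPatchSet"))
    new("LabeledPatchSet", patches = out, labels = patchLabels(x),
        source = patchSource(x))
  else out
}

#' Read and write annotation CSV files
#'
#' Pixel labels: \code{image_id,row,col,label}; region tags:
#' \code{image_id,row0,col0,row1,col1,status}.
#'
#' @param path CSV path.
#' @export
readPixelLabels <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("image_id", "row", "col", "label") %in% names(d)))
  d
}

#' @rdname readPixelLabels
#' @param labels pixel-label data.frame.
#' @export
writePixelLabels <- function(labels, path) {
  write.csv(labels, path, row.names = FALSE)
  invisible(path)
}

#' @rdname readPixelLabels
#' @export
readRegionTags <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("image_id", "row0", "col0", "row1", "col1", "status")
                %in% names(d)))
  lapply(seq_len(nrow(d)), function(i)
    regionTag(d$image_id[i], c(d$row0[i], d$col0[i], d$row1[i], d$col1[i]),
              d$status[i]))
}

#' @rdname readPixelLabels
#' @param tags list of [regionTag()] objects.
#' @export
writeRegionTags <- function(tags, path) {
  d <- do.call(rbind, lapply(tags, function(tg)
    data.frame(image_id = tg$imageId, row0 = tg$rect[1], col0 = tg$rect[2],
               row1 = tg$rect[3], col1 = tg$rect[4], status = tg$status,
               stringsAsFactors = FALSE)))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
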