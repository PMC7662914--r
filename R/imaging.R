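## Imaging: frame enhancement and HSV red-mask foreground segmentation.
## Images are plain numeric arrays height x width x 3, RGB in 0..255,
## 1-based (row, col) indexing at the API boundary regardless of file codec.

asImageArray <- function(img) {
  d <- dim(img)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    stop("image must be a height x width x 3 array")
  if (d[1] < 30 || d[2] < 30) stop("image must be at least 30 x 30")
  if (min(img) < 0 || max(img) > 255) stop("image values must lie in [0, 255]")
  img
}

#' Read / write RGB images
#'
#' PNG is read natively; JPEG/TIFF go through EBImage. Output is always an
#' RGB array in 0..255 with 1-based (row, col) indexing.
#'
#' @param path image file.
#' @export
readColorImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
  } else {
    im <- EBImage::readImage(path)
    a <- aperm(EBImage::imageData(EBImage::Image(im, colormode = "Color")),
               c(2, 1, 3))
  }
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] > 3L) a <- a[, , 1:3]
  a * 255
}

#' @rdname readColorImage
#' @param img RGB array in 0..255.
#' @export
writeColorImage <- function(img, path) {
  png::writePNG(clamp(img, 0, 255) / 255, path)
  invisible(path)
}

#' Contrast-limited adaptive histogram equalization on luminance
#'
#' Applies CLAHE to the L channel of CIELAB only, leaving a and b untouched,
#' so local contrast is amplified while the original hue is maintained — the
#' property that makes CLAHE suitable for dark underwater frames where color
#' is the segmentation signal.
#'
#' @param img RGB array, 0..255.
#' @param clipLimit contrast clip limit (> 0); default 2.
#' @param tileGrid integer pair, number of tiles along (rows, cols).
#' @return enhanced image, same shape and range.
#' @export
enhanceClahe <- function(img, clipLimit = 2, tileGrid = c(8L, 8L)) {
  img <- asImageArray(img)
  stopifnot(clipLimit > 0, length(tileGrid) == 2L, all(tileGrid >= 1))
  h <- dim(img)[1]; w <- dim(img)[2]
  if (h < tileGrid[1] * 2 || w < tileGrid[2] * 2)
    stop("image smaller than one CLAHE tile")
  px <- matrix(img, ncol = 3) / 255
  lab <- grDevices::convertColor(px, from = "sRGB", to = "Lab")
  L <- matrix(lab[, 1], h, w) / 100
  ## the tiled equalizer needs dims divisible by the tile counts: reflect-pad
  ## to the next multiple, equalize, crop back
  hp <- ceiling(h / tileGrid[1]) * tileGrid[1]
  wp <- ceiling(w / tileGrid[2]) * tileGrid[2]
  if (hp > h) L <- rbind(L, L[h:(2 * h - hp + 1), , drop = FALSE])
  if (wp > w) L <- cbind(L, L[, w:(2 * w - wp + 1), drop = FALSE])
  ## EBImage images are x (col) major; transpose in and out.
  Lt <- EBImage::Image(t(L))
  Leq <- t(EBImage::imageData(EBImage::clahe(Lt, nx = tileGrid[2],
                                             ny = tileGrid[1],
                                             limit = clipLimit)))
  Leq <- Leq[seq_len(h), seq_len(w), drop = FALSE]
  lab[, 1] <- clamp(as.numeric(Leq), 0, 1) * 100
  out <- grDevices::convertColor(lab, from = "Lab", to = "sRGB")
  array(clamp(out, 0, 1) * 255, dim(img))
}

#' Simple intensity enhancers for the comparison experiment
#'
#' Standard point/histogram transforms (gamma, log, sigmoid, global histogram
#' equalization, linear rescale), provided to reproduce the enhancement
#' comparison; CLAHE ([enhanceClahe()]) is the method the pipeline uses.
#'
#' @param img RGB array in 0..255.
#' @param method one of \code{"gamma"}, \code{"log"}, \code{"sigmoid"},
#'   \code{"hist_eq"}, \code{"rescale"}.
#' @param gamma exponent for \code{"gamma"}.
#' @param gain,cutoff parameters of the logistic curve for \code{"sigmoid"}.
#' @export
enhanceImage <- function(img, method, gamma = 1, gain = 10, cutoff = 0.5) {
  img <- asImageArray(img)
  u <- img / 255
  out <- switch(method,
    gamma = u^gamma,
    log = log1p(img) / log(256),
    sigmoid = 1 / (1 + exp(gain * (cutoff - u))),
    hist_eq = {
      v <- u
      for (ch in 1:3) {
        f <- ecdf(u[, , ch])
        v[, , ch] <- f(u[, , ch])
      }
      v
    },
    rescale = {
      rng <- range(img)
      if (diff(rng) == 0) u else (img - rng[1]) / diff(rng)
    },
    stop("unknown enhancement method: ", method))
  array(clamp(out, 0, 1) * 255, dim(img))
}

#' HSV mask configuration
#'
#' Hue is in degrees [0, 360); bands may wrap (lo > hi means the band crosses
#' 0). Saturation and value are in [0, 1]. The defaults select the red hues
#' of a coral foreground against a dark, desaturated background.
#'
#' @param hueBands list of \code{c(lo, hi)} degree pairs.
#' @param satRange,valRange \code{c(lo, hi)} in [0, 1].
#' @export
hsvMaskConfig <- function(hueBands = list(c(0, 15), c(345, 360)),
                          satRange = c(0.35, 1), valRange = c(0.12, 1)) {
  bands <- lapply(hueBands, function(b) {
    stopifnot(length(b) == 2L, all(b >= 0), all(b <= 360))
    b
  })
  stopifnot(length(satRange) == 2L, satRange[1] <= satRange[2],
            length(valRange) == 2L, valRange[1] <= valRange[2])
  structure(list(hueBands = bands, satRange = satRange, valRange = valRange),
            class = "HsvMaskConfig")
}

#' Red-mask foreground segmentation in HSV space
#'
#' A pixel is foreground iff its hue falls in any configured band AND its
#' saturation and value fall in the configured ranges — the bitwise
#' comparison between the image and the color mask that extracts coral
#' pixels cheaply.
#'
#' @param img RGB array in 0..255.
#' @param cfg an [hsvMaskConfig()].
#' @return integer matrix of 0/1, same height x width as the image.
#' @export
hsvRedMask <- function(img, cfg = hsvMaskConfig()) {
  img <- asImageArray(img)
  stopifnot(inherits(cfg, "HsvMaskConfig"))
  h <- dim(img)[1]; w <- dim(img)[2]
  rgb <- rbind(as.numeric(img[, , 1]), as.numeric(img[, , 2]),
               as.numeric(img[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  hue <- hsv[1, ] * 360; s <- hsv[2, ]; v <- hsv[3, ]
  inHue <- rep(FALSE, length(hue))
  for (b in cfg$hueBands) {
    if (b[1] <= b[2]) inHue <- inHue | (hue >= b[1] & hue <= b[2])
    else inHue <- inHue | (hue >= b[1] | hue <= b[2]) # wrap-around band
  }
  ok <- inHue & s >= cfg$satRange[1] & s <= cfg$satRange[2] &
    v >= cfg$valRange[1] & v <= cfg$valRange[2]
  matrix(as.integer(ok), h, w)
}

#' Median filtering of a binary mask
#'
#' Each pixel is replaced by the median of its kernel x kernel neighborhood
#' (reflect padding at the edges). For a 0/1 mask this removes isolated
#' specks while preserving region boundaries.
#'
#' @param mask integer 0/1 matrix.
#' @param kernel odd kernel side, >= 3.
#' @export
medianFilterMask <- function(mask, kernel = 3L) {
  if (kernel %% 2 == 0 || kernel < 3) stop("kernel must be odd and >= 3")
  if (!all(mask %in% c(0L, 1L))) stop("mask must be binary 0/1")
  r <- (kernel - 1L) %/% 2L
  p <- reflectPad(mask, r)
  nr <- nrow(mask); nc <- ncol(mask)
  s <- matrix(0L, nr, nc)
  for (dr in 0:(kernel - 1L)) for (dc in 0:(kernel - 1L))
    s <- s + p[dr + seq_len(nr), dc + seq_len(nc)]
  matrix(as.integer(s > (kernel * kernel) / 2), nr, nc)
}
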