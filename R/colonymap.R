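## Colony mapping: sliding-window classification of whole frames, coverage
## percentages, chlorophyll calibration and compilation of the behavioral +
## oceanographic time series.

#' Sliding-window anchor positions
#'
#' Row/column anchors (1-based, top-left corners) of \code{window}-sized
#' crops stepped by \code{step}; the grid has
#' \code{floor((H - window)/step) + 1} rows and likewise for columns.
#'
#' @param height,width frame size in pixels.
#' @param window window side.
#' @param step stride.
#' @export
windowGrid <- function(height, width, window = 30L, step = 10L) {
  if (step <= 0) stop("step must be positive")
  if (height < window || width < window)
    stop("frame smaller than one window")
  list(rows = seq(1L, height - window + 1L, by = step),
       cols = seq(1L, width - window + 1L, by = step))
}

#' Segment a frame into a StatusMap
#'
#' Every window position is classified by the patch model; overlapping
#' windows are combined per grid cell by averaging the softmax vectors of
#' all windows that cover the cell's center pixel, then taking the argmax
#' (ties broken toward the higher-priority class, background < semi <
#' non-bloated < bloated). With \code{step == window} this reduces to
#' independent per-window classification.
#'
#' @param img RGB array in 0..255.
#' @param model a trained [PatchCnn-class].
#' @param window window side (default 30).
#' @param step stride (default 10).
#' @param chunk windows per prediction chunk.
#' @return a [StatusMap-class].
#' @export
segmentFrame <- function(img, model, window = 30L, step = 10L,
                         chunk = 2048L) {
  img <- asImageArray(img)
  g <- windowGrid(dim(img)[1], dim(img)[2], window, step)
  nr <- length(g$rows); nc <- length(g$cols)
  npos <- nr * nc
  probs <- matrix(0, npos, model@spec$nClasses)
  ## windows in grid column-major order: cell (i, j) -> index i + (j-1)*nr
  buf <- array(0, c(min(chunk, npos), window, window, 3))
  pos <- 1L
  while (pos <= npos) {
    m <- min(chunk, npos - pos + 1L)
    for (q in seq_len(m)) {
      lin <- pos + q - 2L
      i <- lin %% nr + 1L
      j <- lin %/% nr + 1L
      r0 <- g$rows[i]; c0 <- g$cols[j]
      buf[q, , , ] <- img[r0:(r0 + window - 1L), c0:(c0 + window - 1L), ]
    }
    probs[pos:(pos + m - 1L), ] <-
      predictPatchCnn(model, buf[seq_len(m), , , , drop = FALSE])
    pos <- pos + m
  }
  ## neighbor offsets whose windows cover a cell's center pixel
  ctr <- window %/% 2L
  dmax <- 0L
  while ((dmax + 1L) * step <= ctr &&
         ctr + (dmax + 1L) * step <= window - 1L) dmax <- dmax + 1L
  offs <- -dmax:dmax
  acc <- array(0, c(nr, nc, model@spec$nClasses))
  cnt <- matrix(0, nr, nc)
  parr <- array(probs, c(nr, nc, model@spec$nClasses))
  for (di in offs) for (dj in offs) {
    ri <- seq_len(nr) + di; ci <- seq_len(nc) + dj
    vr <- ri >= 1 & ri <= nr; vc <- ci >= 1 & ci <= nc
    acc[vr, vc, ] <- acc[vr, vc, , drop = FALSE] +
      parr[ri[vr], ci[vc], , drop = FALSE]
    cnt[vr, vc] <- cnt[vr, vc] + 1
  }
  for (k in seq_len(dim(acc)[3])) acc[, , k] <- acc[, , k] / cnt
  ## argmax with priority tie-break: background < semi < non < bloated
  prio <- match(c("background", "semi_bloated", "non_bloated", "bloated"),
                model@classLevels)
  flat <- matrix(acc, nr * nc, dim(acc)[3])
  best <- max.col(flat[, prio, drop = FALSE], ties.method = "last")
  codes <- statusCode(model@classLevels[prio[best]])
  new("StatusMap", grid = matrix(as.integer(codes), nr, nc),
      window = as.integer(window), step = as.integer(step),
      aggregation = "softmax-mean over covering windows")
}

#' Coverage percentages of the three activity statuses
#'
#' Percentages are taken over coral cells only (background excluded) and sum
#' to 100 when any coral is present; an all-background map yields (0, 0, 0)
#' with the \code{empty} flag set.
#'
#' @param map a [StatusMap-class].
#' @return named list: bloated_pct, semi_bloated_pct, non_bloated_pct,
#'   empty.
#' @export
statusPercentages <- function(map) {
  g <- statusGrid(map)
  if (!length(g)) stop("empty map")
  nb <- sum(g == 1L); ns <- sum(g == 2L); nn <- sum(g == 3L)
  tot <- nb + ns + nn
  if (tot == 0)
    return(list(bloated_pct = 0, semi_bloated_pct = 0, non_bloated_pct = 0,
                empty = TRUE))
  list(bloated_pct = 100 * nb / tot, semi_bloated_pct = 100 * ns / tot,
       non_bloated_pct = 100 * nn / tot, empty = FALSE)
}

#' Chlorophyll calibration from fluorescence
#'
#' Affine conversion of raw fluorescence to chlorophyll-a with separate day
#' and night coefficients: day \code{1.050 * fl + 1.0129}, night
#' \code{0.963 * fl + 0.2159}. The day window defaults to dawn 06:00 --
#' dusk 21:30 (intermediate astronomical timings of the monitored period).
#'
#' @param daySlope,dayIntercept,nightSlope,nightIntercept coefficients.
#' @param dawn,dusk day-window boundaries as decimal clock hours.
#' @export
chlCalibration <- function(daySlope = 1.050, dayIntercept = 1.0129,
                           nightSlope = 0.963, nightIntercept = 0.2159,
                           dawn = 6, dusk = 21.5) {
  stopifnot(daySlope > 0, nightSlope > 0)
  list(daySlope = daySlope, dayIntercept = dayIntercept,
       nightSlope = nightSlope, nightIntercept = nightIntercept,
       dawn = dawn, dusk = dusk)
}

#' @rdname chlCalibration
#' @param fl fluorescence reading (>= 0); vectorized.
#' @param t POSIXct timestamp(s) deciding day vs night.
#' @param cal a [chlCalibration()].
#' @export
calibrateChlorophyll <- function(fl, t, cal = chlCalibration()) {
  if (any(fl < 0, na.rm = TRUE)) stop("fluorescence must be >= 0")
  lt <- as.POSIXlt(t)
  hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  day <- hour >= cal$dawn & hour < cal$dusk
  ifelse(day, cal$daySlope * fl + cal$dayIntercept,
         cal$nightSlope * fl + cal$nightIntercept)
}

#' Compile the behavioral + oceanographic series
#'
#' One row per frame; oceanographic values are joined by nearest timestamp
#' within \code{toleranceMin} minutes (no interpolation: gaps stay missing).
#'
#' @param frames list of \code{list(timestamp = POSIXct, map = StatusMap)}
#'   entries (or precomputed \code{pct} lists from [statusPercentages()]).
#' @param ocean data.frame with a POSIXct \code{timestamp} column and the
#'   oceanographic columns.
#' @param toleranceMin maximum timestamp distance for a join, in minutes.
#' @param calibration optional [chlCalibration()]; when given, a
#'   \code{chl_a} column is added from \code{chl_fluorescence}.
#' @return an [ActivitySeries-class].
#' @export
compileSeries <- function(frames, ocean = NULL, toleranceMin = 30,
                          calibration = NULL) {
  ts <- as.POSIXct(vapply(frames, function(f) as.numeric(f$timestamp),
                          numeric(1)), origin = "1970-01-01", tz = "UTC")
  if (anyDuplicated(ts)) stop("duplicate frame timestamps")
  o <- order(ts)
  rows <- lapply(frames[o], function(f) {
    p <- if (!is.null(f$map)) statusPercentages(f$map) else f$pct
    data.frame(bloated_pct = p$bloated_pct,
               semi_bloated_pct = p$semi_bloated_pct,
               non_bloated_pct = p$non_bloated_pct,
               empty_frame = isTRUE(p$empty))
  })
  d <- cbind(data.frame(timestamp = ts[o]), do.call(rbind, rows))
  oceanCols <- c("temperature_C", "salinity_PSU", "turbidity_NTU",
                 "chl_fluorescence", "depth_m")
  for (cc in oceanCols) d[[cc]] <- NA_real_
  if (!is.null(ocean) && nrow(ocean)) {
    stopifnot("timestamp" %in% names(ocean))
    ot <- as.numeric(ocean$timestamp)
    for (i in seq_len(nrow(d))) {
      dt <- abs(ot - as.numeric(d$timestamp[i]))
      j <- which.min(dt)
      if (dt[j] <= toleranceMin * 60) {
        for (cc in intersect(oceanCols, names(ocean)))
          d[i, cc] <- ocean[j, cc]
      }
    }
  }
  if (!is.null(calibration))
    d$chl_a <- calibrateChlorophyll(d$chl_fluorescence, d$timestamp,
                                    calibration)
  new("ActivitySeries", data = d)
}

#' Reduce a pixel-level ground-truth map to the sliding-window grid
#'
#' The truth class of a grid cell is the label of its window's center pixel,
#' matching how a classified window is anchored.
#'
#' @param truth a pixel-resolution [StatusMap-class] (window = step = 1).
#' @param window,step the segmentation geometry to mirror.
#' @export
truthToGrid <- function(truth, window = 30L, step = 10L) {
  g <- statusGrid(truth)
  wg <- windowGrid(nrow(g), ncol(g), window, step)
  ctr <- window %/% 2L
  grid <- g[wg$rows + ctr, wg$cols + ctr, drop = FALSE]
  new("StatusMap", grid = grid, window = as.integer(window),
      step = as.integer(step), aggregation = "ground-truth center pixel")
}
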