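## Synthetic fixtures: ground-truthed coral-like scenes and rhythmic
## multiparametric series. Every downstream stage of the pipeline is testable
## against these with no external data.

#' Describe a synthetic colony scene
#'
#' A scene is a dark, low-red background with rectangular coral regions, each
#' in one of the three activity statuses. Textures are designed so that the
#' statuses are separable by a local patch classifier the way enlarged views
#' of a real colony are to a trained eye: bloated regions are bright red with
#' speckled polyp-like dots, non-bloated regions are darker, smoother red,
#' and semi-bloated regions are a checkerboard mix of the two.
#'
#' @param width,height frame size in pixels (>= 30 each).
#' @param regions list; each element \code{list(rect = c(row0, col0, row1,
#'   col1), status = "bloated")} with 1-based inclusive bounds and status one
#'   of bloated, semi_bloated, non_bloated.
#' @param backgroundColor RGB triple (0-255) of the background.
#' @param seed integer; the single RNG stream used for all texture noise.
#' @return a \code{SceneSpec} (plain list, validated).
#' @export
sceneSpec <- function(width, height, regions,
                      backgroundColor = c(30, 32, 36), seed = 1L) {
  stopifnot(width >= 30, height >= 30, length(backgroundColor) == 3)
  for (rg in regions) {
    r <- rg$rect
    if (length(r) != 4L || r[1] < 1 || r[2] < 1 || r[3] > height || r[4] > width)
      stop("region rect must lie inside the frame")
    if (r[1] > r[3] || r[2] > r[4]) stop("degenerate rect")
    if (!rg$status %in% CORAL_LEVELS)
      stop("status must be one of ", paste(CORAL_LEVELS, collapse = ", "))
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 regions = regions, backgroundColor = backgroundColor,
                 seed = as.integer(seed)),
            class = "SceneSpec")
}

## Approximate Poisson-disk sampling on a rect via dart throwing with an
## occupancy grid; deterministic under the active RNG stream.
poissonDisk <- function(nr, nc, minDist) {
  cell <- max(1, floor(minDist / sqrt(2)))
  gr <- matrix(FALSE, ceiling(nr / cell), ceiling(nc / cell))
  pts <- matrix(0, 0, 2)
  nTry <- ceiling(4 * nr * nc / minDist^2)
  cand <- cbind(runif(nTry, 1, nr), runif(nTry, 1, nc))
  for (i in seq_len(nTry)) {
    gi <- ceiling(cand[i, 1] / cell); gj <- ceiling(cand[i, 2] / cell)
    if (gr[gi, gj]) next
    ok <- TRUE
    if (nrow(pts)) {
      d2 <- (pts[, 1] - cand[i, 1])^2 + (pts[, 2] - cand[i, 2])^2
      ok <- min(d2) >= minDist^2
    }
    if (ok) { gr[gi, gj] <- TRUE; pts <- rbind(pts, cand[i, ]) }
  }
  round(pts)
}

## 3x3 mean filter with reflect padding, applied to a single channel matrix.
meanFilter3 <- function(m) {
  p <- reflectPad(m, 1L)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (dr in 0:2) for (dc in 0:2)
    out <- out + p[dr + seq_len(nr), dc + seq_len(nc)]
  out / 9
}

## Texture painters return an nr x nc x 3 array for one region.
textureBloated <- function(nr, nc) {
  base <- c(150, 45, 40)
  tex <- array(rep(base, each = nr * nc), c(nr, nc, 3)) +
    array(rnorm(nr * nc * 3, 0, 8), c(nr, nc, 3))
  dots <- poissonDisk(nr, nc, minDist = 6)
  bright <- c(235, 135, 110)
  for (k in seq_len(nrow(dots))) {
    r0 <- max(1, dots[k, 1] - 1); r1 <- min(nr, dots[k, 1] + 1)
    c0 <- max(1, dots[k, 2] - 1); c1 <- min(nc, dots[k, 2] + 1)
    for (ch in 1:3) tex[r0:r1, c0:c1, ch] <- bright[ch]
  }
  tex
}

textureNonBloated <- function(nr, nc) {
  base <- c(150, 45, 40) * 0.6
  tex <- array(rep(base, each = nr * nc), c(nr, nc, 3)) +
    array(rnorm(nr * nc * 3, 0, 6), c(nr, nc, 3))
  for (ch in 1:3) tex[, , ch] <- meanFilter3(meanFilter3(tex[, , ch]))
  tex
}

textureSemiBloated <- function(nr, nc, tile = 10L) {
  a <- textureBloated(nr, nc)
  b <- textureNonBloated(nr, nc)
  ri <- ((seq_len(nr) - 1L) %/% tile) %% 2L
  ci <- ((seq_len(nc) - 1L) %/% tile) %% 2L
  mix <- outer(ri, ci, function(x, y) (x + y) %% 2L) == 1L
  for (ch in 1:3) { m <- a[, , ch]; m[mix] <- b[, , ch][mix]; a[, , ch] <- m }
  a
}

#' Generate a colony scene and its pixel-level ground truth
#'
#' @param spec a [sceneSpec()].
#' @return list with \code{image} (height x width x 3 numeric array, 0-255)
#'   and \code{truth} (a [StatusMap-class] at pixel resolution, window = step
#'   = 1).
#' @details Overlapping rectangles with conflicting statuses are an error;
#'   identical seeds give byte-identical output.
#' @export
generateColonyImage <- function(spec) {
  stopifnot(inherits(spec, "SceneSpec"))
  h <- spec$height; w <- spec$width
  ## conflict check before any RNG is consumed
  truth <- matrix(0L, h, w)
  for (rg in spec$regions) {
    r <- rg$rect; code <- statusCode(rg$status)
    block <- truth[r[1]:r[3], r[2]:r[4]]
    if (any(block != 0L & block != code))
      stop("overlapping regions with conflicting statuses")
    truth[r[1]:r[3], r[2]:r[4]] <- code
  }
  img <- withSeed(spec$seed, {
    img <- array(0, c(h, w, 3))
    for (ch in 1:3)
      img[, , ch] <- spec$backgroundColor[ch] + matrix(rnorm(h * w, 0, 3), h, w)
    for (rg in spec$regions) {
      r <- rg$rect
      nr <- r[3] - r[1] + 1L; nc <- r[4] - r[2] + 1L
      tex <- switch(rg$status,
        bloated = textureBloated(nr, nc),
        semi_bloated = textureSemiBloated(nr, nc),
        non_bloated = textureNonBloated(nr, nc))
      img[r[1]:r[3], r[2]:r[4], ] <- tex
    }
    img
  })
  img <- clamp(img, 0, 255)
  list(image = img,
       truth = new("StatusMap", grid = truth, window = 1L, step = 1L,
                   aggregation = "ground-truth"))
}

#' Describe a synthetic behavioral/oceanographic series
#'
#' The bloated coverage follows \code{mean + A cos(2 pi (t - peak)/period)}
#' plus Gaussian noise, clipped to \code{[0, 100]}; the remainder is split
#' between non-bloated (55\%) and semi-bloated (45\%), mirroring the observed
#' antiphase with a minor, transient semi-bloated state. Depth carries a
#' tidal sinusoid; other oceanographic columns are weakly structured noise.
#'
#' @param start POSIXct start time (hourly sampling).
#' @param nHours number of hourly rows; use >= 48 for any periodogram work.
#' @param rhythmPeriodMin behavioral period in minutes (default 1440, the
#'   day-night cycle).
#' @param rhythmPeakHour clock hour of the bloated peak (default 21.5, dusk).
#' @param rhythmAmplitude cosine amplitude in percentage points.
#' @param meanPct mean bloated coverage; \code{meanPct +/- rhythmAmplitude}
#'   must stay inside [0, 100].
#' @param noiseSd Gaussian noise sd in percentage points.
#' @param depthPeriodMin tidal period for the depth sinusoid (default 745
#'   min, the principal lunar semidiurnal constituent).
#' @param gapWindows list of POSIXct pairs; oceanographic values inside these
#'   windows are set to NA (sensor gaps).
#' @param seed RNG seed.
#' @export
seriesSpec <- function(start = as.POSIXct("2018-02-23 11:30:00", tz = "UTC"),
                       nHours = 720L, rhythmPeriodMin = 1440,
                       rhythmPeakHour = 21.5, rhythmAmplitude = 25,
                       meanPct = 50, noiseSd = 5, depthPeriodMin = 745,
                       gapWindows = list(), seed = 1L) {
  if (rhythmPeriodMin <= 0) stop("rhythmPeriodMin must be positive")
  if (meanPct + rhythmAmplitude > 100 || meanPct - rhythmAmplitude < 0)
    stop("meanPct +/- rhythmAmplitude must stay inside [0, 100]")
  stopifnot(nHours >= 1)
  structure(list(start = start, nHours = as.integer(nHours),
                 rhythmPeriodMin = rhythmPeriodMin,
                 rhythmPeakHour = rhythmPeakHour,
                 rhythmAmplitude = rhythmAmplitude, meanPct = meanPct,
                 noiseSd = noiseSd, depthPeriodMin = depthPeriodMin,
                 gapWindows = gapWindows, seed = as.integer(seed)),
            class = "SeriesSpec")
}

#' Generate a rhythmic activity series with aligned oceanographic columns
#'
#' @param spec a [seriesSpec()].
#' @return an [ActivitySeries-class].
#' @export
generateActivitySeries <- function(spec) {
  stopifnot(inherits(spec, "SeriesSpec"))
  ts <- spec$start + 3600 * (seq_len(spec$nHours) - 1L)
  tmin <- as.numeric(ts) / 60
  day0 <- as.POSIXct(format(spec$start, "%Y-%m-%d 00:00:00"),
                     tz = attr(spec$start, "tzone") %||% "UTC")
  peakMin <- as.numeric(day0) / 60 + spec$rhythmPeakHour * 60
  withSeed(spec$seed, {
    bl <- spec$meanPct + spec$rhythmAmplitude *
      cos(2 * pi * (tmin - peakMin) / spec$rhythmPeriodMin) +
      rnorm(length(ts), 0, spec$noiseSd)
    bl <- clamp(bl, 0, 100)
    non <- (100 - bl) * 0.55
    semi <- 100 - bl - non
    hourFrac <- (tmin %% 1440) / 1440
    temperature <- 6.5 + 0.15 * sin(2 * pi * hourFrac) + rnorm(length(ts), 0, 0.08)
    salinity <- 34.74 + rnorm(length(ts), 0, 0.05)
    turbidity <- exp(rnorm(length(ts), log(6.5), 0.25))
    chl <- pmax(0, 5 + 2 * sin(2 * pi * (hourFrac - 0.25)) +
                  rnorm(length(ts), 0, 0.5))
    depth <- 250.10 + 1.1 * sin(2 * pi * tmin / spec$depthPeriodMin)
    d <- data.frame(timestamp = ts, bloated_pct = bl, semi_bloated_pct = semi,
                    non_bloated_pct = non, temperature_C = temperature,
                    salinity_PSU = salinity, turbidity_NTU = turbidity,
                    chl_fluorescence = chl, depth_m = depth)
    for (gw in spec$gapWindows) {
      sel <- ts >= gw[1] & ts <= gw[2]
      d[sel, c("temperature_C", "salinity_PSU", "turbidity_NTU",
               "chl_fluorescence", "depth_m")] <- NA
    }
    new("ActivitySeries", data = d)
  })
}

#' Write / read scene fixtures and series CSVs
#'
#' \code{writeSceneFixture} saves the frame as PNG, the ground truth as a
#' single-channel label PNG (codes 0-3) plus a JSON legend;
#' \code{writeActivitySeriesCsv}/\code{readActivitySeriesCsv} round-trip the
#' series with ISO-8601 timestamps.
#'
#' @param scene result of [generateColonyImage()].
#' @param dir output directory (created if needed).
#' @param name basename for the files.
#' @return invisibly, the paths written.
#' @export
writeSceneFixture <- function(scene, dir, name = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  imgPath <- file.path(dir, paste0(name, ".png"))
  truthPath <- file.path(dir, paste0(name, "_truth.png"))
  legendPath <- file.path(dir, paste0(name, "_legend.json"))
  png::writePNG(scene$image / 255, imgPath)
  png::writePNG(statusGrid(scene$truth) / 255, truthPath)
  jsonlite::write_json(
    list(legend = as.list(setNames(0:3, STATUS_LEVELS)),
         encoding = "label PNG stores code/255"),
    legendPath, auto_unbox = TRUE)
  invisible(c(imgPath, truthPath, legendPath))
}

#' @rdname writeSceneFixture
#' @param series an [ActivitySeries-class].
#' @param path CSV path.
#' @export
writeActivitySeriesCsv <- function(series, path) {
  d <- seriesData(series)
  d$timestamp <- format(d$timestamp, "%Y-%m-%dT%H:%M:%S")
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSceneFixture
#' @export
readActivitySeriesCsv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  d$timestamp <- as.POSIXct(d$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  new("ActivitySeries", data = d)
}
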