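## Chronobiology statistics: Lomb-Scargle periodogram over a period band
## (floating-mean least-squares formulation, power as % variance explained,
## Baluev-style family-wise false-alarm significance), 24-h waveform
## analysis with MESOR and phase, and monthly aggregation.

asMinutes <- function(t) {
  if (inherits(t, "POSIXct")) as.numeric(t) / 60 else as.numeric(t)
}

## Single-frequency tail probability for the variance-fraction statistic z
## under Gaussian noise (floating-mean normalization): z ~ Beta(1, (n-3)/2).
lsSingleP <- function(z, n) (1 - pmin(z, 1))^((n - 3) / 2)

## Baluev family-wise false-alarm probability over the scanned band:
## 1 - (1 - p_single) * exp(-tau), with tau the Davies bound on the expected
## number of threshold upcrossings. W uses the effective bandwidth of the
## scan and the rms spread of the sampling times.
lsFapBaluev <- function(z, n, tmin, fLo, fHi) {
  teff <- sqrt(4 * pi * mean((tmin - mean(tmin))^2))
  W <- (fHi - fLo) * teff
  tau <- W * (1 - z)^((n - 4) / 2) * sqrt((n - 1) * z / 2)
  1 - (1 - lsSingleP(z, n)) * exp(-tau)
}

## Power threshold (variance fraction) whose Baluev FAP equals alpha.
lsThreshold <- function(alpha, n, tmin, fLo, fHi) {
  f <- function(z) lsFapBaluev(z, n, tmin, fLo, fHi) - alpha
  stats::uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
}

#' Lomb-Scargle periodogram over a period band
#'
#' Scans an evenly spaced period grid (default 600-1620 min at 1-min
#' resolution, covering semidiurnal tidal through day-night periods) with
#' the floating-mean least-squares periodogram, which handles irregular
#' sampling and gaps natively. Power is expressed as the percentage of total
#' variance explained by the sinusoid at each period. Significance uses the
#' family-wise false-alarm probability with the number of independent
#' frequencies estimated from the scanned band and the series span.
#'
#' @param time POSIXct timestamps or numeric minutes.
#' @param values series values; NA rows are dropped.
#' @param periodRange \code{c(lo, hi)} in minutes.
#' @param gridStepMin period grid resolution in minutes.
#' @param alpha family-wise false-alarm level for the threshold.
#' @return a [PeriodogramResult-class].
#' @export
lombScargle <- function(time, values, periodRange = c(600, 1620),
                        gridStepMin = 1, alpha = 0.05) {
  tmin <- asMinutes(time)
  ok <- is.finite(tmin) & is.finite(values)
  tmin <- tmin[ok]; y <- values[ok]
  n <- length(y)
  if (n < 48) stop("need at least 48 finite samples, got ", n)
  if (any(diff(tmin) <= 0)) stop("times must be strictly increasing")
  period <- seq(periodRange[1], periodRange[2], by = gridStepMin)
  f <- 1 / period
  yc <- y - mean(y)
  yy <- sum(yc^2)
  if (yy == 0) {
    return(new("PeriodogramResult", period = period,
               power = rep(0, length(period)), threshold = NA_real_,
               alpha = alpha,
               peaks = data.frame(period = numeric(0), power = numeric(0),
                                  p = numeric(0)),
               n = as.integer(n), constant = TRUE))
  }
  w <- outer(tmin, 2 * pi * f)          # n x nf phase matrix
  cw <- cos(w); sw <- sin(w)
  cm <- colMeans(cw); sm <- colMeans(sw)
  cw <- sweep(cw, 2, cm); sw <- sweep(sw, 2, sm)
  yC <- drop(crossprod(yc, cw)); yS <- drop(crossprod(yc, sw))
  CC <- colSums(cw^2); SS <- colSums(sw^2); CS <- colSums(cw * sw)
  D <- CC * SS - CS^2
  z <- (SS * yC^2 - 2 * CS * yC * yS + CC * yS^2) / (D * yy)
  z <- clamp(z, 0, 1)
  power <- 100 * z
  fap <- lsFapBaluev(z, n, tmin, min(f), max(f))
  zstar <- lsThreshold(alpha, n, tmin, min(f), max(f))
  threshold <- 100 * zstar
  ## significant local maxima of the power curve
  isMax <- power >= c(-Inf, head(power, -1)) &
    power >= c(power[-1], -Inf)
  sig <- which(isMax & power > threshold)
  peaks <- data.frame(period = period[sig], power = power[sig], p = fap[sig])
  peaks <- peaks[order(-peaks$power), , drop = FALSE]
  rownames(peaks) <- NULL
  new("PeriodogramResult", period = period, power = power,
      threshold = threshold, alpha = alpha, peaks = peaks,
      n = as.integer(n), constant = FALSE)
}

#' Monte-Carlo false-alarm calibration of the periodogram threshold
#'
#' Simulates Gaussian white noise on a fixed sampling grid and reports the
#' fraction of simulations in which any scanned period exceeds the alpha
#' threshold. Vectorized across simulations so that large calibration runs
#' stay cheap.
#'
#' @param time timestamps of the sampling grid (POSIXct or minutes).
#' @param nsim number of noise simulations.
#' @inheritParams lombScargle
#' @param seed RNG seed.
#' @return list with \code{rate} (observed family-wise false-alarm
#'   fraction), \code{alpha} and \code{nsim}.
#' @export
lombScargleNull <- function(time, nsim = 1000L, periodRange = c(600, 1620),
                            gridStepMin = 1, alpha = 0.05, seed = 1L) {
  tmin <- asMinutes(time)
  stopifnot(length(tmin) >= 48, all(diff(tmin) > 0))
  n <- length(tmin)
  period <- seq(periodRange[1], periodRange[2], by = gridStepMin)
  f <- 1 / period
  w <- outer(tmin, 2 * pi * f)
  cw <- cos(w); sw <- sin(w)
  cw <- sweep(cw, 2, colMeans(cw)); sw <- sweep(sw, 2, colMeans(sw))
  CC <- colSums(cw^2); SS <- colSums(sw^2); CS <- colSums(cw * sw)
  D <- CC * SS - CS^2
  Y <- withSeed(seed, matrix(rnorm(n * nsim), n, nsim))
  Y <- sweep(Y, 2, colMeans(Y))
  yy <- colSums(Y^2)
  yC <- crossprod(cw, Y)                # nf x nsim
  yS <- crossprod(sw, Y)
  z <- (SS * yC^2 - 2 * CS * yC * yS + CC * yS^2) / D
  zmax <- apply(z, 2, max) / yy
  zstar <- lsThreshold(alpha, n, tmin, min(f), max(f))
  list(rate = mean(zmax > zstar), alpha = alpha, nsim = nsim)
}

#' 24-h waveform analysis
#'
#' Folds the series into 24-h segments and averages values at corresponding
#' clock bins across all days; the MESOR is the re-average of the bin means
#' and the phase is the set of bins strictly above it (a constant series
#' therefore has an empty phase).
#'
#' @param time POSIXct timestamps (must carry clock time).
#' @param values series values; NA dropped.
#' @param binMinutes bin width (default 60).
#' @param offsetMin clock offset of the first bin boundary in minutes (use
#'   30 to anchor bins at half-hours when sampling falls on HH:30).
#' @return a [WaveformResult-class].
#' @export
waveformAnalysis <- function(time, values, binMinutes = 60, offsetMin = 0) {
  stopifnot(inherits(time, "POSIXct"))
  ok <- is.finite(values)
  time <- time[ok]; values <- values[ok]
  lt <- as.POSIXlt(time)
  minOfDay <- lt$hour * 60 + lt$min + lt$sec / 60
  nbins <- as.integer(round(1440 / binMinutes))
  bin <- floor(((minOfDay - offsetMin) %% 1440) / binMinutes) + 1L
  m <- rep(NA_real_, nbins); s <- rep(NA_real_, nbins); n <- integer(nbins)
  for (b in seq_len(nbins)) {
    v <- values[bin == b]
    n[b] <- length(v)
    if (length(v)) { m[b] <- mean(v); s[b] <- sd(v) }
  }
  mes <- mean(m[is.finite(m)])
  phase <- which(is.finite(m) & m > mes) - 1L   # bin start hours, 0-based
  hour <- ((seq_len(nbins) - 1L) * binMinutes + offsetMin) / 60
  new("WaveformResult", hour = hour, mean = m, sd = s, n = n, mesor = mes,
      phase = as.integer(floor(hour[phase + 1L])), binMinutes = binMinutes)
}

#' Maximal contiguous above-MESOR intervals (mod 24)
#'
#' Groups the above-MESOR phase hours into maximal runs of consecutive
#' hours, wrapping across midnight; isolated single bins come out as
#' one-hour intervals.
#'
#' @param wf a [WaveformResult-class].
#' @return data.frame(start_hour, end_hour, n_hours, singleton); empty when
#'   the phase is empty.
#' @export
phaseIntervals <- function(wf) {
  stopifnot(is(wf, "WaveformResult"))
  hours <- sort(unique(phaseHours(wf)))
  nb <- 24L
  empty <- data.frame(start_hour = integer(0), end_hour = integer(0),
                      n_hours = integer(0), singleton = logical(0))
  if (!length(hours)) return(empty)
  if (length(hours) == nb)
    return(data.frame(start_hour = 0L, end_hour = 23L, n_hours = nb,
                      singleton = FALSE))
  inPhase <- rep(FALSE, nb); inPhase[hours + 1L] <- TRUE
  ## find run starts: hour in phase whose predecessor (mod 24) is not
  starts <- which(inPhase & !inPhase[(seq_len(nb) - 2L) %% nb + 1L]) - 1L
  out <- lapply(starts, function(s) {
    len <- 0L
    while (inPhase[(s + len) %% nb + 1L]) len <- len + 1L
    data.frame(start_hour = s, end_hour = (s + len - 1L) %% nb,
               n_hours = len, singleton = len == 1L)
  })
  res <- do.call(rbind, out)
  res[order(res$start_hour), , drop = FALSE]
}

#' Calendar-month means and SDs of every series column
#'
#' @param series an [ActivitySeries-class].
#' @return data.frame(month, variable, mean, sd, n) with missing values
#'   excluded per variable.
#' @export
monthlySummary <- function(series) {
  d <- seriesData(series)
  month <- format(d$timestamp, "%Y-%m")
  vars <- names(d)[vapply(d, is.numeric, logical(1))]
  out <- list()
  for (v in vars) {
    for (mo in unique(month)) {
      x <- d[[v]][month == mo]
      x <- x[is.finite(x)]
      out[[length(out) + 1L]] <- data.frame(
        month = mo, variable = v,
        mean = if (length(x)) mean(x) else NA_real_,
        sd = if (length(x) > 1) sd(x) else NA_real_,
        n = length(x))
    }
  }
  res <- do.call(rbind, out)
  res[order(res$variable, res$month), , drop = FALSE]
}
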