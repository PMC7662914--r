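## Pipeline orchestration: the stages of the image-to-statistics chain
## behind one entry point, with YAML config, JSON run-records and
## prerequisite checking. The command-line wrapper in
## inst/scripts/coralrhythm is a thin shell over runStage().

PIPELINE_STAGES <- c("simulate", "enhance", "tag-sample", "build-patches",
                     "train", "evaluate", "map", "compile", "periodogram",
                     "waveform", "mlfn")

#' Default pipeline configuration
#'
#' Every default that has a published value in the study design equals that
#' value (patch size 30, 120/40 pixel sampling, Adam 1e-4/0.9/0.999, batch
#' 256, 100 epochs, window 30 step 10, period band 600-1620 min, threshold
#' 50\%, 9 hidden nodes, 70\% training fraction, degree-3 expansion); the
#' simulate block controls the synthetic fixture scale.
#'
#' @export
defaultPipelineConfig <- function() {
  list(
    paths = list(output_dir = "coralrhythm-out", series_csv = NULL),
    simulate = list(width = 192L, height = 192L, n_frames = 6L,
                    series_hours = 720L),
    imaging = list(clahe = list(clip_limit = 2, tiles = c(8L, 8L)),
                   segmentation = list(hue_bands = list(c(0, 15), c(345, 360)),
                                       sat_range = c(0.35, 1),
                                       val_range = c(0.12, 1)),
                   median_kernel = 3L),
    patches = list(size = 30L, n_fg = 120L, n_bg = 40L),
    cnn = list(conv_blocks = list(c(32L, 32L), c(64L, 64L), c(128L, 128L)),
               dense_units = 512L, epochs = 100L, batch_size = 256L,
               lr = 1e-4, beta1 = 0.9, beta2 = 0.999, augment = TRUE,
               holdout_frac = 0.3),
    window = list(size = 30L, step = 10L),
    chronostats = list(period_range = c(600, 1620), grid_step = 1,
                       bin_minutes = 60, alpha = 0.05),
    mlfn = list(threshold = 50, nodes = 9L, train_frac = 0.7,
                max_degree = 3L, max_iter = 500L),
    seed = 1L)
}

#' Read a pipeline configuration file
#'
#' YAML values override the defaults of [defaultPipelineConfig()]
#' recursively.
#'
#' @param path YAML file (NULL for pure defaults).
#' @export
readPipelineConfig <- function(path = NULL) {
  cfg <- defaultPipelineConfig()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- mergeConfig(cfg, user)
  }
  cfg
}

mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(base[[nm]])))
      base[[nm]] <- mergeConfig(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

configHash <- function(cfg) {
  strHash(as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = 12)))
}

recordPath <- function(cfg, stage)
  file.path(cfg$paths$output_dir, "runrecords", paste0(stage, ".json"))

writeRunRecord <- function(cfg, stage, t0, extras = list()) {
  rp <- recordPath(cfg, stage)
  dir.create(dirname(rp), showWarnings = FALSE, recursive = TRUE)
  rec <- c(list(stage = stage, config_hash = configHash(cfg),
                seed = cfg$seed,
                wall_time_s = round(as.numeric(Sys.time()) - t0, 2),
                r_version = as.character(getRversion()),
                package_version = "0.1.0"),
           extras)
  jsonlite::write_json(rec, rp, auto_unbox = TRUE)
  invisible(rec)
}

needArtifact <- function(path, producer) {
  if (!file.exists(path))
    stop("missing artifact '", path, "'; run stage '", producer, "' first")
  path
}

frameTimestamps <- function(cfg) {
  start <- as.POSIXct("2018-02-23 11:30:00", tz = "UTC")
  start + 3600 * (seq_len(cfg$simulate$n_frames) - 1L)
}

frameId <- function(ts) format(ts, "frame_%Y%m%dT%H%M%S")

## Region layout used by the simulate stage: three rectangles whose
## statuses rotate with the frame index so coverage varies across frames.
simulatedRegions <- function(cfg, frameIdx) {
  w <- cfg$simulate$width; h <- cfg$simulate$height
  rects <- list(c(10L, 10L, as.integer(h / 2), as.integer(w / 2)),
                c(as.integer(h / 2) + 10L, 15L, h - 10L,
                  as.integer(w / 2) - 5L),
                c(15L, as.integer(w / 2) + 10L, h - 20L, w - 10L))
  statuses <- CORAL_LEVELS[(frameIdx + seq_len(3) - 2L) %% 3L + 1L]
  Map(function(r, s) list(rect = r, status = s), rects, statuses)
}

stageSimulate <- function(cfg) {
  out <- cfg$paths$output_dir
  imgDir <- file.path(out, "images")
  dir.create(imgDir, showWarnings = FALSE, recursive = TRUE)
  ts <- frameTimestamps(cfg)
  tags <- list()
  ## tag rectangles extend 8 px beyond the coral section, the way a manual
  ## tag encloses both coral and nearby background
  pad <- function(r) c(max(1L, r[1] - 8L), max(1L, r[2] - 8L),
                       min(cfg$simulate$height, r[3] + 8L),
                       min(cfg$simulate$width, r[4] + 8L))
  for (i in seq_along(ts)) {
    regions <- simulatedRegions(cfg, i)
    spec <- sceneSpec(cfg$simulate$width, cfg$simulate$height, regions,
                      seed = cfg$seed + i)
    scene <- generateColonyImage(spec)
    writeSceneFixture(scene, imgDir, frameId(ts[i]))
    tags <- c(tags, lapply(regions, function(rg)
      regionTag(frameId(ts[i]), pad(rg$rect), rg$status)))
  }
  writeRegionTags(tags, file.path(out, "regions.csv"))
  sp <- seriesSpec(start = ts[1], nHours = cfg$simulate$series_hours,
                   seed = cfg$seed)
  series <- generateActivitySeries(sp)
  writeActivitySeriesCsv(series, file.path(out, "series.csv"))
  ocean <- seriesData(series)[c("timestamp", "temperature_C", "salinity_PSU",
                                "turbidity_NTU", "chl_fluorescence",
                                "depth_m")]
  ocean$timestamp <- format(ocean$timestamp, "%Y-%m-%dT%H:%M:%S")
  write.csv(ocean, file.path(out, "ocean.csv"), row.names = FALSE)
  list(frames = length(ts))
}

stageEnhance <- function(cfg) {
  out <- cfg$paths$output_dir
  imgDir <- needArtifact(file.path(out, "images"), "simulate")
  dst <- file.path(out, "enhanced")
  dir.create(dst, showWarnings = FALSE, recursive = TRUE)
  files <- list.files(imgDir, pattern = "^frame_.*\\.png$")
  files <- files[!grepl("_truth", files)]
  if (!length(files)) stop("no frames in '", imgDir, "'; run stage 'simulate' first")
  for (f in files) {
    img <- readColorImage(file.path(imgDir, f))
    enh <- enhanceClahe(img, cfg$imaging$clahe$clip_limit,
                        unlist(cfg$imaging$clahe$tiles))
    writeColorImage(enh, file.path(dst, f))
  }
  list(frames = length(files))
}

segCfgFrom <- function(cfg) {
  s <- cfg$imaging$segmentation
  hsvMaskConfig(hueBands = s$hue_bands, satRange = unlist(s$sat_range),
                valRange = unlist(s$val_range))
}

loadEnhanced <- function(cfg) {
  out <- cfg$paths$output_dir
  dir <- needArtifact(file.path(out, "enhanced"), "enhance")
  files <- list.files(dir, pattern = "^frame_.*\\.png$", full.names = TRUE)
  imgs <- lapply(files, readColorImage)
  names(imgs) <- sub("\\.png$", "", basename(files))
  imgs
}

stageTagSample <- function(cfg) {
  out <- cfg$paths$output_dir
  tags <- readRegionTags(needArtifact(file.path(out, "regions.csv"),
                                      "simulate"))
  imgs <- loadEnhanced(cfg)
  segCfg <- segCfgFrom(cfg)
  labs <- list()
  for (i in seq_along(tags)) {
    tg <- tags[[i]]
    img <- imgs[[tg$imageId]]
    if (is.null(img)) stop("no enhanced frame for ", tg$imageId,
                           "; run stage 'enhance' first")
    mask <- medianFilterMask(hsvRedMask(img, segCfg),
                             cfg$imaging$median_kernel)
    labs[[i]] <- sampleRegionPixels(tg, mask, cfg$patches$n_fg,
                                    cfg$patches$n_bg, seed = cfg$seed + i)
  }
  labels <- do.call(rbind, labs)
  writePixelLabels(labels, file.path(out, "labels.csv"))
  list(labels = nrow(labels))
}

stageBuildPatches <- function(cfg) {
  out <- cfg$paths$output_dir
  labels <- readPixelLabels(needArtifact(file.path(out, "labels.csv"),
                                         "tag-sample"))
  imgs <- loadEnhanced(cfg)
  ps <- buildPatchDataset(labels, imgs, cfg$patches$size)
  saveRDS(ps, file.path(out, "patches.rds"))
  list(patches = length(patchLabels(ps)))
}

cnnSpecFrom <- function(cfg) {
  cnnSpec(convBlocks = lapply(cfg$cnn$conv_blocks, as.integer),
          denseUnits = cfg$cnn$dense_units,
          inputShape = c(cfg$patches$size, cfg$patches$size, 3L))
}

stageTrain <- function(cfg) {
  out <- cfg$paths$output_dir
  ps <- readRDS(needArtifact(file.path(out, "patches.rds"), "build-patches"))
  y <- patchLabels(ps)
  k <- max(2L, round(1 / cfg$cnn$holdout_frac))
  fold <- stratifiedFolds(y, k, seed = cfg$seed)
  hold <- fold == 1L
  arr <- patches(ps)
  trainSet <- new("LabeledPatchSet", patches = arr[!hold, , , , drop = FALSE],
                  labels = y[!hold],
                  source = patchSource(ps)[!hold, , drop = FALSE])
  model <- buildPatchCnn(cnnSpecFrom(cfg), seed = cfg$seed)
  model <- trainPatchCnn(model, trainSet, epochs = cfg$cnn$epochs,
                         batchSize = cfg$cnn$batch_size, lr = cfg$cnn$lr,
                         beta1 = cfg$cnn$beta1, beta2 = cfg$cnn$beta2,
                         augment = cfg$cnn$augment, seed = cfg$seed)
  saveRDS(list(model = model, holdout = which(hold)),
          file.path(out, "model.rds"))
  jsonlite::write_json(
    list(classes = model@classLevels, input = model@spec$inputShape,
         epochs = cfg$cnn$epochs, finalLoss = tail(model@history, 1)),
    file.path(out, "model_meta.json"), auto_unbox = TRUE)
  list(finalLoss = tail(model@history, 1))
}

stageEvaluate <- function(cfg) {
  out <- cfg$paths$output_dir
  mm <- readRDS(needArtifact(file.path(out, "model.rds"), "train"))
  ps <- readRDS(needArtifact(file.path(out, "patches.rds"), "build-patches"))
  arr <- patches(ps); y <- patchLabels(ps)
  hold <- mm$holdout
  holdSet <- new("LabeledPatchSet", patches = arr[hold, , , , drop = FALSE],
                 labels = y[hold],
                 source = patchSource(ps)[hold, , drop = FALSE])
  rep <- evaluatePatchCnn(mm$model, holdSet)
  jsonlite::write_json(
    list(accuracy = rep@accuracy, auc = rep@auc,
         pa = as.list(rep@pa), ua = as.list(rep@ua),
         confusion = as.data.frame.matrix(rep@confusion)),
    file.path(out, "metrics.json"), auto_unbox = TRUE)
  list(accuracy = rep@accuracy)
}

stageMap <- function(cfg) {
  out <- cfg$paths$output_dir
  mm <- readRDS(needArtifact(file.path(out, "model.rds"), "train"))
  imgs <- loadEnhanced(cfg)
  rows <- list()
  dir.create(file.path(out, "maps"), showWarnings = FALSE)
  for (nm in names(imgs)) {
    sm <- segmentFrame(imgs[[nm]], mm$model, cfg$window$size,
                       cfg$window$step)
    png::writePNG(statusGrid(sm) / 255, file.path(out, "maps",
                                                  paste0(nm, "_map.png")))
    p <- statusPercentages(sm)
    ts <- as.POSIXct(sub("frame_", "", nm), format = "%Y%m%dT%H%M%S",
                     tz = "UTC")
    rows[[nm]] <- data.frame(timestamp = format(ts, "%Y-%m-%dT%H:%M:%S"),
                             bloated_pct = p$bloated_pct,
                             semi_bloated_pct = p$semi_bloated_pct,
                             non_bloated_pct = p$non_bloated_pct,
                             empty_frame = p$empty)
  }
  cov <- do.call(rbind, rows)
  write.csv(cov, file.path(out, "coverage.csv"), row.names = FALSE)
  list(frames = nrow(cov))
}

stageCompile <- function(cfg) {
  out <- cfg$paths$output_dir
  cov <- read.csv(needArtifact(file.path(out, "coverage.csv"), "map"))
  ocean <- read.csv(needArtifact(file.path(out, "ocean.csv"), "simulate"))
  ocean$timestamp <- as.POSIXct(ocean$timestamp,
                                format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  frames <- lapply(seq_len(nrow(cov)), function(i)
    list(timestamp = as.POSIXct(cov$timestamp[i],
                                format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
         pct = list(bloated_pct = cov$bloated_pct[i],
                    semi_bloated_pct = cov$semi_bloated_pct[i],
                    non_bloated_pct = cov$non_bloated_pct[i],
                    empty = cov$empty_frame[i])))
  series <- compileSeries(frames, ocean, calibration = chlCalibration())
  writeActivitySeriesCsv(series, file.path(out, "compiled.csv"))
  list(rows = nrow(seriesData(series)))
}

chronoInput <- function(cfg) {
  path <- cfg$paths$series_csv %||%
    file.path(cfg$paths$output_dir, "series.csv")
  needArtifact(path, "simulate")
  readActivitySeriesCsv(path)
}

stagePeriodogram <- function(cfg) {
  out <- cfg$paths$output_dir
  series <- chronoInput(cfg)
  d <- seriesData(series)
  pg <- lombScargle(d$timestamp, d$bloated_pct,
                    periodRange = unlist(cfg$chronostats$period_range),
                    gridStepMin = cfg$chronostats$grid_step,
                    alpha = cfg$chronostats$alpha)
  write.csv(data.frame(period_min = pg@period, power_pct = pg@power),
            file.path(out, "periodogram.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(threshold = pg@threshold, alpha = pg@alpha,
         peaks = periodogramPeaks(pg)),
    file.path(out, "periodogram_peaks.json"), auto_unbox = TRUE)
  list(topPeak = if (nrow(periodogramPeaks(pg)))
    periodogramPeaks(pg)$period[1] else NA)
}

stageWaveform <- function(cfg) {
  out <- cfg$paths$output_dir
  series <- chronoInput(cfg)
  d <- seriesData(series)
  res <- list()
  for (v in c("bloated_pct", "semi_bloated_pct", "non_bloated_pct")) {
    wf <- waveformAnalysis(d$timestamp, d[[v]],
                           binMinutes = cfg$chronostats$bin_minutes)
    write.csv(data.frame(hour = wf@hour, mean = wf@mean, sd = wf@sd,
                         n = wf@n),
              file.path(out, paste0("waveform_", v, ".csv")),
              row.names = FALSE)
    res[[v]] <- list(mesor = mesor(wf), phase = phaseHours(wf),
                     intervals = phaseIntervals(wf))
  }
  jsonlite::write_json(res, file.path(out, "waveform_summary.json"),
                       auto_unbox = TRUE)
  list(mesorBloated = res$bloated_pct$mesor)
}

stageMlfn <- function(cfg) {
  out <- cfg$paths$output_dir
  series <- chronoInput(cfg)
  d <- seriesData(series)
  d <- d[complete.cases(d[c("bloated_pct", "temperature_C", "salinity_PSU",
                            "turbidity_NTU", "chl_fluorescence",
                            "depth_m")]), ]
  lt <- as.POSIXlt(d$timestamp)
  base <- cbind(hour_frac = (lt$hour * 60 + lt$min) / 1440,
                chlorophyll = d$chl_fluorescence,
                temperature = d$temperature_C, depth = d$depth_m,
                turbidity = d$turbidity_NTU, salinity = d$salinity_PSU,
                fov = if (!is.null(d$fov)) d$fov
                else as.integer(seq_len(nrow(d)) > nrow(d) / 2))
  y <- binarizeBloated(d$bloated_pct)
  part <- partitionEuclidean(base, cfg$mlfn$train_frac)
  std <- standardizeBlock(base[part$train, , drop = FALSE])
  stdTest <- standardizeBlock(base[part$test, , drop = FALSE],
                              center = std$center, scale = std$scale)
  fbTrain <- expandFeatures(std$x, cfg$mlfn$max_degree,
                            center = std$center, scale = std$scale)
  fbTest <- expandFeatures(stdTest$x, cfg$mlfn$max_degree,
                           center = std$center, scale = std$scale)
  model <- suppressWarnings(
    trainMlfn(featureMatrix(fbTrain), y[part$train],
              nodes = cfg$mlfn$nodes, maxIter = cfg$mlfn$max_iter,
              seed = cfg$seed))
  predTr <- predictMlfn(model, featureMatrix(fbTrain))$class
  predTe <- predictMlfn(model, featureMatrix(fbTest))$class
  mTr <- confusionMetrics(y[part$train], predTr)
  mTe <- confusionMetrics(y[part$test], predTe)
  imp <- featureImportance(model)
  write.csv(imp, file.path(out, "mlfn_importance.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(train = mTr[c("precision", "recall", "pct_bad", "n")],
         test = mTe[c("precision", "recall", "pct_bad", "n")],
         converged = model@converged),
    file.path(out, "mlfn_metrics.json"), auto_unbox = TRUE)
  list(testPrecision = mTe$precision, testRecall = mTe$recall)
}

#' Run one pipeline stage
#'
#' Stages write their artifacts under the configured output directory along
#' with a JSON run-record (config hash, seed, wall time). A stage whose
#' run-record already matches the current config is skipped unless
#' \code{force}; missing prerequisites raise an error naming the producing
#' stage.
#'
#' @param stage one of simulate, enhance, tag-sample, build-patches, train,
#'   evaluate, map, compile, periodogram, waveform, mlfn.
#' @param cfg a configuration list ([readPipelineConfig()]).
#' @param force re-run even when the run-record is up to date.
#' @return invisibly, the stage's summary list (with \code{skipped = TRUE}
#'   when skipped).
#' @export
runStage <- function(stage, cfg = readPipelineConfig(), force = FALSE) {
  stage <- match.arg(stage, PIPELINE_STAGES)
  rp <- recordPath(cfg, stage)
  if (!force && file.exists(rp)) {
    rec <- jsonlite::read_json(rp)
    if (identical(rec$config_hash, configHash(cfg)))
      return(invisible(list(skipped = TRUE)))
  }
  t0 <- as.numeric(Sys.time())
  fn <- switch(stage,
    "simulate" = stageSimulate, "enhance" = stageEnhance,
    "tag-sample" = stageTagSample, "build-patches" = stageBuildPatches,
    "train" = stageTrain, "evaluate" = stageEvaluate, "map" = stageMap,
    "compile" = stageCompile, "periodogram" = stagePeriodogram,
    "waveform" = stageWaveform, "mlfn" = stageMlfn)
  res <- fn(cfg)
  writeRunRecord(cfg, stage, t0, res)
  invisible(res)
}
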