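## Shared fixture builders, memoized so expensive objects (the trained
## classifier in particular) are built once per test run.

fixtureSceneSpec <- function(seed = 3L) {
  sceneSpec(160, 160, list(
    list(rect = c(11, 11, 80, 80), status = "bloated"),
    list(rect = c(90, 11, 150, 70), status = "non_bloated"),
    list(rect = c(11, 95, 70, 150), status = "semi_bloated")), seed = seed)
}

## Tag rectangles extend 8 px beyond the coral sections so each contains
## both foreground and background pixels.
fixtureTags <- function(id) {
  list(regionTag(id, c(3, 3, 88, 88), "bloated"),
       regionTag(id, c(82, 3, 158, 78), "non_bloated"),
       regionTag(id, c(3, 87, 78, 158), "semi_bloated"))
}

.fixtureCache <- new.env(parent = emptyenv())

fixturePatchData <- function() {
  if (!is.null(.fixtureCache$patchData)) return(.fixtureCache$patchData)
  imgs <- list(); labs <- list()
  for (s in 1:3) {
    sc <- generateColonyImage(fixtureSceneSpec(s))
    id <- paste0("img", s)
    imgs[[id]] <- sc$image
    mask <- medianFilterMask(hsvRedMask(sc$image))
    tags <- fixtureTags(id)
    labs <- c(labs, lapply(seq_along(tags), function(i)
      sampleRegionPixels(tags[[i]], mask, 120, 40, seed = s * 10 + i)))
  }
  labels <- do.call(rbind, labs)
  .fixtureCache$patchData <-
    list(images = imgs, labels = labels,
         patchset = buildPatchDataset(labels, imgs))
  .fixtureCache$patchData
}

fixtureCnnSpec <- function() {
  cnnSpec(convBlocks = list(c(8L, 8L), c(16L, 16L), c(32L, 32L)),
          denseUnits = 64L)
}

## A classifier trained on the fixture patches (10 epochs on a reduced-width
## network), shared across test files.
fixtureTrainedModel <- function() {
  if (!is.null(.fixtureCache$model)) return(.fixtureCache$model)
  ps <- fixturePatchData()$patchset
  m <- buildPatchCnn(fixtureCnnSpec(), seed = 1)
  m <- trainPatchCnn(m, ps, epochs = 10, batchSize = 64, lr = 2e-3,
                     seed = 1)
  .fixtureCache$model <- m
  m
}

subsetPatchSet <- function(ps, idx) {
  new("LabeledPatchSet", patches = patches(ps)[idx, , , , drop = FALSE],
      labels = patchLabels(ps)[idx],
      source = patchSource(ps)[idx, , drop = FALSE])
}

## The MLFN recovery dataset: fixture series covariates, response generated
## from the known monomial signal on standardized chlorophyll and depth.
mlfnRecoveryData <- function(n = 1500L, seed = 42L) {
  key <- paste0("mlfn", n, "_", seed)
  if (!is.null(.fixtureCache[[key]])) return(.fixtureCache[[key]])
  d <- seriesData(generateActivitySeries(seriesSpec(nHours = n, seed = seed)))
  zlin <- 2 * as.numeric(scale(d$chl_fluorescence)) -
    1.5 * as.numeric(scale(d$depth_m))
  y <- withSeed(seed + 1, rbinom(nrow(d), 1, 1 / (1 + exp(-zlin))))
  lt <- as.POSIXlt(d$timestamp)
  base <- cbind(hour_frac = (lt$hour * 60 + lt$min) / 1440,
                chlorophyll = d$chl_fluorescence,
                temperature = d$temperature_C, depth = d$depth_m,
                turbidity = d$turbidity_NTU, salinity = d$salinity_PSU,
                fov = as.integer(seq_len(nrow(d)) > nrow(d) / 2))
  part <- partitionEuclidean(base, 0.7)
  std <- standardizeBlock(base[part$train, , drop = FALSE])
  stdT <- standardizeBlock(base[part$test, , drop = FALSE],
                           center = std$center, scale = std$scale)
  res <- list(y = y, part = part,
              xTrain = featureMatrix(expandFeatures(std$x)),
              xTest = featureMatrix(expandFeatures(stdT$x)))
  .fixtureCache[[key]] <- res
  res
}
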