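#' @name accessors
#' @title Accessors for coralrhythm containers
#' @description Slot accessors for the core S4 containers; user code should
#'   use these rather than reaching into slots.
#' @param object a coralrhythm S4 object.
NULL

#' @rdname accessors
#' @export
setGeneric("statusGrid", function(object) standardGeneric("statusGrid"))
#' @rdname accessors
#' @export
setMethod("statusGrid", "StatusMap", function(object) object@grid)

#' @rdname accessors
#' @export
setGeneric("windowSize", function(object) standardGeneric("windowSize"))
#' @rdname accessors
#' @export
setMethod("windowSize", "StatusMap", function(object) object@window)

#' @rdname accessors
#' @export
setGeneric("stepSize", function(object) standardGeneric("stepSize"))
#' @rdname accessors
#' @export
setMethod("stepSize", "StatusMap", function(object) object@step)

#' @rdname accessors
#' @export
setGeneric("patches", function(object) standardGeneric("patches"))
#' @rdname accessors
#' @export
setMethod("patches", "LabeledPatchSet", function(object) object@patches)

#' @rdname accessors
#' @export
setGeneric("patchLabels", function(object) standardGeneric("patchLabels"))
#' @rdname accessors
#' @export
setMethod("patchLabels", "LabeledPatchSet", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("patchSource", function(object) standardGeneric("patchSource"))
#' @rdname accessors
#' @export
setMethod("patchSource", "LabeledPatchSet", function(object) object@source)

#' @rdname accessors
#' @export
setGeneric("seriesData", function(object) standardGeneric("seriesData"))
#' @rdname accessors
#' @export
setMethod("seriesData", "ActivitySeries", function(object) object@data)

#' @rdname accessors
#' @export
setGeneric("mesor", function(object) standardGeneric("mesor"))
#' @rdname accessors
#' @export
setMethod("mesor", "WaveformResult", function(object) object@mesor)

#' @rdname accessors
#' @export
setGeneric("phaseHours", function(object) standardGeneric("phaseHours"))
#' @rdname accessors
#' @export
setMethod("phaseHours", "WaveformResult", function(object) object@phase)

#' @rdname accessors
#' @export
setGeneric("periodogramPeaks", function(object) standardGeneric("periodogramPeaks"))
#' @rdname accessors
#' @export
setMethod("periodogramPeaks", "PeriodogramResult", function(object) object@peaks)

#' @rdname accessors
#' @export
setGeneric("confusion", function(object) standardGeneric("confusion"))
#' @rdname accessors
#' @export
setMethod("confusion", "EvalReport", function(object) object@confusion)

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(object) standardGeneric("featureMatrix"))
#' @rdname accessors
#' @export
setMethod("featureMatrix", "FeatureBlock", function(object) object@x)

#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setMethod("provenance", "FeatureBlock", function(object) object@provenance)

setMethod("show", "StatusMap", function(object) {
  g <- object@grid
  cat(sprintf("StatusMap: %d x %d cells (window %d, step %d, %s)\n",
              nrow(g), ncol(g), object@window, object@step, object@aggregation))
  tab <- tabulate(g + 1L, nbins = 4L)
  cat(sprintf("  %s: %d cells\n", STATUS_LEVELS, tab), sep = "")
})

setMethod("show", "LabeledPatchSet", function(object) {
  d <- dim(object@patches)
  cat(sprintf("LabeledPatchSet: %d patches of %d x %d x %d\n", d[1], d[2], d[3], d[4]))
  print(table(object@labels))
})

setMethod("show", "ActivitySeries", function(object) {
  d <- object@data
  cat(sprintf("ActivitySeries: %d rows, %s .. %s\n", nrow(d),
              format(min(d$timestamp)), format(max(d$timestamp))))
  cat(sprintf("  mean coverage: bloated %.1f%%, semi %.1f%%, non %.1f%%\n",
              mean(d$bloated_pct), mean(d$semi_bloated_pct), mean(d$non_bloated_pct)))
  ocean <- intersect(c("temperature_C", "salinity_PSU", "turbidity_NTU",
                       "chl_fluorescence", "depth_m"), names(d))
  if (length(ocean)) {
    nmiss <- sum(!complete.cases(d[ocean]))
    cat(sprintf("  oceanographic columns: %d (%d rows with gaps)\n",
                length(ocean), nmiss))
  }
})

setMethod("show", "PatchCnn", function(object) {
  s <- object@spec
  cat(sprintf("PatchCnn: input %s, conv blocks %s, dense %d, %d classes (%s)\n",
              paste(s$inputShape, collapse = "x"),
              paste(vapply(s$convBlocks, function(b) paste(b, collapse = "-"),
                           character(1)), collapse = " | "),
              s$denseUnits, s$nClasses,
              if (object@trained) "trained" else "untrained"))
  if (length(object@history))
    cat(sprintf("  final training loss: %.4f (%d epochs)\n",
                tail(object@history, 1), length(object@history)))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: accuracy %.2f%%, macro AUC %s\n",
              100 * object@accuracy,
              if (is.na(object@auc)) "NA" else sprintf("%.4f", object@auc)))
  cat("Confusion (targets on rows):\n")
  print(object@confusion)
  m <- rbind(`PA (%)` = 100 * object@pa, `UA (%)` = 100 * object@ua)
  print(round(m, 2))
})

setMethod("show", "PeriodogramResult", function(object) {
  cat(sprintf("PeriodogramResult: %d periods in [%g, %g] min, n = %d\n",
              length(object@period), min(object@period), max(object@period),
              object@n))
  if (object@constant) {
    cat("  constant series: no power anywhere\n")
  } else if (nrow(object@peaks)) {
    p <- object@peaks[which.max(object@peaks$power), ]
    cat(sprintf("  top significant peak: %g min (%.1f%% variance, p = %.3g)\n",
                p$period, p$power, p$p))
  } else cat(sprintf("  no peak above the alpha = %g threshold\n", object@alpha))
})

setMethod("show", "WaveformResult", function(object) {
  cat(sprintf("WaveformResult: %d bins of %g min, MESOR %.3f\n",
              length(object@hour), object@binMinutes, object@mesor))
  if (length(object@phase))
    cat("  above-MESOR hours:", paste(object@phase, collapse = " "), "\n")
  else cat("  no hours above MESOR\n")
})

setMethod("show", "MlfnModel", function(object) {
  cat(sprintf("MlfnModel: %d sigmoid nodes x %d features, softmax output\n",
              nrow(object@w1), ncol(object@w1)))
  cat(sprintf("  alpha %.3g, beta %.3g, %s\n", object@alpha, object@beta,
              if (object@converged) "converged" else "NOT converged"))
})

setMethod("show", "FeatureBlock", function(object) {
  deg <- vapply(object@provenance, length, integer(1))
  cat(sprintf("FeatureBlock: %d rows x %d monomials over %d base columns (degrees %s)\n",
              nrow(object@x), ncol(object@x), length(object@baseNames),
              paste(range(deg), collapse = "-")))
})
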