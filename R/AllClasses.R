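#' StatusMap: per-cell behavioral classification of one frame
#'
#' A coarse grid of class assignments produced either by sliding-window
#' classification of a frame ([segmentFrame()]) or, at pixel resolution
#' (window = step = 1), as the ground truth of a synthetic scene. Codes are
#' 0 = background, 1 = bloated, 2 = semi_bloated, 3 = non_bloated.
#'
#' @slot grid integer matrix of class codes at stride resolution.
#' @slot window window side length in pixels used to classify each cell.
#' @slot step stride between window anchors in pixels.
#' @slot aggregation how overlapping window scores were combined.
#' @export
setClass("StatusMap",
  slots = c(grid = "matrix", window = "integer", step = "integer",
            aggregation = "character"),
  prototype = list(aggregation = "softmax-mean"))

setValidity("StatusMap", function(object) {
  g <- object@grid
  if (!is.integer(g)) return("grid must be an integer matrix")
  if (length(g) && (min(g) < 0L || max(g) > 3L))
    return("grid codes must lie in 0..3")
  if (object@window < 1L || object@step < 1L)
    return("window and step must be >= 1")
  TRUE
})

#' LabeledPatchSet: square image crops with behavioral class labels
#'
#' The training/test currency of the patch classifier: N crops of size
#' \code{size x size x 3} (RGB in 0..255), each labeled with one of the four
#' classes, plus the source pixel each patch was extracted around.
#'
#' @slot patches numeric array \code{N x size x size x 3}.
#' @slot labels factor with levels background, bloated, semi_bloated,
#'   non_bloated.
#' @slot source data.frame with columns image_id, row, col (one row per patch).
#' @export
setClass("LabeledPatchSet",
  slots = c(patches = "array", labels = "factor", source = "data.frame"))

setValidity("LabeledPatchSet", function(object) {
  d <- dim(object@patches)
  if (length(d) != 4L) return("patches must be a 4-d array N x s x s x 3")
  if (d[2] != d[3] || d[4] != 3L) return("patches must be square with 3 channels")
  if (d[1] != length(object@labels)) return("labels length must equal N")
  if (!identical(levels(object@labels), STATUS_LEVELS))
    return("labels must use the canonical 4 status levels")
  TRUE
})

#' ActivitySeries: behavioral coverage plus aligned oceanographic record
#'
#' One row per frame timestamp with the colony coverage percentages of the
#' three activity statuses (summing to 100 where coral was detected) and the
#' oceanographic readings joined at that time (NA inside sensor gaps).
#'
#' @slot data data.frame with columns timestamp (POSIXct), bloated_pct,
#'   semi_bloated_pct, non_bloated_pct, temperature_C, salinity_PSU,
#'   turbidity_NTU, chl_fluorescence, depth_m, and optionally fov and
#'   empty_frame.
#' @export
setClass("ActivitySeries", slots = c(data = "data.frame"))

setValidity("ActivitySeries", function(object) {
  d <- object@data
  need <- c("timestamp", "bloated_pct", "semi_bloated_pct", "non_bloated_pct")
  miss <- setdiff(need, names(d))
  if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (!inherits(d$timestamp, "POSIXct")) return("timestamp must be POSIXct")
  if (is.unsorted(d$timestamp)) return("timestamps must be sorted")
  tot <- d$bloated_pct + d$semi_bloated_pct + d$non_bloated_pct
  sel <- if (!is.null(d$empty_frame)) !d$empty_frame else rep(TRUE, nrow(d))
  if (any(abs(tot[sel] - 100) > 1e-6))
    return("status percentages must sum to 100 on non-empty frames")
  TRUE
})

#' PatchCnn: the patch classifier model handle
#'
#' Holds the layer specification, current weights and training history of the
#' convolutional patch classifier.
#'
#' @slot spec list describing conv blocks, dense width, dropout rates, input
#'   shape and class count (see [cnnSpec()]).
#' @slot weights list of conv and dense layer weights.
#' @slot classLevels character; class order of the softmax output.
#' @slot trained logical.
#' @slot history numeric; per-epoch mean training loss.
#' @export
setClass("PatchCnn",
  slots = c(spec = "list", weights = "list", classLevels = "character",
            trained = "logical", history = "numeric"))

#' EvalReport: confusion matrix and derived accuracy metrics
#'
#' @slot confusion K x K integer matrix, targets on rows.
#' @slot accuracy overall accuracy (trace / total).
#' @slot pa producer's accuracy per class (recall, diag / row sum).
#' @slot ua user's accuracy per class (precision, diag / column sum).
#' @slot auc macro one-vs-rest AUC from softmax scores (NA if unavailable).
#' @export
setClass("EvalReport",
  slots = c(confusion = "matrix", accuracy = "numeric", pa = "numeric",
            ua = "numeric", auc = "numeric"))

setValidity("EvalReport", function(object) {
  cm <- object@confusion
  if (nrow(cm) != ncol(cm)) return("confusion must be square")
  if (any(cm < 0)) return("confusion entries must be >= 0")
  if (sum(cm) > 0 && abs(object@accuracy - sum(diag(cm)) / sum(cm)) > 1e-12)
    return("accuracy must equal trace/total")
  TRUE
})

#' PeriodogramResult: Lomb-Scargle scan over a period band
#'
#' @slot period scanned periods in minutes (evenly spaced grid).
#' @slot power percent of total variance explained at each period.
#' @slot threshold power level corresponding to the significance level alpha.
#' @slot alpha family-wise false-alarm level used for the threshold.
#' @slot peaks data.frame(period, power, p) of significant local maxima.
#' @slot n number of finite samples used.
#' @slot constant TRUE if the input series had zero variance.
#' @export
setClass("PeriodogramResult",
  slots = c(period = "numeric", power = "numeric", threshold = "numeric",
            alpha = "numeric", peaks = "data.frame", n = "integer",
            constant = "logical"))

#' WaveformResult: 24-h mean daily profile with MESOR and phase
#'
#' @slot hour bin start hour (0..23 by default binning).
#' @slot mean,sd,n per-bin statistics across all days.
#' @slot mesor mean of the non-empty bin means.
#' @slot phase integer hours whose bin mean is strictly above the MESOR.
#' @slot binMinutes bin width in minutes.
#' @export
setClass("WaveformResult",
  slots = c(hour = "numeric", mean = "numeric", sd = "numeric", n = "integer",
            mesor = "numeric", phase = "integer", binMinutes = "numeric"))

setValidity("WaveformResult", function(object) {
  ok <- is.finite(object@mean)
  if (any(ok) && abs(object@mesor - mean(object@mean[ok])) > 1e-9)
    return("mesor must equal the mean of the non-empty bin means")
  if (length(object@phase) && (min(object@phase) < 0 || max(object@phase) > 23))
    return("phase hours must lie in 0..23")
  TRUE
})

#' FeatureBlock: standardized predictors and their polynomial expansion
#'
#' @slot x numeric matrix, one column per monomial, in frozen enumeration
#'   order (degree ascending, then lexicographic by provenance).
#' @slot provenance list of integer vectors; each gives the (sorted) base
#'   column indices whose product forms the monomial.
#' @slot baseNames names of the base columns.
#' @slot center,scale standardization parameters of the continuous base
#'   columns (fit on the training partition).
#' @export
setClass("FeatureBlock",
  slots = c(x = "matrix", provenance = "list", baseNames = "character",
            center = "numeric", scale = "numeric"))

setValidity("FeatureBlock", function(object) {
  if (ncol(object@x) != length(object@provenance))
    return("one provenance tuple per column required")
  if (any(vapply(object@provenance, is.unsorted, logical(1))))
    return("provenance tuples must be sorted")
  TRUE
})

#' MlfnModel: shallow feed-forward classifier with Bayesian regularization
#'
#' Single hidden layer of sigmoid nodes and a 2-way softmax output, trained
#' by minimizing beta*SSE + alpha*||w||^2 with evidence-framework updates of
#' (alpha, beta).
#'
#' @slot w1 hidden weights (nodes x k); @slot b1 hidden biases.
#' @slot w2 output weights (2 x nodes); @slot b2 output biases.
#' @slot featureNames column names of the k input features.
#' @slot alpha,beta final regularization hyperparameters.
#' @slot converged logical; FALSE carries a warning flag.
#' @slot log list with iteration counts, gamma (effective parameters) etc.
#' @export
setClass("MlfnModel",
  slots = c(w1 = "matrix", b1 = "numeric", w2 = "matrix", b2 = "numeric",
            featureNames = "character", alpha = "numeric", beta = "numeric",
            converged = "logical", log = "list"))

setValidity("MlfnModel", function(object) {
  if (ncol(object@w1) != length(object@featureNames))
    return("w1 columns must match featureNames")
  if (nrow(object@w2) != 2L || ncol(object@w2) != nrow(object@w1))
    return("w2 must be 2 x nodes")
  TRUE
})
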