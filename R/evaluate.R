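## Evaluation: confusion matrices with producer's/user's accuracy and macro
## one-vs-rest AUC, plus stratified k-fold cross-validation of the patch
## classifier.

## Rank-based (Mann-Whitney) AUC for one class vs the rest.
aucBinary <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Build an evaluation report from labels and scores
#'
#' Producer's accuracy (PA) is per-class recall (diagonal over row sum,
#' targets on rows); user's accuracy (UA) is per-class precision (diagonal
#' over column sum). AUC is the macro average of one-vs-rest rank AUCs over
#' the classes present.
#'
#' @param truth factor of target labels.
#' @param probs matrix of class scores (columns in level order) or NULL.
#' @param pred optional factor of predicted labels; defaults to the argmax
#'   of \code{probs}.
#' @return an [EvalReport-class].
#' @export
evalReport <- function(truth, probs = NULL, pred = NULL) {
  stopifnot(is.factor(truth))
  lev <- levels(truth)
  if (is.null(pred)) {
    stopifnot(!is.null(probs), ncol(probs) == length(lev))
    pred <- factor(lev[max.col(probs, ties.method = "first")], levels = lev)
  }
  pred <- factor(pred, levels = lev)
  cm <- table(target = truth, prediction = pred)
  cm <- matrix(as.integer(cm), nrow(cm), ncol(cm), dimnames = dimnames(cm))
  acc <- if (sum(cm)) sum(diag(cm)) / sum(cm) else NA_real_
  pa <- diag(cm) / rowSums(cm)
  ua <- diag(cm) / colSums(cm)
  auc <- NA_real_
  if (!is.null(probs)) {
    aucs <- vapply(seq_along(lev), function(k)
      aucBinary(probs[, k], truth == lev[k]), numeric(1))
    if (any(!is.na(aucs))) auc <- mean(aucs, na.rm = TRUE)
  }
  new("EvalReport", confusion = cm, accuracy = acc, pa = pa, ua = ua,
      auc = auc)
}

#' Evaluate a trained patch classifier on labeled patches
#'
#' @param model a trained [PatchCnn-class].
#' @param patchset a [LabeledPatchSet-class].
#' @return an [EvalReport-class].
#' @export
evaluatePatchCnn <- function(model, patchset) {
  probs <- predictPatchCnn(model, patchset)
  truth <- factor(patchLabels(patchset), levels = model@classLevels)
  evalReport(truth, probs)
}

#' Stratified fold assignment
#'
#' Per-class shuffled round-robin assignment: fold sizes differ by at most
#' one and per-class proportions in each fold are within one sample of the
#' global proportions.
#'
#' @param y factor of class labels.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer vector of fold ids in 1..k.
#' @export
stratifiedFolds <- function(y, k = 10L, seed = 1L) {
  counts <- table(droplevels(y))
  if (any(counts < k))
    stop("every class must have at least k = ", k, " members; offending: ",
         paste(names(counts)[counts < k], collapse = ", "))
  fold <- integer(length(y))
  withSeed(seed, {
    for (cl in names(counts)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Cross-validate the patch classifier
#'
#' k disjoint stratified validation folds covering the data; the summary
#' performance is the average of the per-fold validation performances.
#'
#' @param patchset a [LabeledPatchSet-class].
#' @param spec a [cnnSpec()] used for each fold's fresh model.
#' @param k folds (default 10).
#' @param stratified preserve per-class proportions in each fold.
#' @param seed RNG seed (drives fold assignment and each fold's training).
#' @param ... passed to [trainPatchCnn()] (epochs, batchSize, ...).
#' @return list with per-fold \code{reports}, \code{meanAccuracy},
#'   \code{meanAuc} and the fold assignment.
#' @export
crossValidatePatchCnn <- function(patchset, spec = cnnSpec(), k = 10L,
                                  stratified = TRUE, seed = 1L, ...) {
  y <- patchLabels(patchset)
  fold <- if (stratified) stratifiedFolds(y, k, seed)
  else withSeed(seed, sample(rep_len(seq_len(k), length(y))))
  arr <- patches(patchset)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    trainSet <- new("LabeledPatchSet",
                    patches = arr[tr, , , , drop = FALSE],
                    labels = y[tr],
                    source = patchSource(patchset)[tr, , drop = FALSE])
    valSet <- new("LabeledPatchSet",
                  patches = arr[!tr, , , , drop = FALSE],
                  labels = y[!tr],
                  source = patchSource(patchset)[!tr, , drop = FALSE])
    model <- buildPatchCnn(spec, seed = seed + f)
    model <- trainPatchCnn(model, trainSet, seed = seed + f, ...)
    reports[[f]] <- evaluatePatchCnn(model, valSet)
  }
  accs <- vapply(reports, function(r) r@accuracy, numeric(1))
  aucs <- vapply(reports, function(r) r@auc, numeric(1))
  list(reports = reports, meanAccuracy = mean(accs),
       meanAuc = mean(aucs, na.rm = TRUE), folds = fold)
}
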