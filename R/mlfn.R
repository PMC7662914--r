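## Multivariate modeling of colony behavior: binarization of the bloated
## coverage, standardization, combinatorial polynomial feature expansion,
## CV-based feature-count selection, Kennard-Stone Euclidean partitioning,
## a single-hidden-layer sigmoid/softmax network trained with Bayesian
## regularization, and the post-hoc diagnostics (hidden-weight feature
## importance and sigmoid activation profiles).

#' Binarize bloated coverage
#'
#' 1 iff the bloated percentage is >= 50, else 0.
#'
#' @param pct bloated percentage(s) in [0, 100].
#' @export
binarizeBloated <- function(pct) {
  if (any(!is.finite(pct)) || any(pct < 0) || any(pct > 100))
    stop("percentages must be finite and in [0, 100]")
  as.integer(pct >= 50)
}

#' Standardize the base predictor block
#'
#' Continuous columns are centered and scaled; binary dummy columns are
#' left untouched. Parameters are fit on the training rows only and can be
#' re-applied to test rows (no leakage).
#'
#' @param x numeric matrix with named columns.
#' @param binaryCols names of binary dummy columns (not standardized).
#' @param center,scale optional parameters from a previous fit.
#' @return list with \code{x}, \code{center}, \code{scale}.
#' @export
standardizeBlock <- function(x, binaryCols = "fov", center = NULL,
                             scale = NULL) {
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  cont <- setdiff(colnames(x), binaryCols)
  if (is.null(center)) {
    center <- colMeans(x[, cont, drop = FALSE])
    scale <- apply(x[, cont, drop = FALSE], 2, sd)
  }
  if (any(scale == 0)) stop("constant continuous column cannot be standardized")
  x[, cont] <- sweep(sweep(x[, cont, drop = FALSE], 2, center), 2, scale, "/")
  list(x = x, center = center, scale = scale)
}

## All size-d multisets over 1..p, lexicographic.
multisets <- function(p, d, start = 1L) {
  if (d == 0L) return(list(integer(0)))
  out <- list()
  for (i in start:p)
    out <- c(out, lapply(multisets(p, d - 1L, i), function(m) c(i, m)))
  out
}

monomialName <- function(tuple, baseNames) {
  tab <- table(tuple)
  paste(vapply(names(tab), function(i) {
    nm <- baseNames[as.integer(i)]
    if (tab[[i]] > 1) paste0(nm, "^", tab[[i]]) else nm
  }, character(1)), collapse = "*")
}

#' Combinatorial polynomial feature expansion
#'
#' All unique monomials of degree 1..maxDegree over the base columns,
#' enumerated degree-ascending then lexicographically by provenance tuple —
#' the frozen order that "first k columns" refers to everywhere else.
#' Powers of binary dummies collapse (x^2 = x for x in {0,1}) and the
#' resulting duplicates are dropped, keeping the first (lowest-degree)
#' occurrence.
#'
#' @param x standardized base matrix (named columns; see
#'   [standardizeBlock()]).
#' @param maxDegree maximum monomial degree (default 3).
#' @param binaryCols names of binary columns whose powers collapse.
#' @param center,scale standardization parameters to record.
#' @return a [FeatureBlock-class].
#' @export
expandFeatures <- function(x, maxDegree = 3L, binaryCols = "fov",
                           center = numeric(0), scale = numeric(0)) {
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  if (any(!is.finite(x))) stop("non-finite values in the base block")
  p <- ncol(x)
  baseNames <- colnames(x)
  binIdx <- which(baseNames %in% binaryCols)
  tuples <- list()
  for (d in seq_len(maxDegree)) tuples <- c(tuples, multisets(p, d))
  ## collapse powers of binary columns, then drop duplicates (keep first)
  collapsed <- lapply(tuples, function(tp) {
    isBin <- tp %in% binIdx
    sort(c(unique(tp[isBin]), tp[!isBin]))
  })
  keys <- vapply(collapsed, paste, character(1), collapse = ",")
  keep <- !duplicated(keys)
  tuples <- collapsed[keep]
  cols <- vapply(tuples, function(tp) {
    v <- rep(1, nrow(x))
    for (i in tp) v <- v * x[, i]
    v
  }, numeric(nrow(x)))
  cols <- matrix(cols, nrow = nrow(x))
  colnames(cols) <- vapply(tuples, monomialName, character(1), baseNames)
  new("FeatureBlock", x = cols, provenance = tuples, baseNames = baseNames,
      center = center, scale = scale)
}

#' Count of unique monomials by stars-and-bars
#'
#' Reference count \code{sum_d C(p + d - 1, d)} of degree <= maxDegree
#' monomials over p columns, before binary-power collapsing.
#'
#' @param p base columns; @param maxDegree maximum degree.
#' @export
monomialCount <- function(p, maxDegree = 3L) {
  sum(vapply(seq_len(maxDegree), function(d) choose(p + d - 1, d), numeric(1)))
}

#' Kennard-Stone maximin Euclidean partition
#'
#' Picks the two mutually most distant rows, then iteratively adds the row
#' with the largest minimal Euclidean distance to the selected set, until
#' \code{ceiling(trainFrac * n)} training rows are chosen. Deterministic
#' for a fixed matrix; ties break toward the lowest row index.
#'
#' @param x numeric matrix of predictors.
#' @param trainFrac training fraction (default 0.70).
#' @return list with sorted integer vectors \code{train} and \code{test}.
#' @export
partitionEuclidean <- function(x, trainFrac = 0.70) {
  n <- nrow(x)
  if (n < 4) stop("need at least 4 rows")
  nTrain <- ceiling(trainFrac * n)
  D <- as.matrix(dist(x))
  far <- which(D == max(D), arr.ind = TRUE)[1, ]   # lowest index pair first
  sel <- sort(unname(far))
  minDist <- pmin(D[, sel[1]], D[, sel[2]])
  minDist[sel] <- -Inf
  while (length(sel) < nTrain) {
    nxt <- unname(which.max(minDist))              # ties -> lowest index
    sel <- c(sel, nxt)
    minDist <- pmin(minDist, D[, nxt])
    minDist[nxt] <- -Inf
  }
  list(train = as.integer(sort(sel)),
       test = as.integer(setdiff(seq_len(n), sel)))
}

## ---- network internals -------------------------------------------------

mlfnPack <- function(w1, b1, w2, b2) c(as.numeric(w1), b1, as.numeric(w2), b2)

mlfnUnpack <- function(w, nodes, k) {
  i <- 0L
  w1 <- matrix(w[i + seq_len(nodes * k)], nodes, k); i <- i + nodes * k
  b1 <- w[i + seq_len(nodes)]; i <- i + nodes
  w2 <- matrix(w[i + seq_len(2 * nodes)], 2, nodes); i <- i + 2 * nodes
  b2 <- w[i + 1:2]
  list(w1 = w1, b1 = b1, w2 = w2, b2 = b2)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

mlfnForward <- function(par, x) {
  h <- sigmoid(sweep(x %*% t(par$w1), 2, par$b1, "+"))
  z2 <- sweep(h %*% t(par$w2), 2, par$b2, "+")
  z2 <- z2 - apply(z2, 1, max)
  e <- exp(z2)
  p <- e / rowSums(e)
  list(h = h, p = p)
}

## Objective beta*SSE + alpha*||w||^2 and its analytic gradient.
mlfnObjGrad <- function(w, x, tmat, nodes, k, alpha, beta) {
  par <- mlfnUnpack(w, nodes, k)
  fw <- mlfnForward(par, x)
  r <- tmat - fw$p
  ed <- sum(r^2)
  f <- beta * ed + alpha * sum(w^2)
  q <- -2 * r                                  # dED/dP
  dz2 <- fw$p * (q - rowSums(q * fw$p))        # softmax jacobian applied
  gw2 <- t(dz2) %*% fw$h
  gb2 <- colSums(dz2)
  dh <- dz2 %*% par$w2
  dz1 <- dh * fw$h * (1 - fw$h)
  gw1 <- t(dz1) %*% x
  gb1 <- colSums(dz1)
  g <- beta * mlfnPack(gw1, gb1, gw2, gb2) + 2 * alpha * w
  list(f = f, g = g, ed = ed)
}

## Stacked Gauss-Newton Jacobian of the two softmax outputs w.r.t. all
## weights, one pair of rows per sample.
mlfnJacobian <- function(par, x) {
  n <- nrow(x); nodes <- nrow(par$w1); k <- ncol(par$w1)
  nw <- nodes * k + nodes + 2 * nodes + 2
  fw <- mlfnForward(par, x)
  J <- matrix(0, 2 * n, nw)
  for (i in seq_len(n)) {
    p <- fw$p[i, ]; h <- fw$h[i, ]
    S <- diag(p) - tcrossprod(p)               # dP/dz2
    U <- (S %*% par$w2) * rep(h * (1 - h), each = 2)  # 2 x nodes
    rows <- (2 * i - 2) + 1:2
    J[rows, seq_len(nodes * k)] <- kronecker(t(x[i, ]), U)
    J[rows, nodes * k + seq_len(nodes)] <- U
    J[rows, nodes * k + nodes + seq_len(2 * nodes)] <-
      kronecker(t(h), S)
    J[rows, nodes * k + nodes + 2 * nodes + 1:2] <- S
  }
  J
}

#' Train the shallow feed-forward classifier with Bayesian regularization
#'
#' Single hidden layer of sigmoid nodes and a 2-way softmax output. The
#' cost is \code{beta * SSE + alpha * ||w||^2}; after each optimization
#' cycle the hyperparameters are re-estimated with the evidence framework
#' (effective number of parameters gamma from the Gauss-Newton Hessian).
#' When the Hessian is ill-conditioned the current (alpha, beta) are kept
#' as a fixed weight decay and this is noted in the training log.
#'
#' @param x feature matrix (rows = observations), already standardized.
#' @param y binary response (1 = bloated).
#' @param nodes hidden nodes (default 9).
#' @param maxIter total optimization iterations across cycles (default
#'   500).
#' @param gradTol stop when the gradient norm falls below this (default
#'   1e-10).
#' @param seed RNG seed for the weight initialization.
#' @param evidenceCycles number of (alpha, beta) re-estimations.
#' @return an [MlfnModel-class]; non-convergence gives a warning and an
#'   unconverged flag, never an error.
#' @export
trainMlfn <- function(x, y, nodes = 9L, maxIter = 500L, gradTol = 1e-10,
                      seed = 1L, evidenceCycles = 3L, alpha0 = 0.01,
                      beta0 = 1) {
  stopifnot(is.matrix(x), nrow(x) == length(y), all(y %in% c(0, 1)))
  k <- ncol(x); n <- nrow(x)
  tmat <- cbind(1 - y, y)
  nw <- nodes * k + nodes + 2 * nodes + 2
  w <- withSeed(seed, rnorm(nw, 0, 0.1))
  alpha <- alpha0; beta <- beta0
  logRec <- list(cycles = list(), fallback = FALSE)
  itersLeft <- maxIter
  gradNorm <- Inf
  perCycle <- max(25L, ceiling(maxIter / max(1L, evidenceCycles + 1L)))
  repeat {
    it <- min(perCycle, itersLeft)
    opt <- optim(w, fn = function(wv)
      mlfnObjGrad(wv, x, tmat, nodes, k, alpha, beta)$f,
      gr = function(wv) mlfnObjGrad(wv, x, tmat, nodes, k, alpha, beta)$g,
      method = "BFGS",
      control = list(maxit = it, reltol = 1e-14))
    w <- opt$par
    itersLeft <- itersLeft - it
    og <- mlfnObjGrad(w, x, tmat, nodes, k, alpha, beta)
    gradNorm <- sqrt(sum(og$g^2))
    if (length(logRec$cycles) < evidenceCycles && itersLeft > 0) {
      par <- mlfnUnpack(w, nodes, k)
      ew <- sum(w^2)
      upd <- tryCatch({
        J <- mlfnJacobian(par, x)
        Hm <- 2 * beta * crossprod(J) + diag(2 * alpha, nw)
        trInv <- sum(diag(chol2inv(chol(Hm))))
        gamma <- nw - 2 * alpha * trInv
        gamma <- clamp(gamma, 1e-3, nw - 1e-3)
        list(alpha = gamma / (2 * max(ew, 1e-12)),
             beta = (2 * n - gamma) / (2 * max(og$ed, 1e-12)),
             gamma = gamma)
      }, error = function(e) NULL)
      if (is.null(upd)) {
        logRec$fallback <- TRUE
      } else {
        alpha <- upd$alpha; beta <- upd$beta
        logRec$cycles[[length(logRec$cycles) + 1L]] <-
          list(alpha = alpha, beta = beta, gamma = upd$gamma, ed = og$ed)
        next
      }
    }
    if (gradNorm < gradTol || itersLeft <= 0) break
  }
  converged <- gradNorm < gradTol || isTRUE(abs(gradNorm) < 1e-4)
  if (!converged)
    warning("MLFN training did not reach the gradient tolerance (|g| = ",
            format(gradNorm, digits = 3), ")")
  par <- mlfnUnpack(w, nodes, k)
  logRec$gradNorm <- gradNorm
  logRec$iterUsed <- maxIter - itersLeft
  new("MlfnModel", w1 = par$w1, b1 = par$b1, w2 = par$w2, b2 = par$b2,
      featureNames = colnames(x) %||% paste0("f", seq_len(k)),
      alpha = alpha, beta = beta, converged = converged, log = logRec)
}

#' @rdname trainMlfn
#' @param model a trained [MlfnModel-class].
#' @return \code{predictMlfn}: list with \code{prob} (P(bloated)) and
#'   \code{class} (0/1).
#' @export
predictMlfn <- function(model, x) {
  par <- list(w1 = model@w1, b1 = model@b1, w2 = model@w2, b2 = model@b2)
  p <- mlfnForward(par, x)$p[, 2]
  list(prob = p, class = as.integer(p >= 0.5))
}

#' Select the feature count by cross-validated RMS error
#'
#' For each candidate k the first k feature columns (frozen enumeration
#' order) are used; the cross-validated RMS error between the binary target
#' and the predicted bloated probability is recorded and the k with minimal
#' CV RMS is returned together with the full curve.
#'
#' @param xexp expanded feature matrix (a [FeatureBlock-class] or matrix).
#' @param y binary response.
#' @param ks candidate feature counts.
#' @param cvFolds folds (default 5).
#' @param seed RNG seed for fold assignment and inits.
#' @param nodes,maxIter passed to the (reduced) inner trainer.
#' @return list with \code{kStar} and \code{curve} (data.frame k, rms).
#' @export
selectFeatureCount <- function(xexp, y, ks, cvFolds = 5L, seed = 1L,
                               nodes = 9L, maxIter = 60L) {
  xm <- if (is(xexp, "FeatureBlock")) featureMatrix(xexp) else xexp
  stopifnot(all(ks >= 1), all(ks <= ncol(xm)))
  fold <- stratifiedFolds(factor(y), cvFolds, seed)
  rms <- vapply(ks, function(k) {
    errs <- vapply(seq_len(cvFolds), function(f) {
      tr <- fold != f
      m <- suppressWarnings(
        trainMlfn(xm[tr, seq_len(k), drop = FALSE], y[tr], nodes = nodes,
                  maxIter = maxIter, seed = seed + f, evidenceCycles = 1L))
      p <- predictMlfn(m, xm[!tr, seq_len(k), drop = FALSE])$prob
      sqrt(mean((y[!tr] - p)^2))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  list(kStar = ks[which.min(rms)], curve = data.frame(k = ks, rms = rms))
}

#' Binary confusion metrics with the bloated class positive
#'
#' Confusion matrix with targets on rows (bloated first), precision and
#' recall of the bloated class truncated (not rounded) to 3 decimals, the
#' misclassified count and the percentage of bad predictions.
#'
#' @param yTrue,yPred binary vectors (1 = bloated).
#' @export
confusionMetrics <- function(yTrue, yPred) {
  if (!length(yTrue) || length(yTrue) != length(yPred))
    stop("inputs must be non-empty and of equal length")
  lv <- c("bloated", "non_bloated")
  tf <- factor(ifelse(yTrue == 1, lv[1], lv[2]), levels = lv)
  pf <- factor(ifelse(yPred == 1, lv[1], lv[2]), levels = lv)
  cm <- as.matrix(table(target = tf, prediction = pf))
  tp <- cm[1, 1]; fp <- cm[2, 1]; fn <- cm[1, 2]
  trunc3 <- function(v) trunc(v * 1000) / 1000
  mis <- sum(cm) - sum(diag(cm))
  list(confusion = cm,
       precision = trunc3(tp / (tp + fp)),
       recall = trunc3(tp / (tp + fn)),
       precision_raw = tp / (tp + fp),
       recall_raw = tp / (tp + fn),
       misclassified = as.integer(mis),
       pct_bad = 100 * mis / sum(cm),
       n = as.integer(sum(cm)))
}

#' Misclassification breakdown over the intermediate coverage interval
#'
#' Splits the misclassified observations into those whose bloated coverage
#' lies in the intermediate interval (default 20-80\%) and those in the
#' extreme intervals, reporting the share of misclassifications falling in
#' the intermediate interval and the error rates inside/outside it.
#'
#' @param bloatedPct bloated coverage of every observation.
#' @param misclassified logical, same length.
#' @param interval intermediate interval bounds.
#' @export
misclassificationBreakdown <- function(bloatedPct, misclassified,
                                       interval = c(20, 80)) {
  stopifnot(length(bloatedPct) == length(misclassified))
  mid <- bloatedPct >= interval[1] & bloatedPct <= interval[2]
  nMis <- sum(misclassified)
  list(n = length(bloatedPct),
       n_mid = sum(mid),
       n_misclassified = nMis,
       mid_share_of_misclassified_pct = 100 * sum(misclassified & mid) / nMis,
       mid_error_pct = 100 * sum(misclassified & mid) / sum(mid),
       outside_error_pct =
         100 * sum(misclassified & !mid) / sum(!mid))
}

#' Feature importance from the hidden-weight matrix
#'
#' The importance of feature j is the maximum absolute hidden weight over
#' the nodes, \code{max_m |W1[m, j]|}; features are ranked descending with
#' ties broken by column index.
#'
#' @param model a trained [MlfnModel-class].
#' @param topN how many features to return (default 15).
#' @return data.frame(rank, column, feature, importance).
#' @export
featureImportance <- function(model, topN = 15L) {
  imp <- apply(abs(model@w1), 2, max)
  ord <- order(-imp, seq_along(imp))
  top <- head(ord, topN)
  data.frame(rank = seq_along(top), column = top,
             feature = model@featureNames[top], importance = imp[top])
}

#' Sigmoid activation profile of a variable against bloated coverage
#'
#' Observations are sorted by increasing bloated coverage; the standardized
#' variable is smoothed with a centered moving average, mapped through the
#' logistic function, and correlated (Pearson) with the sorted coverage
#' curve. A variable with no variance after smoothing is flagged instead
#' of returning a correlation.
#'
#' @param bloatedPct bloated coverage values.
#' @param variable paired covariate values.
#' @param smoothWindow moving-average window (odd; default 25).
#' @return list(r, p, n, flat).
#' @export
sigmoidProfile <- function(bloatedPct, variable, smoothWindow = 25L) {
  ok <- is.finite(bloatedPct) & is.finite(variable)
  b <- bloatedPct[ok]; v <- variable[ok]
  if (length(b) < 3) stop("need at least 3 paired finite observations")
  o <- order(b)
  b <- b[o]; v <- v[o]
  if (sd(v) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(b), flat = TRUE))
  v <- (v - mean(v)) / sd(v)
  halfw <- max(1L, smoothWindow %/% 2L)
  n <- length(v)
  sm <- vapply(seq_len(n), function(i)
    mean(v[max(1, i - halfw):min(n, i + halfw)]), numeric(1))
  if (sd(sm) == 0 || sd(b) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, flat = TRUE))
  ct <- cor.test(sigmoid(sm), b)
  list(r = unname(ct$estimate), p = ct$p.value, n = n, flat = FALSE)
}
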