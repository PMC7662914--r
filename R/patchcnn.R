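## Patch classifier: build / train / predict. The numerical engine (im2col
## convolutions, pooling, dropout, softmax and their gradients) lives in
## src/cnn.cpp; this file owns weight initialization, the Adam optimizer and
## the epoch loop with on-the-fly augmentation.

#' Describe the patch classifier architecture
#'
#' The default mirrors the six-conv-layer design used for the coral frames:
#' three blocks of two 3x3 ReLU convolutions (32-32, 64-64, 128-128
#' channels), each block closed by a 2x2 max-pool and dropout 0.25; then a
#' dense ReLU layer of 512 units with dropout 0.5 and a 4-way softmax.
#' With "same" convolutions a 30-pixel patch shrinks 30 -> 15 -> 7 -> 3
#' through the three pools before flattening. Widths are configurable so
#' that small fixture problems can use a lighter network of the same shape.
#'
#' @param convBlocks list of integer pairs; output channels of the two
#'   convolutions in each block.
#' @param denseUnits width of the dense layer.
#' @param blockDropout dropout rate after each block.
#' @param denseDropout dropout rate after the dense layer.
#' @param inputShape patch dimensions, \code{c(side, side, 3)}.
#' @param nClasses number of output classes (4: three statuses plus
#'   background).
#' @export
cnnSpec <- function(convBlocks = list(c(32L, 32L), c(64L, 64L), c(128L, 128L)),
                    denseUnits = 512L, blockDropout = 0.25,
                    denseDropout = 0.5, inputShape = c(30L, 30L, 3L),
                    nClasses = 4L) {
  stopifnot(length(inputShape) == 3L, inputShape[1] == inputShape[2],
            inputShape[3] == 3L, nClasses >= 2L,
            all(vapply(convBlocks, length, integer(1)) == 2L))
  side <- inputShape[1]
  for (b in seq_along(convBlocks)) side <- side %/% 2L
  if (side < 1L) stop("too many blocks for this input size")
  list(convBlocks = convBlocks, denseUnits = as.integer(denseUnits),
       blockDropout = rep(blockDropout, length.out = length(convBlocks)),
       denseDropout = denseDropout, inputShape = as.integer(inputShape),
       nClasses = as.integer(nClasses))
}

cnnMeta <- function(spec) {
  list(nBlocks = length(spec$convBlocks),
       blockDrop = as.numeric(spec$blockDropout),
       denseDrop = spec$denseDropout,
       inputSide = spec$inputShape[1])
}

## Spatial side after the pools.
cnnFlatSide <- function(spec) {
  side <- spec$inputShape[1]
  for (b in seq_along(spec$convBlocks)) side <- side %/% 2L
  side
}

#' Build an untrained patch classifier
#'
#' He-normal initialization for the ReLU layers and scaled-normal for the
#' softmax layer; the same seed reproduces the same initial forward pass.
#'
#' @param spec a [cnnSpec()].
#' @param seed RNG seed for the weight draw.
#' @return a [PatchCnn-class].
#' @export
buildPatchCnn <- function(spec = cnnSpec(), seed = 1L) {
  channels <- unlist(spec$convBlocks)
  cin <- c(spec$inputShape[3], channels[-length(channels)])
  weights <- withSeed(seed, {
    conv <- lapply(seq_along(channels), function(l) {
      fanIn <- 9L * cin[l]
      list(W = matrix(rnorm(channels[l] * fanIn, 0, sqrt(2 / fanIn)),
                      channels[l], fanIn),
           b = rep(0, channels[l]))
    })
    flat <- cnnFlatSide(spec)^2 * channels[length(channels)]
    list(conv = conv,
         dense1 = list(W = matrix(rnorm(spec$denseUnits * flat, 0,
                                        sqrt(2 / flat)),
                                  spec$denseUnits, flat),
                       b = rep(0, spec$denseUnits)),
         dense2 = list(W = matrix(rnorm(spec$nClasses * spec$denseUnits, 0,
                                        sqrt(1 / spec$denseUnits)),
                                  spec$nClasses, spec$denseUnits),
                       b = rep(0, spec$nClasses)))
  })
  new("PatchCnn", spec = spec, weights = weights,
      classLevels = STATUS_LEVELS[seq_len(spec$nClasses)],
      trained = FALSE, history = numeric(0))
}

## Walk the nested weight structure applying f(w, g) leaf-wise.
mapWeights <- function(w, g, f) {
  w$conv <- lapply(seq_along(w$conv), function(l)
    list(W = f(w$conv[[l]]$W, g$conv[[l]]$W),
         b = f(w$conv[[l]]$b, g$conv[[l]]$b)))
  for (nm in c("dense1", "dense2"))
    w[[nm]] <- list(W = f(w[[nm]]$W, g[[nm]]$W), b = f(w[[nm]]$b, g[[nm]]$b))
  w
}

zeroLike <- function(w) mapWeights(w, w, function(a, b) a * 0)

#' Train the patch classifier
#'
#' Mini-batch Adam on categorical cross-entropy. Augmentation (random
#' flips and up to 10\% translations) is applied per batch, on the fly.
#' Determinism is same-seed, same-build: shuffling, augmentation and dropout
#' all derive from \code{seed}.
#'
#' @param model a [PatchCnn-class].
#' @param patchset a [LabeledPatchSet-class] with at least two classes
#'   present.
#' @param epochs,batchSize,lr,beta1,beta2 optimizer settings (defaults: 100
#'   epochs, batch 256, Adam 1e-4 / 0.9 / 0.999).
#' @param augment apply random flips/shifts to each training batch.
#' @param shiftFrac maximum translation fraction for augmentation.
#' @param seed RNG seed.
#' @return the trained model, with per-epoch mean loss in its history.
#' @export
trainPatchCnn <- function(model, patchset, epochs = 100L, batchSize = 256L,
                          lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                          augment = TRUE, shiftFrac = 0.1, seed = 1L) {
  stopifnot(is(model, "PatchCnn"), is(patchset, "LabeledPatchSet"),
            lr > 0, batchSize >= 1)
  y <- patchLabels(patchset)
  present <- table(y)
  if (sum(present > 0) < 2L)
    warning("fewer than 2 classes present in the training data; ",
            "the classifier will degenerate to the constant class")
  absent <- names(present)[present == 0]
  if (length(absent) && sum(present > 0) >= 2L)
    warning("classes absent from training data: ",
            paste(absent, collapse = ", "))
  arr <- patches(patchset)
  n <- dim(arr)[1]
  ycode <- as.integer(y) - 1L
  meta <- cnnMeta(model@spec)
  w <- model@weights
  mState <- zeroLike(w); vState <- zeroLike(w)
  tGlobal <- 0L
  history <- numeric(epochs)
  eps <- 1e-8
  withSeed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (b0 in seq(1, n, by = batchSize)) {
        idx <- ord[b0:min(b0 + batchSize - 1L, n)]
        xb <- arr[idx, , , , drop = FALSE]
        if (augment) {
          augSeed <- sample.int(2^30, 1L)
          xb <- augmentPatches(xb, flips = TRUE, shiftFrac = shiftFrac,
                               seed = augSeed)
        }
        dropSeed <- sample.int(2^30, 1L)
        res <- cnn_grad(w, as.numeric(xb),
                        c(length(idx), dim(xb)[2]), ycode[idx], meta,
                        dropSeed)
        losses <- c(losses, res$loss)
        tGlobal <- tGlobal + 1L
        g <- res$grads
        mState <- mapWeights(mState, g, function(m, gr)
          beta1 * m + (1 - beta1) * gr)
        vState <- mapWeights(vState, g, function(v, gr)
          beta2 * v + (1 - beta2) * gr^2)
        corr1 <- 1 - beta1^tGlobal; corr2 <- 1 - beta2^tGlobal
        upd <- mapWeights(mState, vState, function(m, v)
          lr * (m / corr1) / (sqrt(v / corr2) + eps))
        w <- mapWeights(w, upd, function(wt, u) wt - u)
      }
      history[ep] <- mean(losses)
    }
  })
  model@weights <- w
  model@trained <- TRUE
  model@history <- c(model@history, history)
  model
}

#' Classify patches
#'
#' @param model a trained [PatchCnn-class].
#' @param x a [LabeledPatchSet-class] or bare N x s x s x 3 array.
#' @param chunk samples per forward chunk (memory control).
#' @return N x nClasses matrix of softmax probabilities, columns named by
#'   class.
#' @export
predictPatchCnn <- function(model, x, chunk = 1024L) {
  arr <- if (is(x, "LabeledPatchSet")) patches(x) else x
  stopifnot(length(dim(arr)) == 4L)
  n <- dim(arr)[1]
  meta <- cnnMeta(model@spec)
  out <- matrix(0, n, model@spec$nClasses,
                dimnames = list(NULL, model@classLevels))
  for (b0 in seq(1, n, by = chunk)) {
    idx <- b0:min(b0 + chunk - 1L, n)
    xb <- arr[idx, , , , drop = FALSE]
    out[idx, ] <- cnn_forward(model@weights, as.numeric(xb),
                              c(length(idx), dim(xb)[2]), meta,
                              FALSE, 0L)
  }
  out
}
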