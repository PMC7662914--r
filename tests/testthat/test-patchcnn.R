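test_that("the built network outputs a probability simplex of width 4", {
  spec <- fixtureCnnSpec()
  m <- buildPatchCnn(spec, seed = 2)
  set.seed(1)
  x <- array(runif(3 * 30 * 30 * 3, 0, 255), c(3, 30, 30, 3))
  p <- predictPatchCnn(m, x)
  expect_equal(ncol(p), 4)
  expect_lt(max(abs(rowSums(p) - 1)), 1e-6)
  expect_true(all(p >= 0))
  ## same seed -> identical initial forward pass; different seed -> not
  p2 <- predictPatchCnn(buildPatchCnn(spec, seed = 2), x)
  expect_identical(p, p2)
  p3 <- predictPatchCnn(buildPatchCnn(spec, seed = 3), x)
  expect_false(identical(p, p3))
})

test_that("analytic conv-net gradients agree with finite differences", {
  spec <- cnnSpec(convBlocks = list(c(2L, 2L), c(3L, 3L)), denseUnits = 5L,
                  blockDropout = 0, denseDropout = 0,
                  inputShape = c(12L, 12L, 3L))
  m <- buildPatchCnn(spec, seed = 42)
  set.seed(1)
  x <- array(runif(2 * 12 * 12 * 3, 0, 255), c(2, 12, 12, 3))
  y <- c(0L, 2L)
  meta <- coralrhythm:::cnnMeta(spec)
  g <- coralrhythm:::cnn_grad(m@weights, as.numeric(x), c(2L, 12L), y,
                              meta, 7L)
  eps <- 1e-5
  probeRel <- function(setter, ana) {
    w2 <- setter(m@weights, eps)
    lossUp <- coralrhythm:::cnn_grad(w2, as.numeric(x), c(2L, 12L), y,
                                     meta, 7L)$loss
    abs((lossUp - g$loss) / eps - ana) / max(1e-8, abs(ana))
  }
  r1 <- probeRel(function(w, e) { w$conv[[1]]$W[3] <- w$conv[[1]]$W[3] + e; w },
                 g$grads$conv[[1]]$W[3])
  r2 <- probeRel(function(w, e) { w$conv[[4]]$W[10] <- w$conv[[4]]$W[10] + e; w },
                 g$grads$conv[[4]]$W[10])
  r3 <- probeRel(function(w, e) { w$dense1$W[17] <- w$dense1$W[17] + e; w },
                 g$grads$dense1$W[17])
  r4 <- probeRel(function(w, e) { w$dense2$b[1] <- w$dense2$b[1] + e; w },
                 g$grads$dense2$b[1])
  expect_lt(max(r1, r2, r3, r4), 1e-3)
})

test_that("training reduces the loss and fits the fixture patches", {
  m <- fixtureTrainedModel()
  expect_length(m@history, 10)
  expect_lt(tail(m@history, 1), m@history[1])
  rep <- evaluatePatchCnn(m, fixturePatchData()$patchset)
  expect_gte(rep@accuracy, 0.9)
})

test_that("degenerate class composition triggers the warning path", {
  ps <- fixturePatchData()$patchset
  only <- subsetPatchSet(ps, which(patchLabels(ps) == "bloated")[1:16])
  m <- buildPatchCnn(fixtureCnnSpec(), seed = 1)
  expect_warning(trainPatchCnn(m, only, epochs = 1, batchSize = 16),
                 "fewer than 2 classes")
})

test_that("stratified folds partition the data and preserve class ratios", {
  ps <- fixturePatchData()$patchset
  y <- patchLabels(ps)
  k <- 10L
  fold <- stratifiedFolds(y, k, seed = 4)
  ## disjoint cover by construction of a single assignment vector
  expect_equal(sort(unique(fold)), 1:10)
  expect_equal(length(fold), length(y))
  sizes <- table(fold)
  expect_lte(max(sizes) - min(sizes), length(levels(droplevels(y))))
  for (f in 1:10) {
    inFold <- table(y[fold == f])
    expected <- table(y) / k
    expect_true(all(abs(inFold - expected) <= 1))
  }
  expect_error(stratifiedFolds(factor(rep(c("a", "b"), c(30, 4))), 10),
               "at least k")
})

test_that("cross-validation on fixtures reaches the expected reduced-run accuracy", {
  ps <- fixturePatchData()$patchset
  cv <- crossValidatePatchCnn(ps, fixtureCnnSpec(), k = 5, seed = 2,
                              epochs = 3, batchSize = 16, lr = 3e-3,
                              augment = FALSE)
  expect_length(cv$reports, 5)
  sizes <- table(cv$folds)
  expect_lte(max(sizes) - min(sizes), 4)
  expect_gte(cv$meanAccuracy, 0.8)
  expect_true(all(vapply(cv$reports, function(r) sum(r@confusion),
                         numeric(1)) == as.vector(sizes)))
})

test_that("evaluation reproduces hand-computable confusion arithmetic", {
  ## perfect predictions
  truth <- factor(rep(c("background", "bloated"), each = 10),
                  levels = levels(patchLabels(fixturePatchData()$patchset)))
  probs <- matrix(0, 20, 4, dimnames = list(NULL, levels(truth)))
  probs[cbind(seq_len(20), as.integer(truth))] <- 1
  r <- evalReport(truth, probs)
  expect_equal(r@accuracy, 1)
  expect_true(all(r@pa[c(1, 2)] == 1))
  expect_equal(r@auc, 1)
  ## the printed two-class test matrix: rows (223, 70) and (86, 124)
  t2 <- factor(rep(c("bloated", "non_bloated"), c(293, 210)),
               levels = c("bloated", "non_bloated"))
  p2 <- factor(c(rep("bloated", 223), rep("non_bloated", 70),
                 rep("bloated", 86), rep("non_bloated", 124)),
               levels = c("bloated", "non_bloated"))
  r2 <- evalReport(t2, pred = p2)
  expect_equal(r2@accuracy, (223 + 124) / 503)
  expect_equal(unname(r2@pa["bloated"]), 223 / 293)
  expect_equal(unname(r2@ua["bloated"]), 223 / 309)
})

test_that("random scores give chance-level AUC and agree with an external AUC", {
  set.seed(21)
  n <- 2000
  truth <- factor(sample(c("a", "b"), n, TRUE), levels = c("a", "b"))
  score <- runif(n)
  auc <- coralrhythm:::aucBinary(score, truth == "a")
  expect_lt(abs(auc - 0.5), 0.05)
  skip_if_not_installed("pROC")
  ## cross-check the rank AUC against an independent implementation
  set.seed(22)
  sepScore <- rnorm(n, mean = ifelse(truth == "a", 1, 0))
  ours <- coralrhythm:::aucBinary(sepScore, truth == "a")
  ref <- as.numeric(pROC::auc(pROC::roc(response = truth == "a",
                                        predictor = sepScore,
                                        quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})
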