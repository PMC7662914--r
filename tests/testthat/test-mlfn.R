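test_that("binarization implements the >= 50 rule and validates its domain", {
  expect_identical(binarizeBloated(50), 1L)
  expect_identical(binarizeBloated(49.999), 0L)
  expect_identical(binarizeBloated(100), 1L)
  expect_identical(binarizeBloated(c(0, 50, 75)), c(0L, 1L, 1L))
  expect_error(binarizeBloated(101), "0, 100")
  expect_error(binarizeBloated(NA_real_), "finite")
})

test_that("feature expansion matches brute-force enumeration for 2-7 columns", {
  ## independent oracle: enumerate unique sorted tuples via expand.grid
  bruteCount <- function(p, dmax) {
    tot <- 0
    for (d in seq_len(dmax)) {
      gr <- do.call(expand.grid, rep(list(seq_len(p)), d))
      keys <- unique(apply(gr, 1, function(r) paste(sort(r), collapse = ",")))
      tot <- tot + length(keys)
    }
    tot
  }
  for (p in 2:7) {
    x <- matrix(rnorm(5 * p), 5, p,
                dimnames = list(NULL, paste0("v", seq_len(p))))
    fb <- expandFeatures(x, 3L, binaryCols = character(0))
    expect_equal(ncol(featureMatrix(fb)), bruteCount(p, 3))
    expect_equal(ncol(featureMatrix(fb)), monomialCount(p, 3))
  }
})

test_that("the seven-column degree-3 expansion has 119 monomials and frozen order", {
  nm <- c("hour_frac", "chlorophyll", "temperature", "depth", "turbidity",
          "salinity", "fov")
  x <- matrix(rnorm(20 * 7), 20, 7, dimnames = list(NULL, nm))
  fb <- expandFeatures(x, 3L, binaryCols = character(0))
  expect_equal(ncol(featureMatrix(fb)), 119)
  ## degree-ascending: the first 7 columns are the base variables
  expect_identical(colnames(featureMatrix(fb))[1:7], nm)
  degs <- vapply(provenance(fb), length, integer(1))
  expect_true(!is.unsorted(degs))
  ## provenance column reproduces the elementwise product
  i <- which(colnames(featureMatrix(fb)) == "temperature^2")
  expect_equal(featureMatrix(fb)[, i], x[, "temperature"]^2)
})

test_that("binary dummy powers collapse and are de-duplicated", {
  nm <- c("a", "b", "fov")
  x <- cbind(a = rnorm(15), b = rnorm(15),
             fov = as.numeric(runif(15) > 0.5))
  fb <- expandFeatures(x, 3L, binaryCols = "fov")
  cn <- colnames(featureMatrix(fb))
  expect_false(any(grepl("fov\\^", cn)))
  ## fov appears once as a monomial and in products without powers
  expect_true("fov" %in% cn)
  expect_true("a*fov" %in% cn)
  ## count: 19 full enumeration minus duplicates (fov^2, fov^3, a*fov^2,
  ## b*fov^2) = 15
  expect_equal(ncol(featureMatrix(fb)), monomialCount(3, 3) - 4)
  expect_error(expandFeatures(cbind(a = c(1, NA)), 2), "finite")
})

test_that("standardization is fit on train and applied to test without leakage", {
  set.seed(3)
  x <- cbind(u = rnorm(50, 5, 2), v = rnorm(50, -3, 4),
             fov = as.numeric(runif(50) > 0.5))
  tr <- 1:35; te <- 36:50
  std <- standardizeBlock(x[tr, ])
  stdT <- standardizeBlock(x[te, ], center = std$center, scale = std$scale)
  expect_lt(max(abs(colMeans(std$x[, c("u", "v")]))), 1e-9)
  expect_equal(unname(apply(std$x[, c("u", "v")], 2, sd)), c(1, 1))
  ## test block uses the train parameters, so its means are not exactly 0
  expect_gt(max(abs(colMeans(stdT$x[, c("u", "v")]))), 1e-9)
  expect_identical(std$x[, "fov"], x[tr, "fov"])
})

test_that("the maximin partition picks diagonal corners and is deterministic", {
  sq <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)
  pt <- partitionEuclidean(sq, 0.5)
  ## brute-force maximin: the two selected points must be a diagonal
  expect_equal(dist(sq[pt$train, ])[1], sqrt(2))
  set.seed(9)
  x <- matrix(rnorm(60), 20, 3)
  p1 <- partitionEuclidean(x, 0.7)
  p2 <- partitionEuclidean(x, 0.7)
  expect_identical(p1, p2)
  expect_equal(length(p1$train), ceiling(0.7 * 20))
  expect_equal(sort(c(p1$train, p1$test)), 1:20)
  ## duplicate rows tolerated
  xd <- rbind(x, x[1, , drop = FALSE])
  expect_silent(partitionEuclidean(xd, 0.5))
})

test_that("the network drives training error to near zero on separable data", {
  set.seed(5)
  n <- 200
  x <- cbind(f1 = rnorm(n), f2 = rnorm(n))
  y <- as.integer(x[, 1] + x[, 2] > 0)
  m <- suppressWarnings(trainMlfn(x, y, nodes = 4, maxIter = 300, seed = 1))
  pr <- predictMlfn(m, x)$class
  expect_lte(mean(pr != y), 0.01)
  ## constant response gives the constant-class model
  m0 <- suppressWarnings(trainMlfn(x, rep(1L, n), nodes = 3, maxIter = 50,
                                   seed = 1))
  expect_true(all(predictMlfn(m0, x)$class == 1L))
})

test_that("MLFN recovery approaches the Bayes limit of the generating process", {
  rec <- mlfnRecoveryData(1000, seed = 12)
  m <- suppressWarnings(trainMlfn(rec$xTrain[, 1:10, drop = FALSE],
                                  rec$y[rec$part$train],
                                  maxIter = 300, seed = 2))
  pr <- predictMlfn(m, rec$xTest[, 1:10, drop = FALSE])$class
  cm <- confusionMetrics(rec$y[rec$part$test], pr)
  ## the Bernoulli labels put the Bayes-optimal P and R near 0.82; a
  ## correct implementation must land within reach of that ceiling
  expect_gte(cm$precision_raw, 0.70)
  expect_gte(cm$recall_raw, 0.70)
})

test_that("the CV-RMS curve identifies that the informative features come first", {
  set.seed(6)
  n <- 300
  x <- matrix(rnorm(n * 12), n, 12,
              dimnames = list(NULL, paste0("f", 1:12)))
  ## response generated from the first 3 enumerated features
  y <- as.integer(x[, 1] + 2 * x[, 2] - x[, 3] +
                    rnorm(n, 0, 0.3) > 0)
  sel <- selectFeatureCount(x, y, ks = c(1, 2, 3, 6, 12), cvFolds = 3,
                            seed = 2, nodes = 4, maxIter = 40)
  expect_true(all(is.finite(sel$curve$rms)))
  expect_true(all(sel$curve$rms >= 0))
  expect_gte(sel$kStar, 3)
  ## the curve improves from 1 feature to 3 features
  expect_lt(sel$curve$rms[sel$curve$k == 3],
            sel$curve$rms[sel$curve$k == 1])
  ## a single candidate is returned as-is
  expect_equal(selectFeatureCount(x, y, ks = 4, cvFolds = 3, seed = 1,
                                  nodes = 3, maxIter = 20)$kStar, 4)
})

test_that("confusion metrics reproduce the printed contingency arithmetic", {
  ## reconstruct labels from the printed matrix (223, 70 / 86, 124)
  yTrue <- rep(c(1, 1, 0, 0), c(223, 70, 86, 124))
  yPred <- rep(c(1, 0, 1, 0), c(223, 70, 86, 124))
  cm <- confusionMetrics(yTrue, yPred)
  expect_equal(cm$precision, 0.721)
  expect_equal(cm$recall, 0.761)
  expect_equal(cm$misclassified, 156L)
  expect_equal(cm$pct_bad, 100 * 156 / 503)
  expect_equal(unname(cm$confusion[1, ]), c(223, 70))
  ## perfect and degenerate predictions
  p <- confusionMetrics(c(1, 0, 1), c(1, 0, 1))
  expect_equal(c(p$precision, p$recall, p$pct_bad), c(1, 1, 0))
  allPos <- confusionMetrics(c(1, 0, 0, 1), c(1, 1, 1, 1))
  expect_equal(allPos$recall, 1)
  expect_equal(allPos$precision_raw, 0.5)  # prevalence
  expect_error(confusionMetrics(numeric(0), numeric(0)), "non-empty")
})

test_that("feature importance ranks by max absolute hidden weight with stable ties", {
  w1 <- rbind(c(0, 1, 0.5), c(0, -2, 0.5))
  m <- new("MlfnModel", w1 = w1, b1 = c(0, 0),
           w2 = matrix(0, 2, 2), b2 = c(0, 0),
           featureNames = c("zero", "big", "mid"),
           alpha = 1, beta = 1, converged = TRUE, log = list())
  imp <- featureImportance(m, 3)
  expect_equal(imp$feature, c("big", "mid", "zero"))
  expect_equal(imp$importance, c(2, 0.5, 0))
  ## identity-like weights: all equal, ties broken by column index
  mId <- new("MlfnModel", w1 = diag(3), b1 = rep(0, 3),
             w2 = matrix(0, 2, 3), b2 = c(0, 0),
             featureNames = c("a", "b", "c"),
             alpha = 1, beta = 1, converged = TRUE, log = list())
  expect_equal(featureImportance(mId, 3)$column, 1:3)
})

test_that("informative monomials surface in the importance top-5 under noise", {
  set.seed(31)
  hits <- 0L
  for (s in 1:10) {
    n <- 250
    x <- matrix(rnorm(n * 33), n, 33,
                dimnames = list(NULL, c("s1", "s2", "s3",
                                        paste0("n", 1:30))))
    y <- as.integer(2 * x[, 1] - 1.5 * x[, 2] + x[, 3] +
                      rnorm(n, 0, 0.5) > 0)
    m <- suppressWarnings(trainMlfn(x, y, nodes = 5, maxIter = 150,
                                    seed = s))
    top5 <- featureImportance(m, 5)$feature
    if (sum(c("s1", "s2", "s3") %in% top5) >= 2) hits <- hits + 1L
  }
  expect_gte(hits, 6)  # majority over 10 seeds
})

test_that("sigmoid profiles detect monotone association and flag flat variables", {
  set.seed(13)
  b <- runif(400, 0, 100)
  selfP <- sigmoidProfile(b, b)
  expect_gte(selfP$r, 0.99)
  antiP <- sigmoidProfile(b, -b)
  expect_lte(antiP$r, -0.99)
  flat <- sigmoidProfile(b, rep(1, 400))
  expect_true(flat$flat)
  expect_true(is.na(flat$r))
  ## null behavior: independent noise rarely correlates strongly
  cnt <- 0L
  for (s in 1:50) {
    set.seed(100 + s)
    r <- sigmoidProfile(b, rnorm(400))$r
    if (abs(r) < 0.5) cnt <- cnt + 1L
  }
  expect_gte(cnt, 45)
})
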