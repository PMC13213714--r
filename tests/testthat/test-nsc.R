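# Independent brute-force oracle: plain nearest-centroid with the same
# standardization and prior term, computed with explicit loops.
.bruteNearestCentroid <- function(X, y, Xnew) {
  y <- factor(y)
  classes <- levels(y); n <- nrow(X); K <- length(classes)
  cent <- sapply(classes, function(k) colMeans(X[y == k, , drop = FALSE]))
  ss <- rep(0, ncol(X))
  for (k in classes)
    ss <- ss + colSums(sweep(X[y == k, , drop = FALSE], 2, cent[, k])^2)
  s <- sqrt(ss / (n - K)); s0 <- median(s)
  pri <- as.numeric(table(y)) / n
  pred <- character(nrow(Xnew))
  for (i in seq_len(nrow(Xnew))) {
    d <- vapply(seq_len(K), function(k)
      sum((Xnew[i, ] - cent[, k])^2 / (s + s0)^2) - 2 * log(pri[k]),
      numeric(1))
    pred[i] <- classes[which.min(d)]
  }
  pred
}

.gaussianFixture <- function(n = 100, p = 20, informative = 5, sep = 4,
                             seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n * p), 2 * n, p)
  X[(n + 1):(2 * n), seq_len(informative)] <-
    X[(n + 1):(2 * n), seq_len(informative)] + sep
  colnames(X) <- paste0("f", seq_len(p))
  rownames(X) <- paste0("s", seq_len(2 * n))
  list(X = X, y = factor(rep(c("a", "b"), each = n)))
}

test_that("delta = 0 reproduces brute-force standardized nearest centroid", {
  set.seed(3)
  fx <- .gaussianFixture(n = 30, p = 10, seed = 3)
  Xnew <- matrix(rnorm(40 * 10), 40, 10, dimnames = list(NULL, paste0("f", 1:10)))
  model <- nscFit(fx$X, fx$y, deltaGrid = 0)
  expect_equal(model@shrunkenCentroids, model@classCentroids,
               tolerance = 1e-12)
  pred <- nscPredict(model, Xnew)
  expect_identical(pred$label, .bruteNearestCentroid(fx$X, fx$y, Xnew))
})

test_that("full shrinkage collapses to the prior-only rule", {
  fx <- .gaussianFixture(n = 20, p = 8, seed = 5)
  y <- factor(c(rep("a", 30), rep("b", 10)))  # unequal priors
  X <- fx$X[1:40, ]
  st <- MutSigSubtypes:::.nscStats(X, y)
  model <- nscFit(X, y, deltaGrid = max(abs(st$dik)) + 1)
  expect_equal(model@shrunkenCentroids[, "a"], model@overallCentroid,
               tolerance = 1e-12)
  expect_equal(model@shrunkenCentroids[, "b"], model@overallCentroid,
               tolerance = 1e-12)
  pred <- nscPredict(model, matrix(rnorm(50 * 8), 50, 8,
                                   dimnames = list(NULL, colnames(X))))
  expect_true(all(pred$label == "a"))  # arg-max prior
})

test_that("surviving-feature count is non-increasing in delta", {
  fx <- .gaussianFixture(n = 40, p = 15, seed = 7)
  st <- MutSigSubtypes:::.nscStats(fx$X, fx$y)
  grid <- seq(0, max(abs(st$dik)) * 1.1, length.out = 12)
  nSurv <- vapply(grid, function(d) {
    m <- nscFit(fx$X, fx$y, deltaGrid = d)
    length(survivingFeatures(m))
  }, integer(1))
  expect_true(all(diff(nSurv) <= 0))
})

test_that("planted 5-of-20 structure: high held-out accuracy, nulls shrunk away", {
  fx <- .gaussianFixture(n = 100, p = 20, informative = 5, sep = 4, seed = 11)
  te <- .gaussianFixture(n = 100, p = 20, informative = 5, sep = 4, seed = 12)
  model <- nscFit(fx$X, fx$y, cvFolds = 10, seed = 2)
  pred <- nscPredict(model, te$X)
  expect_gte(mean(pred$label == as.character(te$y)), 0.95)
  nulls <- paste0("f", 6:20)
  expect_gte(sum(!nulls %in% survivingFeatures(model)), 10)
})

test_that("posteriors sum to 1 and ties break to the first class", {
  fx <- .gaussianFixture(n = 20, p = 6, seed = 9)
  model <- nscFit(fx$X, fx$y, deltaGrid = 0, priors = "uniform")
  pred <- nscPredict(model, fx$X)
  expect_equal(pred$posterior.a + pred$posterior.b, rep(1, nrow(fx$X)),
               tolerance = 1e-12)
  # a sample exactly midway between the two centroids: posterior 0.5/0.5,
  # label = first class
  mid <- matrix((model@shrunkenCentroids[, 1] + model@shrunkenCentroids[, 2]) / 2,
                1, dimnames = list("mid", model@featureNames))
  p <- nscPredict(model, mid)
  expect_equal(p$posterior.a, 0.5, tolerance = 1e-10)
  expect_identical(p$label, "a")
  # a sample at a shrunken centroid is assigned to that class
  at <- matrix(model@shrunkenCentroids[, "b"], 1,
               dimnames = list("at", model@featureNames))
  expect_identical(nscPredict(model, at)$label, "b")
})

test_that("prediction is invariant under consistent feature permutation", {
  fx <- .gaussianFixture(n = 30, p = 10, seed = 13)
  model <- nscFit(fx$X, fx$y, deltaGrid = 0.5)
  Xnew <- fx$X[1:10, ]
  perm <- sample(ncol(Xnew))
  expect_identical(nscPredict(model, Xnew)$label,
                   nscPredict(model, Xnew[, perm])$label)
})

test_that("feature misalignment errors; extra features warn", {
  fx <- .gaussianFixture(n = 20, p = 6, seed = 15)
  model <- nscFit(fx$X, fx$y, deltaGrid = 0)
  expect_error(nscPredict(model, fx$X[, -1]), "f1")
  Xplus <- cbind(fx$X, extra = rnorm(nrow(fx$X)))
  expect_warning(nscPredict(model, Xplus), "unknown")
})

test_that("the published m_k variant is available behind the flag", {
  fx <- .gaussianFixture(n = 30, p = 8, seed = 17)
  m1 <- nscFit(fx$X, fx$y, deltaGrid = 0, mCorrection = "pamr")
  m2 <- nscFit(fx$X, fx$y, deltaGrid = 0, mCorrection = "published")
  n <- nrow(fx$X); nk <- n / 2
  expect_equal(unname(m1@mk), rep(sqrt(1 / nk - 1 / n), 2), tolerance = 1e-12)
  expect_equal(unname(m2@mk), rep(sqrt(1 / nk + 1 / n), 2), tolerance = 1e-12)
})

test_that("NSC model JSON round-trips and predicts identically", {
  fx <- .gaussianFixture(n = 30, p = 8, seed = 19)
  model <- nscFit(fx$X, fx$y, cvFolds = 5, seed = 1)
  p <- tempfile(fileext = ".json")
  writeNscModel(model, p)
  back <- readNscModel(p)
  expect_equal(nscPredict(back, fx$X), nscPredict(model, fx$X),
               tolerance = 1e-12)
})

test_that("rank-based AUC matches brute-force pair counting", {
  expect_equal(rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(rocAuc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  # brute force over all positive-negative pairs, ties scoring 1/2
  set.seed(21)
  sc <- sample(1:5, 40, TRUE); tr <- rbinom(40, 1, 0.5)
  pairSum <- 0
  for (i in which(tr == 1)) for (j in which(tr == 0))
    pairSum <- pairSum + (sc[i] > sc[j]) + 0.5 * (sc[i] == sc[j])
  expect_equal(rocAuc(sc, tr), pairSum / (sum(tr == 1) * sum(tr == 0)),
               tolerance = 1e-12)
  # independent scores: AUC near 1/2
  set.seed(22)
  expect_lt(abs(rocAuc(rnorm(4000), rbinom(4000, 1, 0.5)) - 0.5), 0.05)
  expect_error(rocAuc(1:4, c(1, 1, 1, 1)), "both classes")
})
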