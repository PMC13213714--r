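.nscStats <- function(X, y, mCorrection = "pamr") {
  classes <- levels(y)
  n <- nrow(X); K <- length(classes)
  nk <- table(y)
  overall <- colMeans(X)
  cent <- vapply(classes, function(k) colMeans(X[y == k, , drop = FALSE]),
                 numeric(ncol(X)))
  ss <- 0
  for (k in classes) {
    Xi <- X[y == k, , drop = FALSE]
    ss <- ss + colSums(sweep(Xi, 2, cent[, k])^2)
  }
  s <- sqrt(ss / (n - K))
  s0 <- stats::median(s)
  mk <- if (mCorrection == "published") sqrt(1 / nk + 1 / n)
        else sqrt(pmax(1 / nk - 1 / n, 0))
  dik <- sweep(cent - overall, 1, s + s0, "/")
  dik <- sweep(dik, 2, as.numeric(mk), "/")
  list(overall = overall, cent = cent, s = s, s0 = s0,
       mk = stats::setNames(as.numeric(mk), classes), dik = dik,
       nk = nk, classes = classes)
}

.nscShrink <- function(st, delta) {
  dshr <- sign(st$dik) * pmax(abs(st$dik) - delta, 0)
  shr <- st$overall +
    sweep(sweep(dshr, 2, st$mk, "*"), 1, st$s + st$s0, "*")
  list(dshr = dshr, centroids = shr)
}

.nscScore <- function(Xnew, centroids, s, s0, priors) {
  K <- ncol(centroids)
  delta <- matrix(0, nrow(Xnew), K, dimnames = list(rownames(Xnew),
                                                    colnames(centroids)))
  for (k in seq_len(K)) {
    delta[, k] <- colSums((t(Xnew) - centroids[, k])^2 / (s + s0)^2) -
      2 * log(priors[k])
  }
  delta
}

#' Fit a nearest-shrunken-centroid (PAM) classifier
#'
#' Standardized class contrasts `d_ik = (xbar_ik - xbar_i) / (m_k (s_i + s0))`
#' are soft-thresholded by the shrinkage Delta, and the class centroids are
#' reconstructed from the surviving contrasts. Delta is chosen by stratified
#' cross-validation using the one-standard-error rule: the largest Delta whose
#' CV error is within one SE of the minimum (the most parsimonious model that
#' is statistically indistinguishable from the best).
#'
#' @param X samples x features numeric matrix with feature column names.
#' @param y class labels (2 or more classes, each with >= 2 samples); the
#'   first level is the tie-break winner at prediction time.
#' @param deltaGrid shrinkage values to evaluate; default 30 values from 0 to
#'   `max |d_ik|`.
#' @param cvFolds stratified folds (default 10; capped at the smallest class
#'   size so no fold loses a class).
#' @param seed RNG seed for fold assignment.
#' @param mCorrection `"pamr"` uses `m_k = sqrt(1/n_k - 1/n)` (the reference
#'   implementation); `"published"` uses `sqrt(1/n_k + 1/n)`.
#' @param priors `"class"` (training proportions) or `"uniform"`, or a named
#'   numeric vector.
#' @return a [ShrunkenCentroids-class].
#' @export
nscFit <- function(X, y, deltaGrid = NULL, cvFolds = 10, seed = 1L,
                   mCorrection = c("pamr", "published"),
                   priors = c("class", "uniform")) {
  mCorrection <- match.arg(mCorrection)
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("features must be finite")
  y <- factor(y)
  if (nlevels(y) < 2) stop("need >= 2 classes")
  if (any(table(y) < 2)) stop("every class needs >= 2 samples")
  st <- .nscStats(X, y, mCorrection)
  if (is.character(priors)) {
    priors <- match.arg(priors)
    pri <- if (priors == "uniform")
      stats::setNames(rep(1 / nlevels(y), nlevels(y)), levels(y))
    else stats::setNames(as.numeric(st$nk) / nrow(X), levels(y))
  } else pri <- priors[levels(y)]
  if (is.null(deltaGrid))
    deltaGrid <- seq(0, max(abs(st$dik)), length.out = 30)
  cvCurve <- data.frame(delta = numeric(), error = numeric(), se = numeric())
  chosen <- 0
  if (length(deltaGrid) > 1) {
    folds <- .stratifiedFolds(y, cvFolds, seed)
    nf <- max(folds)
    errMat <- matrix(NA_real_, nf, length(deltaGrid))
    for (f in seq_len(nf)) {
      tr <- folds != f
      if (nlevels(droplevels(y[tr])) < nlevels(y))
        stop("a class vanished from a CV training fold; reduce cvFolds")
      stf <- .nscStats(X[tr, , drop = FALSE], droplevels(y[tr]), mCorrection)
      prf <- stats::setNames(as.numeric(stf$nk) / sum(tr), stf$classes)
      if (is.numeric(priors)) prf <- pri
      for (d in seq_along(deltaGrid)) {
        sh <- .nscShrink(stf, deltaGrid[d])
        sc <- .nscScore(X[!tr, , drop = FALSE], sh$centroids, stf$s, stf$s0, prf)
        pred <- stf$classes[max.col(-sc, ties.method = "first")]
        errMat[f, d] <- mean(pred != as.character(y[!tr]))
      }
    }
    err <- colMeans(errMat)
    se <- apply(errMat, 2, stats::sd) / sqrt(nf)
    cvCurve <- data.frame(delta = deltaGrid, error = err, se = se)
    best <- which.min(err)
    ok <- which(err <= err[best] + se[best])
    chosen <- deltaGrid[max(ok)]
  } else chosen <- deltaGrid[1]
  sh <- .nscShrink(st, chosen)
  new("ShrunkenCentroids",
      featureNames = colnames(X), overallCentroid = st$overall,
      classCentroids = st$cent, shrunkenCentroids = sh$centroids,
      s = unname(st$s), s0 = st$s0, mk = st$mk, delta = chosen,
      priors = pri, classes = levels(y), cvCurve = cvCurve,
      mCorrection = mCorrection)
}

.stratifiedFolds <- function(y, nFolds, seed) {
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old), add = TRUE)
  set.seed(seed)
  nFolds <- min(nFolds, min(table(y)))
  folds <- integer(length(y))
  for (k in levels(y)) {
    idx <- sample(which(y == k))
    folds[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  folds
}

#' Predict subtypes with a fitted shrunken-centroid model
#'
#' Discriminant score `delta_k(x) = sum_i (x_i - xbar'_ik)^2 / (s_i + s0)^2 -
#' 2 log pi_k`; the predicted label is the arg-min (ties to the first class)
#' and posteriors are the softmax of `-delta_k / 2`.
#'
#' @param model a [ShrunkenCentroids-class].
#' @param Xnew samples x features matrix; features aligned by name. Missing
#'   model features are an error; extra columns are dropped with a warning.
#' @return data.frame: sample_id, label, one `posterior.<class>` and one
#'   `score.<class>` column per class.
#' @export
nscPredict <- function(model, Xnew) {
  Xnew <- as.matrix(Xnew)
  if (any(!is.finite(Xnew))) stop("features must be finite")
  missing <- setdiff(model@featureNames, colnames(Xnew))
  if (length(missing))
    stop("new data lacks model feature(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  extra <- setdiff(colnames(Xnew), model@featureNames)
  if (length(extra))
    warning("ignoring ", length(extra), " feature(s) unknown to the model")
  Xnew <- Xnew[, model@featureNames, drop = FALSE]
  sc <- .nscScore(Xnew, model@shrunkenCentroids, model@s, model@s0,
                  model@priors)
  lab <- model@classes[max.col(-sc, ties.method = "first")]
  lp <- -sc / 2
  post <- exp(lp - apply(lp, 1, max))
  post <- post / rowSums(post)
  out <- data.frame(
    sample_id = if (!is.null(rownames(Xnew))) rownames(Xnew)
                else as.character(seq_len(nrow(Xnew))),
    label = lab, stringsAsFactors = FALSE)
  for (k in seq_along(model@classes)) {
    out[[paste0("posterior.", model@classes[k])]] <- post[, k]
    out[[paste0("score.", model@classes[k])]] <- sc[, k]
  }
  out
}

#' @describeIn nscFit features with nonzero class contrast at the fitted
#'   shrinkage (the features the classifier actually uses).
#' @param model a ShrunkenCentroids model.
#' @export
survivingFeatures <- function(model) {
  contrast <- model@shrunkenCentroids - model@overallCentroid
  model@featureNames[rowSums(abs(contrast)) > 1e-12]
}

setMethod("show", "ShrunkenCentroids", function(object) {
  cat("ShrunkenCentroids:", length(object@classes), "classes (",
      paste(object@classes, collapse = ", "), "), delta =",
      signif(object@delta, 4), "\n  ", length(survivingFeatures(object)),
      "of", length(object@featureNames), "features survive shrinkage\n")
})

#' Serialize / restore a shrunken-centroid model as JSON
#' @param model a [ShrunkenCentroids-class].
#' @param path JSON path.
#' @export
writeNscModel <- function(model, path) {
  obj <- list(featureNames = model@featureNames,
              overallCentroid = model@overallCentroid,
              classCentroids = model@classCentroids,
              shrunkenCentroids = model@shrunkenCentroids,
              s = model@s, s0 = model@s0, mk = model@mk,
              delta = model@delta, priors = model@priors,
              classes = model@classes, cvCurve = model@cvCurve,
              mCorrection = model@mCorrection)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "columnmajor")
  invisible(path)
}

#' @rdname writeNscModel
#' @export
readNscModel <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  dimn <- list(o$featureNames, o$classes)
  # column-major serialization comes back with one row per original column
  cc <- matrix(t(o$classCentroids), ncol = length(o$classes), dimnames = dimn)
  shc <- matrix(t(o$shrunkenCentroids), ncol = length(o$classes),
                dimnames = dimn)
  new("ShrunkenCentroids", featureNames = o$featureNames,
      overallCentroid = stats::setNames(o$overallCentroid, o$featureNames),
      classCentroids = cc, shrunkenCentroids = shc,
      s = o$s, s0 = o$s0, mk = stats::setNames(o$mk, o$classes),
      delta = o$delta, priors = stats::setNames(unlist(o$priors), o$classes),
      classes = o$classes,
      cvCurve = if (is.data.frame(o$cvCurve)) o$cvCurve else
        data.frame(delta = numeric(), error = numeric(), se = numeric()),
      mCorrection = o$mCorrection)
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney AUC of a continuous score against binary truth; ties handled
#' by midranks.
#'
#' @param scores numeric scores (higher = more positive).
#' @param truth binary truth (0/1, logical, or 2-level factor with the second
#'   level positive).
#' @return AUC in [0, 1].
#' @export
#' @examples
#' rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
rocAuc <- function(scores, truth) {
  if (is.factor(truth)) truth <- as.integer(truth) - 1L
  truth <- as.integer(as.logical(truth) | truth == 1)
  if (length(unique(truth)) < 2)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores)
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
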