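#' Non-negative matrix factorization by multiplicative updates
#'
#' Minimizes the Frobenius loss `||V - W H||^2_F` with Lee-Seung
#' multiplicative updates from a seeded uniform random initialization. A small
#' epsilon (1e-12) in the denominators guards against division by zero, which
#' keeps the per-iteration objective non-increasing.
#'
#' @param V nonnegative numeric matrix (no NA rows; samples x features here).
#' @param k factorization rank, `2 <= k < min(dim(V))` (k = 1 allowed for
#'   rank-1 checks).
#' @param maxIter iteration cap (default 2000).
#' @param tol stop when the relative objective change drops below this
#'   (default 1e-6).
#' @param seed RNG seed for the initialization.
#' @return an [NMFFit-class].
#' @export
nmfFactorize <- function(V, k, maxIter = 2000, tol = 1e-6, seed = 1L) {
  V <- as.matrix(V)
  if (any(!is.finite(V))) stop("V must be finite (no NA/NaN/Inf entries)")
  if (any(V < 0)) stop("V must be nonnegative")
  if (k >= min(dim(V)) && k > 1)
    stop("rank k must be below min(dim(V)) = ", min(dim(V)))
  eps <- 1e-12
  n <- nrow(V); m <- ncol(V)
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old), add = TRUE)
  set.seed(seed)
  scale <- sqrt(mean(V) / k + eps)
  W <- matrix(stats::runif(n * k), n, k) * scale
  H <- matrix(stats::runif(k * m), k, m) * scale
  obj <- numeric(0)
  prev <- Inf
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    H <- H * (crossprod(W, V)) / (crossprod(W) %*% H + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    cur <- sum((V - W %*% H)^2)
    obj <- c(obj, cur)
    if (is.finite(prev) && abs(prev - cur) <= tol * (prev + eps)) {
      converged <- TRUE
      break
    }
    prev <- cur
  }
  rownames(W) <- rownames(V); colnames(H) <- colnames(V)
  new("NMFFit", W = W, H = H, k = as.integer(k), objective = obj,
      seed = as.integer(seed), converged = converged)
}

.Random.seed.save <- function()
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
.Random.seed.restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Hard clusters from an NMF fit
#'
#' Arg-max over each row of W; ties break toward the lower cluster index.
#' @param fit an [NMFFit-class].
#' @return integer cluster per sample.
#' @export
nmfClusters <- function(fit) max.col(fit@W, ties.method = "first")

#' Consensus clustering over repeated NMF runs
#'
#' For each candidate rank, runs seeded NMF restarts, derives hard clusters by
#' arg-max over W rows, averages the run connectivity matrices into a
#' consensus matrix, and scores rank stability by the cophenetic coefficient:
#' the correlation between the consensus distance (1 - consensus) and the
#' cophenetic distances of its average-linkage dendrogram. Runs that put every
#' sample in one cluster are discarded with a warning.
#'
#' @param V nonnegative samples x features matrix.
#' @param kRange candidate ranks (default 2:6).
#' @param nRuns restarts per rank (default 50).
#' @param seed base seed; run r at rank k uses seed + 1000 * k + r.
#' @param maxIter,tol passed to [nmfFactorize()].
#' @return a [ConsensusClustering-class]; `selectedK` is the rank with the
#'   highest cophenetic coefficient (pipelines may still force k = 2, the
#'   working rank for the MUT1/MUT2 split, and report this diagnostic).
#' @export
consensusCluster <- function(V, kRange = 2:6, nRuns = 50, seed = 1L,
                             maxIter = 500, tol = 1e-5) {
  V <- as.matrix(V)
  if (nRuns < 2) stop("nRuns must be >= 2")
  n <- nrow(V)
  consensus <- list(); coph <- numeric(0); kept <- integer(0)
  for (k in kRange) {
    Csum <- matrix(0, n, n)
    good <- 0L
    for (r in seq_len(nRuns)) {
      fit <- nmfFactorize(V, k, maxIter = maxIter, tol = tol,
                          seed = seed + 1000L * k + r)
      cl <- nmfClusters(fit)
      if (length(unique(cl)) < 2L) {
        warning("discarding degenerate run (all samples in one cluster) at k = ", k)
        next
      }
      Csum <- Csum + outer(cl, cl, "==")
      good <- good + 1L
    }
    if (good == 0L) stop("all runs degenerate at k = ", k)
    C <- Csum / good
    diag(C) <- 1
    dimnames(C) <- list(rownames(V), rownames(V))
    d <- stats::as.dist(1 - C)
    cc <- if (stats::sd(d) == 0) 1 else
      stats::cor(d, stats::cophenetic(stats::hclust(d, method = "average")))
    consensus[[as.character(k)]] <- C
    coph <- c(coph, stats::setNames(cc, k))
    kept <- c(kept, good)
  }
  new("ConsensusClustering", consensus = consensus, cophenetic = coph,
      kRange = as.integer(kRange),
      selectedK = as.integer(kRange[which.max(coph)]),
      nRuns = as.integer(nRuns), runsKept = kept)
}

#' @describeIn consensusCluster consensus matrix at rank k.
#' @param x a ConsensusClustering.
#' @param k rank.
#' @export
consensusMatrix <- function(x, k = x@selectedK) x@consensus[[as.character(k)]]

#' @describeIn consensusCluster cophenetic coefficient per rank.
#' @export
copheneticCoefficients <- function(x) x@cophenetic

setMethod("show", "ConsensusClustering", function(object) {
  cat("ConsensusClustering over k in {",
      paste(object@kRange, collapse = ", "), "}; selected k =",
      object@selectedK, "\n  cophenetic:",
      paste(sprintf("%s: %.3f", names(object@cophenetic), object@cophenetic),
            collapse = "  "), "\n")
})

#' Label two clusters as MUT1 / MUT2 by APOBEC anchoring
#'
#' The cluster with the higher mean cosine similarity over the APOBEC
#' signatures (SBS2/SBS13 by default) is labeled MUT1; the other MUT2. When no
#' anchor signature is present in the CS matrix, labeling falls back to the
#' mismatch-repair set (SBS6/SBS15) with the rule inverted (higher MMR
#' similarity means MUT2), with a loud warning.
#'
#' @param clusters integer vector of cluster indices (exactly 2 distinct),
#'   named by sample.
#' @param cs a [CSMatrix-class] covering the same samples.
#' @param apobecSignatures anchor set, default `c("SBS2", "SBS13")`.
#' @param fallbackSignatures inverted-anchor set used when no APOBEC signature
#'   is available, default `c("SBS6", "SBS15")`.
#' @return named character vector of labels in {MUT1, MUT2}.
#' @export
assignSubtypeLabels <- function(clusters, cs,
                                apobecSignatures = c("SBS2", "SBS13"),
                                fallbackSignatures = c("SBS6", "SBS15")) {
  ids <- sort(unique(clusters))
  if (length(ids) != 2) stop("exactly 2 clusters required")
  v <- csValues(cs)[names(clusters), , drop = FALSE]
  anchors <- intersect(apobecSignatures, colnames(v))
  invert <- FALSE
  if (!length(anchors)) {
    anchors <- intersect(fallbackSignatures, colnames(v))
    if (!length(anchors))
      stop("neither APOBEC nor fallback anchor signatures present in CS matrix")
    invert <- TRUE
    warning("no APOBEC anchor signature retained; labeling via inverted ",
            "fallback anchors: ", paste(anchors, collapse = ", "))
  }
  meanCS <- vapply(ids, function(g)
    mean(v[clusters == g, anchors, drop = FALSE]), numeric(1))
  mut1 <- if (invert) ids[which.min(meanCS)] else ids[which.max(meanCS)]
  stats::setNames(ifelse(clusters == mut1, "MUT1", "MUT2"), names(clusters))
}

#' Discover MUT1/MUT2 subtypes from a cosine-similarity matrix
#'
#' End-to-end discovery: subsets the CS matrix to the retained signatures,
#' drops undefined samples, runs consensus diagnostics over `kRange`, fits the
#' final NMF at the working rank (k = 2 by default, the two-subtype solution),
#' derives hard clusters, and anchors the MUT1/MUT2 labels on APOBEC
#' similarity. Membership strength is the max-normalized W row entry.
#'
#' @param cs a [CSMatrix-class].
#' @param retained a [RetainedSignatures-class] (or character vector of
#'   signature names to use).
#' @param k working rank (default 2).
#' @param kRange ranks for the stability diagnostic (default `2:6`).
#' @param nRuns consensus restarts per rank.
#' @param seed base seed.
#' @param apobecSignatures passed to [assignSubtypeLabels()].
#' @return a [SubtypeCall-class]; both labels are guaranteed nonempty.
#' @export
discoverSubtypes <- function(cs, retained, k = 2, kRange = 2:6, nRuns = 50,
                             seed = 1L, apobecSignatures = c("SBS2", "SBS13")) {
  keep <- if (is(retained, "RetainedSignatures")) retainedNames(retained)
          else as.character(retained)
  v <- csValues(cs)[!cs@undefined, keep, drop = FALSE]
  if (length(und <- undefinedSamples(cs)))
    message("excluding ", length(und), " zero-spectrum sample(s) from clustering")
  cons <- consensusCluster(v, kRange = kRange, nRuns = nRuns, seed = seed)
  fit <- nmfFactorize(v, k, seed = seed)
  cl <- stats::setNames(nmfClusters(fit), rownames(v))
  if (length(unique(cl)) < 2)
    stop("discovery produced a single cluster; both subtypes must be nonempty")
  csSub <- new("CSMatrix", values = csValues(cs)[!cs@undefined, , drop = FALSE],
               undefined = rep(FALSE, sum(!cs@undefined)))
  labels <- assignSubtypeLabels(cl, csSub, apobecSignatures = apobecSignatures)
  membership <- fit@W[cbind(seq_len(nrow(fit@W)), cl)] / rowSums(fit@W)
  new("SubtypeCall",
      assignment = data.frame(sample_id = rownames(v),
                              label = unname(labels),
                              cluster = unname(cl),
                              membership = unname(membership),
                              stringsAsFactors = FALSE),
      consensus = cons, fit = fit, apobecSignatures = apobecSignatures)
}

#' @describeIn discoverSubtypes per-sample assignment data.frame.
#' @param x a SubtypeCall.
#' @export
subtypeAssignment <- function(x) x@assignment

#' @describeIn discoverSubtypes named character vector of labels.
#' @export
subtypeLabels <- function(x)
  stats::setNames(x@assignment$label, x@assignment$sample_id)

setMethod("show", "SubtypeCall", function(object) {
  tab <- table(object@assignment$label)
  cat("SubtypeCall:", nrow(object@assignment), "samples (",
      paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")\n")
  cat("  cophenetic at working rank:",
      sprintf("%.3f", object@consensus@cophenetic[as.character(object@fit@k)]),
      "\n")
})
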