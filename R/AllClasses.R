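#' @import methods
NULL

#' Reference SBS signature set
#'
#' A set of single-base-substitution (SBS) signatures: a channels x signatures
#' nonnegative matrix whose columns are probability vectors over the 96
#' pyrimidine-referenced trinucleotide channels. Columns are renormalized on
#' construction when they do not sum to one.
#'
#' @slot channels character vector of channel labels (canonical order).
#' @slot signatures numeric matrix, channels x S, column names are signature
#'   names (e.g. "SBS2"); every column sums to 1.
#' @export
setClass("SignatureSet",
  representation(channels = "character", signatures = "matrix"))

setValidity("SignatureSet", function(object) {
  m <- object@signatures
  if (!is.numeric(m)) return("signature matrix must be numeric")
  if (nrow(m) != length(object@channels))
    return("channel labels and matrix rows differ in length")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    return("signature names must be present and unique")
  if (ncol(m) < 2) return("at least 2 signatures required")
  if (any(!is.finite(m)) || any(m < 0))
    return("signature entries must be finite and nonnegative")
  cs <- colSums(m)
  if (any(abs(cs - 1) > 1e-6))
    return("signature columns must sum to 1 (tolerance 1e-6)")
  TRUE
})

#' Cosine-similarity matrix between sample spectra and reference signatures
#'
#' Samples x signatures matrix of cosine similarities in [0, 1]. Samples whose
#' spectrum was all-zero have no defined cosine; they are flagged in
#' `undefined` and their rows are NA, never silently zero.
#'
#' @slot values numeric matrix, samples x signatures.
#' @slot undefined logical vector (one per sample): TRUE where the sample had
#'   a zero spectrum and the row is undefined.
#' @export
setClass("CSMatrix",
  representation(values = "matrix", undefined = "logical"))

setValidity("CSMatrix", function(object) {
  v <- object@values
  if (length(object@undefined) != nrow(v))
    return("undefined flag length must equal number of samples")
  ok <- !object@undefined
  if (any(v[ok, , drop = FALSE] < -1e-12 | v[ok, , drop = FALSE] > 1 + 1e-12,
          na.rm = TRUE))
    return("cosine values must lie in [0, 1]")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("values must carry sample and signature names")
  TRUE
})

#' Retained-signature filter result
#'
#' Outcome of the prevalence filter on a [CSMatrix]: a signature is retained
#' when the fraction of samples reaching cosine similarity >= `csThreshold`
#' for it is at least `minPrevalence`.
#'
#' @slot signatureNames all signature names, in input order.
#' @slot prevalence fraction of (defined) samples with CS >= csThreshold.
#' @slot retained logical retention flag per signature.
#' @slot csThreshold,minPrevalence thresholds used.
#' @export
setClass("RetainedSignatures",
  representation(signatureNames = "character", prevalence = "numeric",
                 retained = "logical", csThreshold = "numeric",
                 minPrevalence = "numeric"))

setValidity("RetainedSignatures", function(object) {
  n <- length(object@signatureNames)
  if (length(object@prevalence) != n || length(object@retained) != n)
    return("prevalence/retained must match signatureNames in length")
  if (any(object@prevalence < 0 | object@prevalence > 1))
    return("prevalence must lie in [0, 1]")
  TRUE
})

#' Non-negative matrix factorization fit
#'
#' Frobenius-loss NMF `V ~ W H` fitted by multiplicative updates from a seeded
#' uniform random start.
#'
#' @slot W samples x k basis-weight matrix (nonnegative).
#' @slot H k x features coefficient matrix (nonnegative).
#' @slot k factorization rank.
#' @slot objective per-iteration Frobenius loss, non-increasing.
#' @slot seed integer seed used for initialization.
#' @slot converged TRUE if the relative-change tolerance was reached.
#' @export
setClass("NMFFit",
  representation(W = "matrix", H = "matrix", k = "integer",
                 objective = "numeric", seed = "integer",
                 converged = "logical"))

setValidity("NMFFit", function(object) {
  if (any(object@W < 0) || any(object@H < 0))
    return("W and H must be nonnegative")
  if (ncol(object@W) != object@k || nrow(object@H) != object@k)
    return("W/H dimensions inconsistent with k")
  d <- diff(object@objective)
  if (length(d) && any(d > 1e-9 * (abs(object@objective[-length(object@objective)]) + 1)))
    return("objective trace must be non-increasing")
  TRUE
})

#' Consensus clustering of repeated NMF runs
#'
#' For each candidate rank, hard clusters from repeated seeded NMF runs are
#' averaged into a consensus (co-membership) matrix; the cophenetic
#' correlation of the induced consensus distance scores rank stability.
#'
#' @slot consensus list (one per rank) of samples x samples consensus matrices.
#' @slot cophenetic named numeric: cophenetic coefficient per rank.
#' @slot kRange integer ranks evaluated.
#' @slot selectedK rank with the highest cophenetic coefficient.
#' @slot nRuns runs requested per rank.
#' @slot runsKept runs retained per rank after discarding degenerate runs.
#' @export
setClass("ConsensusClustering",
  representation(consensus = "list", cophenetic = "numeric",
                 kRange = "integer", selectedK = "integer",
                 nRuns = "integer", runsKept = "integer"))

setValidity("ConsensusClustering", function(object) {
  for (C in object@consensus) {
    if (!isTRUE(all.equal(C, t(C), tolerance = 1e-12)))
      return("consensus matrices must be symmetric")
    if (any(abs(diag(C) - 1) > 1e-12))
      return("consensus diagonal must be exactly 1")
    if (any(C < 0 | C > 1)) return("consensus entries must lie in [0, 1]")
  }
  TRUE
})

#' Subtype call for a discovery cohort
#'
#' Per-sample MUT1/MUT2 assignment with cluster index and membership strength
#' (max-normalized NMF basis weight), plus the diagnostics that produced it.
#'
#' @slot assignment data.frame: sample_id, label, cluster, membership.
#' @slot consensus the [ConsensusClustering] diagnostics.
#' @slot fit the final [NMFFit] at the working rank.
#' @slot apobecSignatures anchor signatures used for labeling.
#' @export
setClass("SubtypeCall",
  representation(assignment = "data.frame", consensus = "ConsensusClustering",
                 fit = "NMFFit", apobecSignatures = "character"))

setValidity("SubtypeCall", function(object) {
  a <- object@assignment
  need <- c("sample_id", "label", "cluster", "membership")
  if (!all(need %in% names(a)))
    return("assignment must have sample_id, label, cluster, membership")
  if (!all(a$label %in% c("MUT1", "MUT2")))
    return("labels must be MUT1 or MUT2")
  if (anyDuplicated(a$sample_id)) return("each sample labeled exactly once")
  TRUE
})

#' Nearest-shrunken-centroid classifier
#'
#' Class centroids standardized by pooled within-class dispersion are
#' soft-thresholded toward the overall centroid by the shrinkage `delta`;
#' features whose standardized contrast shrinks to zero in every class drop
#' out of the discriminant.
#'
#' @slot featureNames feature (signature) names.
#' @slot overallCentroid,classCentroids raw centroids (features, features x K).
#' @slot shrunkenCentroids features x K shrunken centroids at `delta`.
#' @slot s pooled within-class standard deviation per feature.
#' @slot s0 fudge constant (median of s).
#' @slot mk per-class standardization factor m_k.
#' @slot delta chosen shrinkage.
#' @slot priors class priors (sum to 1).
#' @slot classes class labels, prediction tie-break favors the first.
#' @slot cvCurve data.frame delta/error/se from cross-validation (may be empty).
#' @slot mCorrection "pamr" (sqrt(1/n_k - 1/n)) or "published"
#'   (sqrt(1/n_k + 1/n)).
#' @export
setClass("ShrunkenCentroids",
  representation(featureNames = "character", overallCentroid = "numeric",
                 classCentroids = "matrix", shrunkenCentroids = "matrix",
                 s = "numeric", s0 = "numeric", mk = "numeric",
                 delta = "numeric", priors = "numeric", classes = "character",
                 cvCurve = "data.frame", mCorrection = "character"))

setValidity("ShrunkenCentroids", function(object) {
  if (abs(sum(object@priors) - 1) > 1e-8) return("priors must sum to 1")
  if (any(object@s < 0)) return("pooled dispersions must be nonnegative")
  if (object@delta < 0) return("delta must be nonnegative")
  if (any(object@s > 0) && object@s0 <= 0)
    return("s0 must be positive when any s_i > 0")
  TRUE
})
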