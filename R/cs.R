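#' Cosine similarity of two nonnegative vectors
#'
#' `a . b / (||a|| ||b||)`; scale-invariant, so counts and frequencies give
#' identical results, and bounded in [0, 1] for nonnegative inputs.
#'
#' @param a,b numeric nonnegative vectors of equal length, each with at least
#'   one positive entry.
#' @return similarity in [0, 1].
#' @export
#' @examples
#' cosineSimilarity(c(1, 1, 0), c(1, 0, 0))  # 1/sqrt(2)
cosineSimilarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length")
  if (any(!is.finite(a)) || any(!is.finite(b)) || any(a < 0) || any(b < 0))
    stop("inputs must be finite and nonnegative")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("cosine similarity undefined for a zero vector")
  min(1, sum(a * b) / (na * nb))
}

#' Cosine-similarity matrix between spectra and reference signatures
#'
#' Computes `values[i, j] = cos(spectrum_i, signature_j)` for every sample and
#' signature. Channel labels are aligned by name: the spectrum columns must
#' all exist among the signature set's channels. Samples whose spectrum is
#' all-zero are flagged undefined and get NA rows.
#'
#' @param spectra samples x 96 matrix with channel column names.
#' @param signatures a [SignatureSet-class].
#' @return a [CSMatrix-class].
#' @export
buildCSMatrix <- function(spectra, signatures) {
  off <- setdiff(colnames(spectra), channelLabels(signatures))
  if (length(off) || is.null(colnames(spectra)))
    stop("channel labels do not align with the signature set: ",
         paste(utils::head(off, 3), collapse = ", "))
  sig <- signatureMatrix(signatures)[colnames(spectra), , drop = FALSE]
  zero <- rowSums(spectra) == 0
  num <- spectra %*% sig
  v <- num / (sqrt(rowSums(spectra^2)) %o% sqrt(colSums(sig^2)))
  v <- pmin(v, 1)
  v[zero, ] <- NA_real_
  if (any(zero))
    warning(sum(zero), " zero-count sample(s) flagged undefined: ",
            paste(utils::head(rownames(spectra)[zero], 5), collapse = ", "))
  new("CSMatrix", values = v, undefined = unname(zero))
}

#' @describeIn buildCSMatrix the samples x signatures value matrix.
#' @param x a CSMatrix.
#' @export
csValues <- function(x) x@values

#' @describeIn buildCSMatrix sample ids whose cosine row is undefined.
#' @export
undefinedSamples <- function(x) rownames(x@values)[x@undefined]

setMethod("show", "CSMatrix", function(object) {
  cat("CSMatrix:", nrow(object@values), "samples x", ncol(object@values),
      "signatures;", sum(object@undefined), "undefined sample(s)\n")
})

#' Prevalence filter on the cosine-similarity matrix
#'
#' A signature is retained when the fraction of samples reaching cosine
#' similarity >= `csThreshold` for it is at least `minPrevalence` (both
#' boundaries inclusive). Samples flagged undefined (zero spectra) are
#' excluded from the prevalence denominator.
#'
#' @param cs a [CSMatrix-class].
#' @param csThreshold per-sample similarity threshold (default 0.24).
#' @param minPrevalence minimum fraction of samples attaining it (default
#'   0.10).
#' @return a [RetainedSignatures-class].
#' @export
filterSignatures <- function(cs, csThreshold = 0.24, minPrevalence = 0.10) {
  v <- csValues(cs)[!cs@undefined, , drop = FALSE]
  if (nrow(v) == 0) stop("no samples with defined cosine rows")
  prev <- colMeans(v >= csThreshold)
  keep <- prev >= minPrevalence
  if (!any(keep))
    stop("every signature was filtered out; review csThreshold (",
         csThreshold, ") and minPrevalence (", minPrevalence, ")")
  new("RetainedSignatures", signatureNames = colnames(v),
      prevalence = unname(prev), retained = unname(keep),
      csThreshold = csThreshold, minPrevalence = minPrevalence)
}

#' @describeIn filterSignatures names of retained signatures.
#' @param x a RetainedSignatures object.
#' @export
retainedNames <- function(x) x@signatureNames[x@retained]

#' @describeIn filterSignatures audit table (name, prevalence, retained).
#' @export
retentionTable <- function(x)
  data.frame(signature = x@signatureNames, prevalence = x@prevalence,
             retained = x@retained)

setMethod("show", "RetainedSignatures", function(object) {
  cat("RetainedSignatures:", sum(object@retained), "of",
      length(object@retained), "signatures retained (CS >=",
      object@csThreshold, "in >=", 100 * object@minPrevalence,
      "% of samples)\n")
})
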