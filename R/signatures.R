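#' Construct a SignatureSet
#'
#' @param matrix channels x signatures nonnegative matrix with signature
#'   column names and channel row names (any row order; matched by label).
#' @param channels channel label order to impose; defaults to the canonical
#'   96-channel order.
#' @return a [SignatureSet-class].
#' @export
SignatureSet <- function(matrix, channels = sbsChannels()) {
  if (is.null(rownames(matrix)))
    stop("signature matrix must carry channel row names")
  missing <- setdiff(channels, rownames(matrix))
  if (length(missing))
    stop("signature matrix lacks channel(s): ",
         paste(utils::head(missing, 3), collapse = ", "),
         if (length(missing) > 3) ", ...")
  m <- matrix[channels, , drop = FALSE]
  cs <- colSums(m)
  if (any(abs(cs - 1) > 1e-6)) {
    warning("renormalizing ", sum(abs(cs - 1) > 1e-6),
            " signature column(s) that did not sum to 1")
    m <- sweep(m, 2, cs, "/")
  }
  new("SignatureSet", channels = channels, signatures = m)
}

#' Read a COSMIC-style signature TSV
#'
#' First column: channel label in the `"A[C>A]A"` dialect; remaining columns:
#' one signature each. Rows are matched to the canonical channel order by
#' label, never trusted by position.
#'
#' @param path TSV path.
#' @return a [SignatureSet-class].
#' @export
readSignatureSet <- function(path) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  SignatureSet(m)
}

#' Write a SignatureSet as COSMIC-style TSV
#' @param x a [SignatureSet-class].
#' @param path output path.
#' @export
writeSignatureSet <- function(x, path) {
  df <- data.frame(Type = x@channels, x@signatures, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @describeIn SignatureSet signature names.
#' @param x a SignatureSet.
#' @export
signatureNames <- function(x) colnames(x@signatures)

#' @describeIn SignatureSet channel labels.
#' @export
channelLabels <- function(x) x@channels

#' @describeIn SignatureSet the channels x signatures matrix.
#' @export
signatureMatrix <- function(x) x@signatures

setMethod("show", "SignatureSet", function(object) {
  cat("SignatureSet:", ncol(object@signatures), "signatures x",
      length(object@channels), "channels\n")
  cat("  ", paste(utils::head(signatureNames(object), 8), collapse = ", "),
      if (ncol(object@signatures) > 8) ", ..." else "", "\n", sep = "")
})
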