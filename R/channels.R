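.BASES <- c("A", "C", "G", "T")
.SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Canonical 96 SBS channel labels
#'
#' Channel order is fixed to the COSMIC convention: substitution class major
#' (C>A, C>G, C>T, T>A, T>C, T>G), then 5' flank (A, C, G, T), then 3' flank
#' (A, C, G, T), giving labels like `"A[C>A]A"`.
#'
#' @return character vector of length 96.
#' @export
#' @examples
#' head(sbsChannels())
sbsChannels <- function() {
  unlist(lapply(.SUBS, function(s)
    paste0(rep(.BASES, each = 4), "[", s, "]", rep(.BASES, times = 4))),
    use.names = FALSE)
}

#' Reverse complement of short sequences
#'
#' Vectorized over plain character 3-mers (or any fixed-width DNA strings).
#' @param x character vector over A/C/G/T.
#' @return character vector of reverse complements.
#' @export
reverseComplement3 <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  n <- nchar(comp)
  if (all(n == 3)) {
    paste0(substr(comp, 3, 3), substr(comp, 2, 2), substr(comp, 1, 1))
  } else {
    vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), "")
  }
}

#' Collapse a substitution to its pyrimidine-referenced channel
#'
#' Maps (ref, alt, trinucleotide context) onto the canonical 96-channel index.
#' Purine-reference mutations (ref A or G) are first rewritten as their
#' reverse-complement pyrimidine representation, so every raw class and its
#' reverse complement land on the same channel (an exact 2-to-1 surjection
#' from the 192 raw classes onto the 96 channels).
#'
#' @param ref,alt single reference/alternate bases (vectorized).
#' @param context 3-mer context whose middle base equals `ref`.
#' @return integer channel indices in 1..96 (labels via [sbsChannels()]).
#' @export
#' @examples
#' collapseSubstitution("C", "T", "ACA")  # A[C>T]A
#' collapseSubstitution("G", "A", "TGT")  # same channel by strand symmetry
collapseSubstitution <- function(ref, alt, context) {
  ref <- toupper(ref); alt <- toupper(alt); context <- toupper(context)
  if (any(!ref %in% .BASES) || any(!alt %in% .BASES) ||
      any(!grepl("^[ACGT]{3}$", context)))
    stop("malformed record: ref/alt must be single A/C/G/T and context a 3-mer over A/C/G/T")
  if (any(ref == alt))
    stop("malformed record: ref and alt must differ")
  if (any(substr(context, 2, 2) != ref))
    stop("inconsistent record: context middle base must equal ref")
  flip <- ref %in% c("A", "G")
  if (any(flip)) {
    ref[flip] <- chartr("AG", "TC", ref[flip])
    alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
    context[flip] <- reverseComplement3(context[flip])
  }
  lab <- paste0(substr(context, 1, 1), "[", ref, ">", alt, "]",
                substr(context, 3, 3))
  idx <- match(lab, sbsChannels())
  stopifnot(!anyNA(idx))
  idx
}
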