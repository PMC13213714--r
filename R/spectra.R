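#' @importFrom data.table fread fwrite
NULL

.DEFAULT_MAF_COLUMNS <- c(
  sample = "Tumor_Sample_Barcode",
  chromosome = "Chromosome",
  position = "Start_Position",
  ref = "Reference_Allele",
  alt = "Tumor_Seq_Allele2",
  context = "ref_context"
)

.validateRecords <- function(df, dedupe = TRUE) {
  ref <- toupper(df$ref_allele); alt <- toupper(df$alt_allele)
  singleRef <- nchar(ref) == 1L & ref != "-"
  singleAlt <- nchar(alt) == 1L & alt != "-"
  notSnv <- !(singleRef & singleAlt)
  acgt <- ref %in% .BASES & alt %in% .BASES & ref != alt
  nonAcgt <- !notSnv & !acgt
  keep <- !notSnv & !nonAcgt
  out <- df[keep, , drop = FALSE]
  out$ref_allele <- toupper(out$ref_allele)
  out$alt_allele <- toupper(out$alt_allele)
  nDup <- 0L
  if (dedupe && nrow(out)) {
    key <- paste(out$sample_id, out$chromosome, out$position,
                 out$ref_allele, out$alt_allele, sep = "\r")
    dup <- duplicated(key)
    nDup <- sum(dup)
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  list(records = out,
       skipped = c(not_snv = sum(notSnv), non_acgt = sum(nonAcgt),
                   duplicate = nDup))
}

.resolveContexts <- function(records, fastaPath) {
  fa <- Rsamtools::FaFile(fastaPath)
  if (!file.exists(paste0(fastaPath, ".fai"))) Rsamtools::indexFa(fastaPath)
  gr <- GenomicRanges::GRanges(records$chromosome,
          IRanges::IRanges(records$position - 1L, records$position + 1L))
  ctx <- toupper(as.character(Rsamtools::getSeq(fa, gr)))
  bad <- substr(ctx, 2, 2) != records$ref_allele
  if (any(bad))
    stop("reference FASTA disagrees with ref allele at ",
         sum(bad), " position(s), e.g. ",
         records$chromosome[bad][1], ":", records$position[bad][1])
  ctx
}

#' Read somatic SNVs from a MAF-dialect table
#'
#' Reads a tab-delimited mutation table, keeps only valid single-nucleotide
#' substitutions (single A/C/G/T ref and alt, ref != alt) and returns them
#' with their trinucleotide contexts. Contexts come from a context column if
#' one is present, otherwise from an indexed reference FASTA. Indels, MNVs,
#' ambiguous-base rows and (by default) duplicate records are dropped with
#' per-reason counts returned as metadata.
#'
#' @param path MAF file path (TSV; positions 1-based).
#' @param columnMap named character vector mapping the roles
#'   sample/chromosome/position/ref/alt (and optionally context) to column
#'   names; defaults to the standard MAF names.
#' @param fasta optional reference FASTA path used to look up contexts when
#'   the context column is absent.
#' @param dedupe drop duplicate (sample, chrom, pos, ref, alt) records.
#' @return list with `records` (data.frame: sample_id, chromosome, position,
#'   ref_allele, alt_allele, context) and `skipped` (named counts).
#' @export
readMAF <- function(path, columnMap = .DEFAULT_MAF_COLUMNS, fasta = NULL,
                    dedupe = TRUE) {
  cm <- .DEFAULT_MAF_COLUMNS
  cm[names(columnMap)] <- columnMap
  raw <- data.table::fread(path, sep = "\t", data.table = FALSE,
                           colClasses = list(character = unname(cm["chromosome"])))
  need <- cm[c("sample", "chromosome", "position", "ref", "alt")]
  missing <- setdiff(unname(need), names(raw))
  if (length(missing))
    stop("MAF is missing required column(s): ", paste(missing, collapse = ", "))
  if (nrow(raw) == 0L) {
    warning("MAF contains a header but no records")
    return(list(records = data.frame(sample_id = character(),
                  chromosome = character(), position = integer(),
                  ref_allele = character(), alt_allele = character(),
                  context = character()),
                skipped = c(not_snv = 0L, non_acgt = 0L, duplicate = 0L)))
  }
  df <- data.frame(
    sample_id = as.character(raw[[cm["sample"]]]),
    chromosome = as.character(raw[[cm["chromosome"]]]),
    position = as.integer(raw[[cm["position"]]]),
    ref_allele = as.character(raw[[cm["ref"]]]),
    alt_allele = as.character(raw[[cm["alt"]]]),
    stringsAsFactors = FALSE)
  hasCtx <- cm["context"] %in% names(raw)
  if (hasCtx) df$context <- toupper(as.character(raw[[cm["context"]]]))
  v <- .validateRecords(df, dedupe = dedupe)
  rec <- v$records
  if (!hasCtx) {
    if (is.null(fasta))
      stop("MAF has no context column ('", cm["context"],
           "'); supply `fasta` for context lookup")
    rec$context <- if (nrow(rec)) .resolveContexts(rec, fasta) else character()
  }
  list(records = rec, skipped = v$skipped)
}

#' Read somatic SNVs from a VCF
#'
#' Thin wrapper over `vcfR`: keeps biallelic SNV records, converts them to the
#' same record layout as [readMAF()] (VCF positions are already 1-based) and
#' resolves contexts from a reference FASTA.
#'
#' @param path VCF path (plain or bgzipped).
#' @param sampleId sample identifier to stamp on the records; defaults to the
#'   file name without extension.
#' @param fasta reference FASTA for trinucleotide context lookup.
#' @inheritParams readMAF
#' @return as [readMAF()].
#' @export
readVCFSNVs <- function(path, sampleId = sub("\\.vcf(\\.gz)?$", "", basename(path)),
                        fasta, dedupe = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  df <- data.frame(
    sample_id = sampleId,
    chromosome = as.character(fx[, "CHROM"]),
    position = as.integer(fx[, "POS"]),
    ref_allele = as.character(fx[, "REF"]),
    alt_allele = as.character(fx[, "ALT"]),
    stringsAsFactors = FALSE)
  out <- .validateRecords(df, dedupe = dedupe)
  out$records$context <- if (nrow(out$records))
    .resolveContexts(out$records, fasta) else character()
  out
}

#' Build the samples x 96 mutational spectrum matrix
#'
#' Bins accepted SNV records into the canonical pyrimidine-referenced
#' channels. Row sums equal per-sample record counts; samples listed in
#' `sampleOrder` but absent from the records get all-zero rows with a warning.
#'
#' @param records data.frame as returned by [readMAF()]`$records`.
#' @param sampleOrder optional character vector fixing row order; inferred
#'   (sorted unique sample ids) when NULL.
#' @return integer matrix, samples x 96, with channel column names.
#' @export
buildSpectrumMatrix <- function(records, sampleOrder = NULL) {
  channels <- sbsChannels()
  if (is.null(sampleOrder)) sampleOrder <- sort(unique(records$sample_id))
  if (nrow(records) && !all(records$sample_id %in% sampleOrder))
    stop("records contain sample ids not present in sampleOrder")
  m <- matrix(0L, nrow = length(sampleOrder), ncol = 96L,
              dimnames = list(sampleOrder, channels))
  if (nrow(records)) {
    idx <- collapseSubstitution(records$ref_allele, records$alt_allele,
                                records$context)
    tab <- table(factor(records$sample_id, levels = sampleOrder),
                 factor(idx, levels = seq_len(96L)))
    m[] <- as.integer(tab)
  }
  zero <- rowSums(m) == 0L
  if (any(zero))
    warning("sample(s) with zero accepted SNVs: ",
            paste(sampleOrder[zero], collapse = ", "))
  m
}

#' Write / read a spectrum matrix as TSV
#'
#' Samples x 96 matrix with a `sample_id` first column and canonical channel
#' headers.
#' @param spectra integer matrix from [buildSpectrumMatrix()].
#' @param path output TSV path.
#' @export
writeSpectrumMatrix <- function(spectra, path) {
  df <- data.frame(sample_id = rownames(spectra), spectra,
                   check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname writeSpectrumMatrix
#' @export
readSpectrumMatrix <- function(path) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  missing <- setdiff(sbsChannels(), colnames(m))
  if (length(missing))
    stop("spectrum TSV lacks channel column(s): ",
         paste(utils::head(missing, 3), collapse = ", "))
  m[, sbsChannels(), drop = FALSE]
}
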