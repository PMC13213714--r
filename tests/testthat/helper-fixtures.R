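# Shared fixtures, built in code at test time.

fixtureSignatures <- function(seed = 7, n = 12)
  makeSyntheticSignatures(nSignatures = n, seed = seed)

# Small simulated cohort for module-level tests (fast).
fixtureCohort <- function(n = 60, seed = 11, ...) {
  simulateCohort(simulationConfig(nSamples = n, seed = seed, ...),
                 fixtureSignatures())
}

# Write a data.frame as a temp MAF and return the path.
writeTempMAF <- function(df) {
  p <- tempfile(fileext = ".maf.tsv")
  data.table::fwrite(df, p, sep = "\t")
  p
}

# Toy 5-row MAF: 4 valid SNVs (one of them purine-referenced) + 1 insertion.
toyMAF <- function() {
  data.frame(
    Tumor_Sample_Barcode = c("A", "A", "A", "B", "B"),
    Chromosome = c("1", "1", "2", "2", "3"),
    Start_Position = c(100L, 200L, 300L, 400L, 500L),
    Reference_Allele = c("C", "G", "T", "AT", "C"),
    Tumor_Seq_Allele2 = c("T", "A", "G", "A", "A"),
    ref_context = c("ACA", "TGT", "GTC", "ATG", "CCG"),
    stringsAsFactors = FALSE)
}

# Independent oracle for the pyrimidine collapse: builds the channel label
# through Biostrings reverse-complementation (a different code path from the
# package's chartr-based collapse).
oracleChannelLabel <- function(ref, alt, fiveP, threeP) {
  if (ref %in% c("A", "G")) {
    rc <- function(x) as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(x)))
    ctx <- rc(paste0(fiveP, ref, threeP))
    alt <- rc(alt)
    ref <- substr(ctx, 2, 2); fiveP <- substr(ctx, 1, 1)
    threeP <- substr(ctx, 3, 3)
  }
  paste0(fiveP, "[", ref, ">", alt, "]", threeP)
}
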