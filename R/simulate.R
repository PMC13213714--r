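.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Synthetic reference signature set
#'
#' Draws sparse Dirichlet probability columns over the 96 channels, rejecting
#' draws until every signature pair has cosine similarity below
#' `maxPairwiseCosine`, so synthetic signatures are as mutually distinct as
#' real SBS signatures. The default names cover the signatures the subtype
#' presets reference (APOBEC SBS2/SBS13; clock-like/MMR SBS1/SBS6/SBS15;
#' chemotherapy SBS87; flat SBS5), so labeling logic is exercised end to end.
#'
#' @param nChannels channels (default 96).
#' @param nSignatures number of signatures (>= 2; default 12).
#' @param sparsity Dirichlet concentration per channel; smaller = sparser
#'   (default 0.08).
#' @param seed RNG seed.
#' @param names signature names; defaults to the preset-relevant SBS names
#'   extended with synthetic fillers.
#' @param maxPairwiseCosine rejection threshold (default 0.7).
#' @return a [SignatureSet-class].
#' @export
makeSyntheticSignatures <- function(nChannels = 96, nSignatures = 12,
                                    sparsity = 0.08, seed = 1L,
                                    names = NULL,
                                    maxPairwiseCosine = 0.7) {
  if (nSignatures < 2) stop("need at least 2 signatures")
  if (is.null(names)) {
    base <- c("SBS1", "SBS2", "SBS5", "SBS6", "SBS13", "SBS15", "SBS87")
    names <- c(base, paste0("SBSS", seq_len(max(0, nSignatures - length(base)))))
  }
  names <- names[seq_len(nSignatures)]
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old), add = TRUE)
  set.seed(seed)
  m <- matrix(0, nChannels, nSignatures)
  for (j in seq_len(nSignatures)) {
    for (try in 1:200) {
      cand <- .rdirichlet(rep(sparsity, nChannels))
      ok <- j == 1 || all(apply(m[, seq_len(j - 1), drop = FALSE], 2,
                                function(prev) cosineSimilarity(cand, prev)) <
                            maxPairwiseCosine)
      if (ok) break
    }
    if (!ok) stop("could not draw signature ", j, " distinct enough; lower sparsity")
    m[, j] <- cand
  }
  chan <- if (nChannels == 96) sbsChannels() else paste0("ch", seq_len(nChannels))
  dimnames(m) <- list(chan, names)
  SignatureSet(m, channels = chan)
}

#' Simulation configuration
#'
#' Study-condition defaults for the synthetic urothelial-carcinoma cohort:
#' a 60/40 MUT1/MUT2 split; APOBEC-dominant (SBS2/SBS13) exposures for MUT1
#' and clock-like/MMR/chemotherapy exposures (SBS1/SBS6/SBS15/SBS87) for
#' MUT2; WES-like mutation burdens (truncated log-normal, median ~100 SNVs,
#' floor 100); exponential survival with MUT1 median 15 months and
#' MUT2-vs-MUT1 hazard ratio 1.74 under uniform censoring tuned to a pooled
#' event fraction of 0.39; Bernoulli immunotherapy response at 31.8% (MUT1)
#' vs 13.1% (MUT2); age/sex/smoking drawn from pooled-cohort-like marginals,
#' independent of subtype.
#'
#' @param nSamples cohort size (default 300).
#' @param subtypeProportions named MUT1/MUT2 mixing proportions.
#' @param exposureMeans named list of per-subtype mean exposure vectors
#'   (signature-named simplex vectors).
#' @param exposureConcentration Dirichlet concentration around the means.
#' @param mutationCountMeanlog,mutationCountSdlog log-normal burden parameters.
#' @param minMutations lower truncation of the per-sample SNV count.
#' @param baselineMedianOS MUT1 median overall survival, months.
#' @param hazardRatio MUT2 vs MUT1 hazard ratio.
#' @param eventFraction target fraction of observed (uncensored) deaths.
#' @param responseRates named MUT1/MUT2 Bernoulli response probabilities.
#' @param seed RNG seed.
#' @return list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nSamples = 300,
                             subtypeProportions = c(MUT1 = 0.6, MUT2 = 0.4),
                             exposureMeans = list(
                               MUT1 = c(SBS2 = 0.35, SBS13 = 0.35,
                                        SBS5 = 0.20, SBS1 = 0.10),
                               MUT2 = c(SBS1 = 0.30, SBS6 = 0.25,
                                        SBS15 = 0.20, SBS87 = 0.15,
                                        SBS5 = 0.10)),
                             exposureConcentration = 50,
                             mutationCountMeanlog = log(100),
                             mutationCountSdlog = 0.8,
                             minMutations = 100,
                             baselineMedianOS = 15,
                             hazardRatio = 1.74,
                             eventFraction = 0.39,
                             responseRates = c(MUT1 = 0.318, MUT2 = 0.131),
                             seed = 1L) {
  stopifnot(abs(sum(subtypeProportions) - 1) < 1e-8,
            all(vapply(exposureMeans,
                       function(e) abs(sum(e) - 1) < 1e-8, logical(1))),
            hazardRatio > 0,
            all(responseRates >= 0 & responseRates <= 1))
  cfg <- list(nSamples = nSamples, subtypeProportions = subtypeProportions,
              exposureMeans = exposureMeans,
              exposureConcentration = exposureConcentration,
              mutationCountMeanlog = mutationCountMeanlog,
              mutationCountSdlog = mutationCountSdlog,
              minMutations = minMutations,
              baselineMedianOS = baselineMedianOS,
              hazardRatio = hazardRatio, eventFraction = eventFraction,
              responseRates = responseRates, seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  cfg
}

.channelToMafRow <- function(channelIdx) {
  lab <- sbsChannels()[channelIdx]
  ref <- substr(lab, 3, 3); alt <- substr(lab, 5, 5)
  ctx <- paste0(substr(lab, 1, 1), ref, substr(lab, 7, 7))
  flip <- stats::runif(length(lab)) < 0.5
  ref[flip] <- chartr("CT", "GA", ref[flip])
  alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
  ctx[flip] <- reverseComplement3(ctx[flip])
  data.frame(Reference_Allele = ref, Tumor_Seq_Allele2 = alt,
             ref_context = ctx, stringsAsFactors = FALSE)
}

#' Simulate a cohort of tumors with known subtype ground truth
#'
#' Per sample: draw the subtype from the configured proportions, an exposure
#' vector from a Dirichlet centered on the subtype's mean exposures, a
#' mutation burden from the truncated log-normal, and channel counts from
#' `Multinomial(burden, signatures %*% exposure)`. Each mutation is realized
#' as a concrete MAF row (random chromosome/position; the substitution is
#' written on a random strand, so the purine-collapse path is exercised),
#' and the clinical table is drawn by [simulateClinical()].
#'
#' @param config a [simulationConfig()].
#' @param signatures a [SignatureSet-class] containing every signature named
#'   in the exposure means.
#' @return list of class `SimulatedCohort`: `maf` (MAF-dialect data.frame),
#'   `clinical`, `trueSubtypes` (named), `trueExposures` (samples x
#'   signatures), `spectra` (samples x 96 true channel counts), `config`.
#' @export
simulateCohort <- function(config, signatures) {
  sigNames <- signatureNames(signatures)
  for (k in names(config$exposureMeans)) {
    unknown <- setdiff(names(config$exposureMeans[[k]]), sigNames)
    if (length(unknown))
      stop("exposure means for ", k, " reference unknown signature(s): ",
           paste(unknown, collapse = ", "))
  }
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old), add = TRUE)
  set.seed(config$seed)
  n <- config$nSamples
  ids <- sprintf("S%04d", seq_len(n))
  subtypes <- sample(names(config$subtypeProportions), n, replace = TRUE,
                     prob = config$subtypeProportions)
  names(subtypes) <- ids
  sigM <- signatureMatrix(signatures)
  expo <- matrix(0, n, length(sigNames), dimnames = list(ids, sigNames))
  spectra <- matrix(0L, n, 96L, dimnames = list(ids, sbsChannels()))
  burden <- pmax(config$minMutations,
                 round(stats::rlnorm(n, config$mutationCountMeanlog,
                                     config$mutationCountSdlog)))
  mafParts <- vector("list", n)
  for (i in seq_len(n)) {
    mu <- config$exposureMeans[[subtypes[i]]]
    e <- .rdirichlet(config$exposureConcentration * mu)
    expo[i, names(mu)] <- e
    p <- as.numeric(sigM %*% expo[i, ])
    cnt <- as.integer(stats::rmultinom(1, burden[i], p))
    spectra[i, ] <- cnt
    idx <- rep.int(seq_len(96L), cnt)
    alleles <- .channelToMafRow(idx)
    mafParts[[i]] <- data.frame(
      Tumor_Sample_Barcode = ids[i],
      Chromosome = as.character(sample.int(22L, length(idx), replace = TRUE)),
      Start_Position = sample.int(100000000L, length(idx), replace = TRUE),
      alleles, stringsAsFactors = FALSE)
  }
  maf <- do.call(rbind, mafParts)
  rownames(maf) <- NULL
  clinical <- simulateClinical(config, subtypes)
  out <- list(maf = maf, clinical = clinical, trueSubtypes = subtypes,
              trueExposures = expo, spectra = spectra, config = config)
  class(out) <- "SimulatedCohort"
  out
}

#' @export
print.SimulatedCohort <- function(x, ...) {
  tab <- table(x$trueSubtypes)
  cat("SimulatedCohort:", length(x$trueSubtypes), "samples (",
      paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "),",
      nrow(x$maf), "SNVs\n")
  invisible(x)
}

.censoringWindow <- function(rates, props, target) {
  if (target <= 0 || target >= 1)
    stop("target event fraction must lie strictly in (0, 1)")
  evFrac <- function(C)
    sum(props * (1 - (1 - exp(-rates * C)) / (rates * C)))
  stats::uniroot(function(C) evFrac(C) - target,
                 lower = 1e-6, upper = 1e6, tol = 1e-9)$root
}

#' Simulate the clinical table for drawn subtypes
#'
#' Overall survival is exponential with the MUT1 rate `log(2) /
#' baselineMedianOS` and the MUT2 rate scaled by the hazard ratio; censoring
#' is uniform on (0, C) with C solved numerically so the expected event
#' fraction matches the configured target. Response is Bernoulli per subtype;
#' age/sex/smoking are drawn from pooled-cohort-like marginals independent of
#' subtype (confounded scenarios can be built by editing the returned table).
#'
#' @param config a [simulationConfig()].
#' @param subtypes named character vector of MUT1/MUT2 assignments.
#' @return data.frame: sample_id, subtype, os_months, os_event, response,
#'   age, sex, smoking.
#' @export
simulateClinical <- function(config, subtypes) {
  n <- length(subtypes)
  rate1 <- log(2) / config$baselineMedianOS
  rates <- c(MUT1 = rate1, MUT2 = rate1 * config$hazardRatio)
  props <- table(factor(subtypes, levels = c("MUT1", "MUT2"))) / n
  C <- .censoringWindow(rates, as.numeric(props), config$eventFraction)
  lam <- rates[subtypes]
  T <- stats::rexp(n, lam)
  U <- stats::runif(n, 0, C)
  data.frame(
    sample_id = names(subtypes),
    subtype = unname(subtypes),
    os_months = pmin(T, U),
    os_event = as.integer(T <= U),
    response = stats::rbinom(n, 1, config$responseRates[subtypes]),
    age = round(pmin(90, pmax(30, stats::rnorm(n, 66, 10.6)))),
    sex = sample(c("male", "female"), n, TRUE, prob = c(0.758, 0.242)),
    smoking = sample(c("former", "never", "current"), n, TRUE,
                     prob = c(0.519, 0.318, 0.132)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a simulated cohort's artifacts to a directory
#' @param cohort a `SimulatedCohort`.
#' @param dir output directory (created).
#' @return invisibly, the paths written.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(maf = file.path(dir, "cohort.maf.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             truth = file.path(dir, "truth.tsv"))
  data.table::fwrite(cohort$maf, paths["maf"], sep = "\t")
  data.table::fwrite(cohort$clinical, paths["clinical"], sep = "\t")
  data.table::fwrite(data.frame(sample_id = names(cohort$trueSubtypes),
                                true_subtype = unname(cohort$trueSubtypes)),
                     paths["truth"], sep = "\t")
  invisible(paths)
}
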