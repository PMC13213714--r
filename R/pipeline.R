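#' Pipeline configuration
#'
#' Collects the paths, thresholds and seeds the stage runner uses. Every
#' stage writes its outputs plus a provenance JSON (input checksums,
#' parameters, seed, package version) into `outDir`.
#'
#' @param outDir artifact directory.
#' @param maf,clinical,signatures input paths (stages that need an input not
#'   present among the artifacts read it from here).
#' @param csThreshold,minPrevalence signature-retention thresholds.
#' @param k,nRuns,kRange NMF working rank and consensus settings.
#' @param deltaGrid,cvFolds NSC settings (NULL deltaGrid = automatic).
#' @param seed base seed recorded in every provenance block.
#' @param simulation a [simulationConfig()] for the `simulate` stage.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(outDir, maf = NULL, clinical = NULL,
                           signatures = NULL, csThreshold = 0.24,
                           minPrevalence = 0.10, k = 2, nRuns = 50,
                           kRange = 2:6, deltaGrid = NULL, cvFolds = 10,
                           seed = 1L, simulation = simulationConfig(seed = seed)) {
  if (csThreshold < 0 || csThreshold > 1 || minPrevalence < 0 || minPrevalence > 1)
    stop("thresholds must lie in [0, 1]")
  cfg <- list(outDir = outDir, maf = maf, clinical = clinical,
              signatures = signatures, csThreshold = csThreshold,
              minPrevalence = minPrevalence, k = k, nRuns = nRuns,
              kRange = kRange, deltaGrid = deltaGrid, cvFolds = cvFolds,
              seed = as.integer(seed), simulation = simulation)
  class(cfg) <- "PipelineConfig"
  cfg
}

.art <- function(cfg, name) file.path(cfg$outDir, name)

.needArtifact <- function(cfg, name, producer) {
  p <- .art(cfg, name)
  if (!file.exists(p))
    stop("missing artifact '", name, "'; run the '", producer,
         "' stage first (or point the config at an existing file)")
  p
}

.writeProvenance <- function(cfg, stage, inputs, params) {
  prov <- list(stage = stage,
               package = as.character(utils::packageVersion("MutSigSubtypes")),
               seed = cfg$seed,
               parameters = params,
               inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])))
  jsonlite::write_json(prov, .art(cfg, paste0(stage, ".provenance.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (synthetic MAF/clinical/truth/signatures), `spectra`
#' (MAF to 96-channel matrix), `cs` (cosine-similarity matrix), `filter`
#' (signature retention), `discover` (NMF consensus subtyping + NSC model
#' trained on the discovered labels), `classify` (apply the NSC model to a
#' spectrum matrix), `survive` (KM/log-rank/Cox by subtype), `summarize`
#' (Table-1-style pooled demographics), `report` (assemble the key results
#' into one JSON). Each stage writes TSV/JSON artifacts plus a provenance
#' JSON into `config$outDir`.
#'
#' @param name stage name.
#' @param config a [pipelineConfig()].
#' @return invisibly, the main artifact path(s) written.
#' @export
runSubcommand <- function(name, config) {
  name <- match.arg(name, c("simulate", "spectra", "cs", "filter", "discover",
                            "classify", "survive", "summarize", "report"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  switch(name,
    simulate = .stageSimulate(config),
    spectra = .stageSpectra(config),
    cs = .stageCS(config),
    filter = .stageFilter(config),
    discover = .stageDiscover(config),
    classify = .stageClassify(config),
    survive = .stageSurvive(config),
    summarize = .stageSummarize(config),
    report = .stageReport(config))
}

.stageSimulate <- function(cfg) {
  sigs <- if (!is.null(cfg$signatures)) readSignatureSet(cfg$signatures)
          else makeSyntheticSignatures(seed = cfg$seed)
  cohort <- simulateCohort(cfg$simulation, sigs)
  paths <- writeCohort(cohort, cfg$outDir)
  sigPath <- .art(cfg, "signatures.tsv")
  writeSignatureSet(sigs, sigPath)
  .writeProvenance(cfg, "simulate", character(0),
                   cfg$simulation[setdiff(names(cfg$simulation), "exposureMeans")])
  invisible(c(paths, signatures = sigPath))
}

.stageSpectra <- function(cfg) {
  mafPath <- if (!is.null(cfg$maf)) cfg$maf
             else .needArtifact(cfg, "cohort.maf.tsv", "simulate")
  maf <- readMAF(mafPath)
  spectra <- buildSpectrumMatrix(maf$records)
  out <- .art(cfg, "spectra.tsv")
  writeSpectrumMatrix(spectra, out)
  .writeProvenance(cfg, "spectra", mafPath,
                   list(skipped = as.list(maf$skipped)))
  invisible(out)
}

.stageCS <- function(cfg) {
  spectra <- readSpectrumMatrix(.needArtifact(cfg, "spectra.tsv", "spectra"))
  sigPath <- if (!is.null(cfg$signatures)) cfg$signatures
             else .needArtifact(cfg, "signatures.tsv", "simulate")
  cs <- buildCSMatrix(spectra, readSignatureSet(sigPath))
  out <- .art(cfg, "cs_matrix.tsv")
  data.table::fwrite(data.frame(sample_id = rownames(csValues(cs)),
                                csValues(cs), check.names = FALSE),
                     out, sep = "\t")
  .writeProvenance(cfg, "cs", c(.art(cfg, "spectra.tsv"), sigPath), list())
  invisible(out)
}

.readCS <- function(path) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  new("CSMatrix", values = v, undefined = apply(v, 1, function(r) all(is.na(r))))
}

.stageFilter <- function(cfg) {
  cs <- .readCS(.needArtifact(cfg, "cs_matrix.tsv", "cs"))
  ret <- filterSignatures(cs, cfg$csThreshold, cfg$minPrevalence)
  out <- .art(cfg, "retained_signatures.tsv")
  data.table::fwrite(retentionTable(ret), out, sep = "\t")
  .writeProvenance(cfg, "filter", .art(cfg, "cs_matrix.tsv"),
                   list(csThreshold = cfg$csThreshold,
                        minPrevalence = cfg$minPrevalence))
  invisible(out)
}

.stageDiscover <- function(cfg) {
  cs <- .readCS(.needArtifact(cfg, "cs_matrix.tsv", "cs"))
  ret <- data.table::fread(.needArtifact(cfg, "retained_signatures.tsv",
                                         "filter"), data.table = FALSE)
  call <- discoverSubtypes(cs, ret$signature[ret$retained], k = cfg$k,
                           kRange = cfg$kRange, nRuns = cfg$nRuns,
                           seed = cfg$seed)
  out <- .art(cfg, "subtypes.tsv")
  data.table::fwrite(subtypeAssignment(call), out, sep = "\t")
  for (kk in call@consensus@kRange) {
    C <- consensusMatrix(call@consensus, kk)
    data.table::fwrite(data.frame(sample_id = rownames(C), C,
                                  check.names = FALSE),
                       .art(cfg, sprintf("consensus_k%d.tsv", kk)), sep = "\t")
  }
  jsonlite::write_json(
    list(cophenetic = as.list(copheneticCoefficients(call@consensus)),
         selectedK = call@consensus@selectedK, workingK = cfg$k,
         nRuns = cfg$nRuns, seed = cfg$seed),
    .art(cfg, "discover_diagnostics.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  labels <- subtypeLabels(call)
  X <- csValues(cs)[names(labels), ret$signature[ret$retained], drop = FALSE]
  model <- nscFit(X, labels, deltaGrid = cfg$deltaGrid,
                  cvFolds = cfg$cvFolds, seed = cfg$seed)
  writeNscModel(model, .art(cfg, "nsc_model.json"))
  .writeProvenance(cfg, "discover",
                   c(.art(cfg, "cs_matrix.tsv"),
                     .art(cfg, "retained_signatures.tsv")),
                   list(k = cfg$k, nRuns = cfg$nRuns, kRange = cfg$kRange,
                        cvFolds = cfg$cvFolds))
  invisible(out)
}

.stageClassify <- function(cfg) {
  modelPath <- .needArtifact(cfg, "nsc_model.json", "discover")
  model <- readNscModel(modelPath)
  cs <- .readCS(.needArtifact(cfg, "cs_matrix.tsv", "cs"))
  X <- csValues(cs)[!cs@undefined, , drop = FALSE]
  pred <- suppressWarnings(nscPredict(model, X))
  out <- .art(cfg, "predictions.tsv")
  data.table::fwrite(pred, out, sep = "\t")
  .writeProvenance(cfg, "classify",
                   c(modelPath, .art(cfg, "cs_matrix.tsv")), list())
  invisible(out)
}

.stageSurvive <- function(cfg) {
  clinPath <- if (!is.null(cfg$clinical)) cfg$clinical
              else .needArtifact(cfg, "clinical.tsv", "simulate")
  clin <- data.table::fread(clinPath, data.table = FALSE)
  subPath <- .art(cfg, "subtypes.tsv")
  if (file.exists(subPath)) {
    sub <- data.table::fread(subPath, data.table = FALSE)
    clin$subtype <- sub$label[match(clin$sample_id, sub$sample_id)]
  }
  if (!"subtype" %in% names(clin))
    stop("clinical table has no subtype column; run 'discover' first")
  a <- clin[clin$subtype == "MUT1", ]; b <- clin[clin$subtype == "MUT2", ]
  kmA <- kmEstimate(a$os_months, a$os_event)
  kmB <- kmEstimate(b$os_months, b$os_event)
  lr <- logrankTest(a$os_months, a$os_event, b$os_months, b$os_event)
  covs <- intersect(c("subtype", "age", "sex", "smoking"), names(clin))
  cox <- coxFit(clin, covs)
  for (nm in c("MUT1", "MUT2")) {
    km <- if (nm == "MUT1") kmA else kmB
    data.table::fwrite(km$curve, .art(cfg, paste0("km_", nm, ".tsv")),
                       sep = "\t")
  }
  res <- list(median_os = list(MUT1 = kmA$median, MUT2 = kmB$median),
              logrank = list(chiSquare = lr$chiSquare, p = lr$p),
              cox = cox$table)
  if ("response" %in% names(clin)) {
    tab <- table(clin$subtype, clin$response)
    ct <- chiSquareTest(tab)
    res$response <- list(
      rate = list(MUT1 = mean(a$response), MUT2 = mean(b$response)),
      chiSquare = ct$statistic, p = ct$p)
  }
  out <- .art(cfg, "survival.json")
  jsonlite::write_json(res, out, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  .writeProvenance(cfg, "survive", c(clinPath, subPath), list(covariates = covs))
  invisible(out)
}

.stageSummarize <- function(cfg) {
  clinPath <- if (!is.null(cfg$clinical)) cfg$clinical
              else .needArtifact(cfg, "clinical.tsv", "simulate")
  clin <- data.table::fread(clinPath, data.table = FALSE)
  if (!"cohort" %in% names(clin)) clin$cohort <- "cohort1"
  subPath <- .art(cfg, "subtypes.tsv")
  if (!"subtype" %in% names(clin) && file.exists(subPath)) {
    sub <- data.table::fread(subPath, data.table = FALSE)
    clin$subtype <- sub$label[match(clin$sample_id, sub$sample_id)]
  }
  counts <- tabulateClinical(clin)
  sizes <- table(clin$cohort)
  summ <- cohortSummary(counts, stats::setNames(as.numeric(sizes), names(sizes)))
  out <- .art(cfg, "cohort_summary.tsv")
  data.table::fwrite(summ$pooled, out, sep = "\t")
  .writeProvenance(cfg, "summarize", clinPath, list(totalN = summ$totalN))
  invisible(out)
}

.stageReport <- function(cfg) {
  sub <- data.table::fread(.needArtifact(cfg, "subtypes.tsv", "discover"),
                           data.table = FALSE)
  report <- list(subtype_counts = as.list(table(sub$label)))
  dg <- .art(cfg, "discover_diagnostics.json")
  if (file.exists(dg)) report$diagnostics <- jsonlite::read_json(dg)
  sv <- .art(cfg, "survival.json")
  if (file.exists(sv)) report$survival <- jsonlite::read_json(sv)
  out <- .art(cfg, "report.json")
  jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  data.table::fwrite(data.frame(label = names(table(sub$label)),
                                n = as.integer(table(sub$label))),
                     .art(cfg, "report_subtype_counts.tsv"), sep = "\t")
  .writeProvenance(cfg, "report", c(.art(cfg, "subtypes.tsv"), dg, sv), list())
  invisible(out)
}

#' Run a sequence of pipeline stages
#' @param stages character vector of stage names, in order.
#' @param config a [pipelineConfig()].
#' @export
runPipeline <- function(stages = c("simulate", "spectra", "cs", "filter",
                                   "discover", "survive", "report"),
                        config) {
  for (s in stages) runSubcommand(s, config)
  invisible(config$outDir)
}
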