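#' Run the end-to-end analysis pipeline
#'
#' Executes the stages of the analysis in their fixed order — simulate,
#' lactation scoring, preprocessing, design-weighted differential
#' abundance, lipid-structure aggregation, longitudinal screening,
#' signature selection, cohort report — writing each stage's artifacts
#' under `outdir` and a manifest JSON listing every file with its MD5
#' checksum. Reruns with the same configuration and seed produce identical
#' checksums.
#'
#' @param config Path to a YAML/JSON configuration file, or an equivalent
#'   named list. Recognized fields: `seed`, `stages` (subset of the stage
#'   names above, default all), `nCohort`, `nCases`, `nControls`,
#'   `panelScale` (fraction of the lipid panel to simulate, default 0.15),
#'   `missingThresholdMetab` (0.40), `missingThresholdLipid` (0.05),
#'   `signature` (list of [signatureConfig()] overrides).
#' @param outdir Output directory.
#' @param seed Overrides the configuration seed when non-NULL.
#' @return Invisibly, the manifest (named list of file checksums), also
#'   written to `manifest.json`.
#' @export
runPipeline <- function(config = list(), outdir, seed = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("configuration file not found: ", config)
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE) else
        yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  allStages <- c("simulate", "lactation", "preprocess", "de", "structure",
                 "longitudinal", "signature", "report")
  stages <- config$stages %||% allStages
  bad <- setdiff(stages, allStages)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  if (!is.null(seed)) config$seed <- seed
  config$seed <- config$seed %||% 1L
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  logFile <- file.path(outdir, "pipeline.log")
  logMsg <- function(...) {
    cat(format(Sys.time(), "%H:%M:%S"), "|", ..., "\n",
        file = logFile, append = TRUE)
  }
  emit <- function(obj, name, writer = utils::write.csv) {
    f <- file.path(outdir, name)
    writer(obj, f)
    f
  }
  files <- character()

  scfg <- simConfig(
    nCohort = config$nCohort %||% 600,
    nCases = config$nCases %||% 110,
    nControls = config$nControls %||% 120,
    seed = config$seed)
  logMsg("simulate: cohort of", scfg@nCohort)
  cohort <- simulateCohort(scfg)
  subset <- nestedCaseControlSample(cohort, scfg@nCases, scfg@nControls,
                                    seed = config$seed)
  panel <- lipidomicsPanel(scale = config$panelScale %||% 0.15)
  omics <- simulateOmics(subset, panel, scfg, panelType = "lipid")
  if ("simulate" %in% stages)
    files <- c(files, writeCohortArtifacts(subset, omics, outdir))

  scores <- scoreLactation(diaries(subset))
  if ("lactation" %in% stages)
    files <- c(files, emit(scores, "lactation_scores.csv",
                           function(o, f) utils::write.csv(o, f,
                                                           row.names = FALSE)))

  thrLip <- config$missingThresholdLipid %||% 0.05
  base <- preprocessPanel(omics$baseline, threshold = thrLip)
  de <- NULL
  if (any(c("de", "structure", "signature") %in% stages)) {
    logMsg("de: weighted differential abundance on", nrow(base), "analytes")
    cd <- as.data.frame(colData(base))
    keep <- !cd$isControl
    w <- samplingWeights(cd$samplingProb[keep])
    de <- weightedDiffAbundance(
      assay(base, "log2norm")[, keep, drop = FALSE],
      group = cd$feedingGroup[keep],
      covariates = data.frame(prepregBMI = cd$prepregBMI[keep]),
      weights = w)
    de$class <- analyteClass(base)
    if ("de" %in% stages)
      files <- c(files, emit(de, "de_results.tsv", function(o, f)
        utils::write.table(o, f, sep = "\t", quote = FALSE,
                           row.names = FALSE)))
  }

  if ("structure" %in% stages) {
    ann <- parseLipidName(de$analyte)
    grid <- aggregateByStructure(de, ann)
    files <- c(files, emit(grid, "structure_grid.tsv", function(o, f)
      utils::write.table(o, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)))
    fam <- fattyAcidCompositionMatrix(de, ann)
    files <- c(files, emit(
      data.frame(class = rownames(fam$log2FC), fam$log2FC,
                 check.names = FALSE),
      "fa_composition_log2fc.tsv", function(o, f)
        utils::write.table(o, f, sep = "\t", quote = FALSE,
                           row.names = FALSE)))
  }

  if ("longitudinal" %in% stages) {
    logMsg("longitudinal: mixed-model screen")
    filt <- filterMissingnessLongitudinal(
      omics$baseline, omics$followup,
      threshold = config$missingThresholdMetab %||% 0.40)
    b <- normalizeTotalSum(imputeHalfLOD(filt$baseline))
    f <- normalizeTotalSum(imputeHalfLOD(filt$followup))
    bc <- batchCorrect(b, f)
    rec <- makeLongitudinalRecords(bc$baseline, bc$followup)
    long <- mixedModelScreen(rec)
    files <- c(files, emit(long, "longitudinal_results.tsv",
                           function(o, f) utils::write.table(
                             o, f, sep = "\t", quote = FALSE,
                             row.names = FALSE)))
  }

  if ("signature" %in% stages) {
    logMsg("signature: repeated random-forest selection")
    cd <- as.data.frame(colData(base))
    keep <- !cd$isControl & cd$feedingGroup == "IBF"
    ibf <- assay(base, "log2norm")[, keep, drop = FALSE]
    labs <- factor(ifelse(cd$futureT2d[keep], "T2D", "noT2D"),
                   levels = c("noT2D", "T2D"))
    deT2d <- weightedDiffAbundance(
      ibf, group = labs, weights = samplingWeights(cd$samplingProb[keep]))
    sigRes <- tryCatch({
      feats <- selectInputFeatures(deT2d)
      sc <- do.call(signatureConfig, c(
        list(seed = config$seed),
        config$signature %||%
          list(nRepeats = 25, holdoutPerClass = 15, nTrees = 200,
               topKLogged = min(30, length(feats)))))
      sel <- repeatedSelection(t(ibf[feats, , drop = FALSE]), labs, sc)
      sig <- finalizeSignature(sel, min(sc@signatureSize,
                                        sum(sel$frequency > 0)))
      list(frequency = as.list(sel$frequency), signature = sig,
           medianAUC = stats::median(sel$metrics[, "AUC"], na.rm = TRUE))
    }, error = function(e) list(error = conditionMessage(e)))
    f <- file.path(outdir, "signature_report.json")
    jsonlite::write_json(sigRes, f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  }

  if ("report" %in% stages) {
    tab <- summarizeCohort(
      cbind(participants(subset),
            feedingGroup = feedingGroups(subset)[participants(subset)$id]),
      "feedingGroup",
      c(age = "normal", prepregBMI = "normal", race = "categorical",
        glucoseTolerance = "categorical", lactationDuration = "skewed"))
    files <- c(files, emit(tab, "cohort_table.csv", function(o, f)
      utils::write.csv(o, f, row.names = FALSE)))
  }

  manifest <- as.list(tools::md5sum(sort(unique(files))))
  names(manifest) <- basename(names(manifest))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE)
  logMsg("done:", length(manifest), "artifacts")
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
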