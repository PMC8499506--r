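#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData assay<- colData<- rowData<-
NULL

#' Configuration for the synthetic cohort generator
#'
#' Holds every parameter of the synthetic-cohort and synthetic-omics
#' generator: cohort and case-control sizes, the incident type 2 diabetes
#' (T2D) rate, the planted per-class group effects on the log2 scale, the
#' attenuation of those effects in the future-T2D stratum, missingness
#' rates, the between-batch offset scale, and the master seed. A given seed
#' fully determines the generated cohort and omics tables.
#'
#' @slot nCohort Number of participants in the full simulated cohort.
#' @slot nCases,nControls Sizes of the nested case-control subset.
#' @slot t2dRate Marginal probability of incident T2D during follow-up.
#' @slot effectMap Named numeric vector: planted log2 group effect
#'   (intensive breastfeeding relative to formula/mixed feeding) per analyte
#'   class. Classes absent from the map get effect 0.
#' @slot attenuationT2d Multiplier in `[0, 1]` applied to planted effects in
#'   the future-T2D stratum.
#' @slot followupShrink Multiplier applied to planted effects at follow-up
#'   (default 0: effects vanish after lactation ceases).
#' @slot missingRateMetab,missingRateLipid Missing-completely-at-random
#'   rates for the metabolomic and lipidomic panels.
#' @slot batchOffsetSd Standard deviation (log2 units) of the per-analyte
#'   follow-up batch offset.
#' @slot sdRange Range from which per-analyte log2 noise SDs are drawn.
#' @slot seed Integer master seed.
#'
#' @seealso [simConfig()] for the user-facing constructor with defaults.
#' @export
setClass("SimConfig",
  representation(
    nCohort = "numeric", nCases = "numeric", nControls = "numeric",
    t2dRate = "numeric", effectMap = "numeric", attenuationT2d = "numeric",
    followupShrink = "numeric", missingRateMetab = "numeric",
    missingRateLipid = "numeric", batchOffsetSd = "numeric",
    sdRange = "numeric", seed = "numeric"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  p <- c(t2dRate = object@t2dRate,
         attenuationT2d = object@attenuationT2d,
         followupShrink = object@followupShrink,
         missingRateMetab = object@missingRateMetab,
         missingRateLipid = object@missingRateLipid)
  bad <- names(p)[is.na(p) | p < 0 | p > 1]
  if (length(bad))
    msg <- c(msg, paste0("probabilities/multipliers must lie in [0, 1]: ",
                         paste(bad, collapse = ", ")))
  if (object@nCohort < 1) msg <- c(msg, "nCohort must be >= 1")
  if (object@nCases < 0 || object@nControls < 0)
    msg <- c(msg, "nCases and nControls must be nonnegative")
  if (object@nCases + object@nControls > object@nCohort)
    msg <- c(msg, "nCases + nControls must not exceed nCohort")
  if (object@batchOffsetSd < 0) msg <- c(msg, "batchOffsetSd must be >= 0")
  if (length(object@sdRange) != 2L || any(object@sdRange <= 0) ||
      diff(object@sdRange) < 0)
    msg <- c(msg, "sdRange must be two positive increasing values")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (length(object@effectMap) && is.null(names(object@effectMap)))
    msg <- c(msg, "effectMap must be a named numeric vector")
  if (length(msg)) msg else TRUE
})

#' Construct a synthetic-cohort configuration
#'
#' Defaults emulate the structure of the study cohort: ~1000 women with
#' gestational diabetes, a 350-woman nested case-control subset, incident
#' T2D in roughly half of the subset (cases are oversampled by design), and
#' planted lactation effects of the direction reported for the plasma
#' lipidome — lower triacylglycerols (TAG) and diacylglycerols (DAG), higher
#' glycerophospholipids and sphingolipids in intensively breastfeeding
#' women — attenuated in the future-T2D stratum.
#'
#' @param nCohort,nCases,nControls Cohort and case-control subset sizes.
#' @param t2dRate Marginal incident-T2D probability in the full cohort.
#' @param effectMap Named numeric vector of planted log2 class effects.
#' @param attenuationT2d Effect multiplier in the future-T2D stratum.
#' @param followupShrink Effect multiplier at follow-up (0 = effects gone).
#' @param missingRateMetab,missingRateLipid MCAR missingness rates.
#' @param batchOffsetSd SD (log2) of the per-analyte follow-up batch offset.
#' @param sdRange Range of per-analyte log2 noise SDs.
#' @param seed Master seed; identical seeds give identical output.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nCohort = 200, nCases = 30, nControls = 40, seed = 1)
#' cfg
#' @export
simConfig <- function(nCohort = 1000, nCases = 171, nControls = 179,
                      t2dRate = 0.17,
                      effectMap = c(
                        TAG = -0.4, DAG = -0.35, MAG = -0.1, FFA = -0.1,
                        CE = 0, PC = 0.25, PE = 0.2, PI = 0.2, LPC = 0.15,
                        LPE = 0.15, SM = 0.3, CER = 0.25, DCER = 0.2,
                        HCER = 0.2, LCER = 0.2,
                        glycerophospholipid = 0.2, sphingomyelin = 0.25,
                        AA = 0, AC = 0, BA = 0, monosaccharide = 0),
                      attenuationT2d = 0.5, followupShrink = 0,
                      missingRateMetab = 0.05, missingRateLipid = 0.02,
                      batchOffsetSd = 0.3, sdRange = c(0.2, 0.6),
                      seed = 1L) {
  new("SimConfig",
      nCohort = nCohort, nCases = nCases, nControls = nControls,
      t2dRate = t2dRate, effectMap = effectMap,
      attenuationT2d = attenuationT2d, followupShrink = followupShrink,
      missingRateMetab = missingRateMetab,
      missingRateLipid = missingRateLipid,
      batchOffsetSd = batchOffsetSd, sdRange = sdRange, seed = seed)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig\n",
      "  cohort: ", object@nCohort,
      " (cases ", object@nCases, " / controls ", object@nControls, ")\n",
      "  t2dRate: ", object@t2dRate,
      "  attenuationT2d: ", object@attenuationT2d, "\n",
      "  planted classes: ",
      paste(names(object@effectMap)[object@effectMap != 0], collapse = ", "),
      "\n  seed: ", object@seed, "\n", sep = "")
})

#' Cohort of postpartum participants with feeding diaries
#'
#' Container pairing a participant covariate table with per-month feeding
#' diaries. Case-control subsets produced by [nestedCaseControlSample()] are
#' the same class, with the `samplingProb` column filled and the sampling
#' rule recorded in `metadata`.
#'
#' @slot participants `data.frame` with one row per participant (columns
#'   `id`, `age`, `prepregBMI`, `race`, `ogttZsum`, `gdmTreatment`,
#'   `glucoseTolerance`, `futureT2d`, `followupMonths`, `lactationDuration`,
#'   `samplingProb`).
#' @slot diaries `data.frame` with one row per participant-month (columns
#'   `id`, `month`, `breastFeeds`, `formulaFeeds`, `formulaOz`).
#' @slot metadata List of provenance details (generator config, sampling
#'   rule, matching bins).
#' @export
setClass("LactationCohort",
  representation(participants = "data.frame", diaries = "data.frame",
                 metadata = "list")
)

setValidity("LactationCohort", function(object) {
  msg <- character()
  need <- c("id", "age", "prepregBMI", "race", "futureT2d", "samplingProb")
  miss <- setdiff(need, names(object@participants))
  if (length(miss))
    msg <- c(msg, paste("participants lacks columns:",
                        paste(miss, collapse = ", ")))
  else {
    if (anyDuplicated(object@participants$id))
      msg <- c(msg, "participant ids must be unique")
    sp <- object@participants$samplingProb
    if (any(!is.na(sp) & (sp <= 0 | sp > 1)))
      msg <- c(msg, "samplingProb must lie in (0, 1]")
  }
  dneed <- c("id", "month", "breastFeeds", "formulaFeeds", "formulaOz")
  dmiss <- setdiff(dneed, names(object@diaries))
  if (length(dmiss))
    msg <- c(msg, paste("diaries lacks columns:",
                        paste(dmiss, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

setMethod("show", "LactationCohort", function(object) {
  p <- object@participants
  cat("LactationCohort with", nrow(p), "participants\n")
  cat("  future T2D:", sum(p$futureT2d), " diary months:",
      nrow(object@diaries), "\n")
  if (any(!is.na(p$samplingProb)))
    cat("  case-control subset (sampling probabilities attached)\n")
})

#' Samples-by-analytes assay container
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] for
#' targeted metabolomic / lipidomic panels. The `"abundance"` assay holds
#' measured concentrations with `NA` marking missing cells; `rowData` must
#' carry the analyte class (`class`) and limit of detection (`lod`);
#' `colData` carries sample metadata, including the `timepoint`/batch label
#' and, for internal-control samples, `isControl = TRUE`.
#'
#' @export
setClass("AnalyteExperiment", contains = "SummarizedExperiment")

setValidity("AnalyteExperiment", function(object) {
  msg <- character()
  if (!"abundance" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'abundance' is required")
  rd <- rowData(object)
  for (col in c("class", "lod"))
    if (!col %in% names(rd))
      msg <- c(msg, paste0("rowData column '", col, "' is required"))
  if ("abundance" %in% SummarizedExperiment::assayNames(object)) {
    a <- assay(object, "abundance")
    if (any(a <= 0, na.rm = TRUE))
      msg <- c(msg, "abundance values must be positive (NA marks missing)")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "unique analyte rownames are required")
  if (length(msg)) msg else TRUE
})

#' Construct an AnalyteExperiment
#'
#' @param abundance Numeric matrix, analytes in rows, samples in columns;
#'   `NA` marks missing measurements.
#' @param analyteClass Character vector of per-analyte class labels.
#' @param lod Numeric vector of per-analyte limits of detection.
#' @param colData `data.frame`/`DataFrame` of sample metadata (one row per
#'   column of `abundance`).
#' @param metadata Optional list stored in the object metadata.
#' @return An [AnalyteExperiment-class].
#' @examples
#' m <- matrix(rlnorm(12), 3, 4,
#'             dimnames = list(paste0("a", 1:3), paste0("s", 1:4)))
#' ae <- AnalyteExperiment(m, analyteClass = c("AA", "AA", "SM"),
#'                         lod = c(0.1, 0.1, 0.2))
#' ae
#' @export
AnalyteExperiment <- function(abundance, analyteClass, lod,
                              colData = NULL, metadata = list()) {
  if (is.null(colData))
    colData <- S4Vectors::DataFrame(row.names = colnames(abundance))
  se <- SummarizedExperiment(
    assays = list(abundance = abundance),
    rowData = S4Vectors::DataFrame(class = analyteClass, lod = lod,
                                   row.names = rownames(abundance)),
    colData = colData)
  metadata(se) <- metadata
  new("AnalyteExperiment", se)
}

setMethod("show", "AnalyteExperiment", function(object) {
  methods::callNextMethod()
  a <- assay(object, "abundance")
  cat(sprintf("missing cells: %d (%.1f%%)\n", sum(is.na(a)),
              100 * mean(is.na(a))))
})

#' Configuration for the random-forest signature selector
#'
#' Defaults follow the published procedure: a single 25-per-class hold-out,
#' 100 repeats of down-sampled training, the top 30 analytes by variable
#' importance logged per repeat, and a final 10-analyte signature.
#'
#' @slot nRepeats Number of down-sample/fit/evaluate repeats.
#' @slot holdoutPerClass Hold-out test-set size per class.
#' @slot topKLogged Analytes logged per repeat by importance.
#' @slot signatureSize Size of the final signature.
#' @slot nTrees Trees per random forest.
#' @slot importance Importance measure: "impurity" (mean decrease in Gini)
#'   or "permutation" (mean decrease in accuracy).
#' @slot redrawHoldout Redraw the hold-out each repeat (off by default; the
#'   published procedure fixes the hold-out once).
#' @slot seed Integer master seed.
#' @export
setClass("SignatureConfig",
  representation(nRepeats = "numeric", holdoutPerClass = "numeric",
                 topKLogged = "numeric", signatureSize = "numeric",
                 nTrees = "numeric", importance = "character",
                 redrawHoldout = "logical", seed = "numeric")
)

setValidity("SignatureConfig", function(object) {
  msg <- character()
  if (object@signatureSize > object@topKLogged)
    msg <- c(msg, "signatureSize must not exceed topKLogged")
  if (object@nRepeats < 1) msg <- c(msg, "nRepeats must be >= 1")
  if (object@holdoutPerClass < 1) msg <- c(msg, "holdoutPerClass must be >= 1")
  if (!object@importance %in% c("impurity", "permutation"))
    msg <- c(msg, "importance must be 'impurity' or 'permutation'")
  if (length(msg)) msg else TRUE
})

#' @rdname SignatureConfig-class
#' @param nRepeats,holdoutPerClass,topKLogged,signatureSize,nTrees,importance,redrawHoldout,seed
#'   See the class slots.
#' @return A validated [SignatureConfig-class].
#' @export
signatureConfig <- function(nRepeats = 100, holdoutPerClass = 25,
                            topKLogged = 30, signatureSize = 10,
                            nTrees = 500, importance = "impurity",
                            redrawHoldout = FALSE, seed = 1L) {
  new("SignatureConfig", nRepeats = nRepeats,
      holdoutPerClass = holdoutPerClass, topKLogged = topKLogged,
      signatureSize = signatureSize, nTrees = nTrees,
      importance = importance, redrawHoldout = redrawHoldout, seed = seed)
}

setMethod("show", "SignatureConfig", function(object) {
  cat("SignatureConfig: ", object@nRepeats, " repeats, hold-out ",
      object@holdoutPerClass, "/class, top-", object@topKLogged,
      " logged, signature size ", object@signatureSize, "\n", sep = "")
})
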