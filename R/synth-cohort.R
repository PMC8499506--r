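#' Simulate a postpartum GDM cohort with feeding diaries
#'
#' Generates a full cohort of women with gestational diabetes: covariates
#' (age, pre-pregnancy BMI, race/ethnicity, prenatal OGTT z-score sum, GDM
#' treatment), baseline glucose-tolerance status, incident type 2 diabetes
#' during follow-up, and six months of postpartum feeding diaries. Feeding
#' behaviour is negatively correlated with pre-pregnancy BMI (heavier women
#' breastfeed less intensively), glucose-tolerance status is linked to BMI,
#' and the incident-T2D probability is `t2dRate` modulated by
#' glucose-tolerance status (lower in NGT, higher in IFG/IGT, marginally
#' equal to `t2dRate`). The seed in `config` fully determines the output.
#'
#' @param config A [SimConfig-class] from [simConfig()].
#' @return A [LactationCohort-class] with `samplingProb = NA` (filled by
#'   [nestedCaseControlSample()]).
#' @examples
#' coh <- simulateCohort(simConfig(nCohort = 100, nCases = 10,
#'                                 nControls = 10, seed = 1))
#' coh
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "SimConfig"))
  methods::validObject(config)
  set.seed(config@seed)
  n <- config@nCohort
  id <- sprintf("P%05d", seq_len(n))
  age <- pmin(50, pmax(18, stats::rnorm(n, 34, 4.9)))
  bmi <- pmin(60, pmax(18, stats::rnorm(n, 33, 7.5)))
  race <- sample(c("white", "asian", "black", "hispanic", "other"), n,
                 replace = TRUE, prob = c(0.17, 0.30, 0.11, 0.41, 0.01))
  ogtt <- stats::rnorm(n, 0.5, 2.8)
  treat <- sample(c("diet", "medication"), n, replace = TRUE,
                  prob = c(0.58, 0.42))
  # impaired glucose tolerance more likely at higher BMI; marginal ~0.5
  pIfg <- stats::plogis(0.4 * (bmi - 33) / 7.5)
  gluc <- ifelse(stats::runif(n) < pIfg, "IFG/IGT", "NGT")
  mult <- ifelse(gluc == "IFG/IGT", 1.35, 0.65)
  t2d <- stats::runif(n) < pmin(1, config@t2dRate * mult)
  followup <- pmax(1, stats::rnorm(n, 53, 32))

  # latent lactation propensity, anti-correlated with BMI
  lambda <- stats::plogis(stats::rnorm(n, 1.1 - 0.5 * (bmi - 33) / 7.5, 1.2))
  months <- 6L
  diary <- do.call(rbind, lapply(seq_len(months), function(m) {
    # intensity decays with month for low-propensity women
    lam <- stats::plogis(stats::qlogis(lambda) - 0.25 * (m - 1))
    total <- pmax(1L, stats::rpois(n, 8))
    breast <- stats::rbinom(n, total, lam)
    formula <- total - breast
    oz <- formula * pmax(0, stats::rnorm(n, 3, 0.5))
    data.frame(id = id, month = m, breastFeeds = breast,
               formulaFeeds = formula, formulaOz = oz,
               stringsAsFactors = FALSE)
  }))
  # total lactation duration: last month with any breastfeeding, jittered
  lastBf <- vapply(split(diary, diary$id), function(d)
    max(c(0, d$month[d$breastFeeds > 0])), numeric(1))[id]
  duration <- pmax(0, lastBf * 2 + stats::rnorm(n, 0, 1))

  part <- data.frame(
    id = id, age = age, prepregBMI = bmi, race = race, ogttZsum = ogtt,
    gdmTreatment = treat, glucoseTolerance = gluc, futureT2d = t2d,
    followupMonths = followup, lactationDuration = duration,
    samplingProb = NA_real_, stringsAsFactors = FALSE)
  new("LactationCohort", participants = part, diaries = diary,
      metadata = list(config = config))
}

.matchingBins <- function(part, matchingVars) {
  bins <- rep("", nrow(part))
  if ("age" %in% matchingVars)
    bins <- paste(bins, floor(part$age / 10), sep = "|")
  if ("prepregBMI" %in% matchingVars)
    bins <- paste(bins, cut(part$prepregBMI,
                            breaks = c(-Inf, 25, 30, 35, 40, Inf),
                            labels = FALSE), sep = "|")
  if ("race" %in% matchingVars)
    bins <- paste(bins, part$race, sep = "|")
  bins
}

#' Draw a nested case-control subset with known sampling probabilities
#'
#' Cases (future T2D) are taken with probability 1 when all are requested,
#' or uniformly otherwise. Controls are sampled within coarse matching bins
#' (age decade x BMI class x race/ethnicity by default), with per-bin
#' quotas proportional to the bin's case count, so every sampled control's
#' sampling probability is exactly (bin quota) / (bin control count). These
#' exact probabilities are the ground truth for inverse-probability
#' weighting downstream.
#'
#' @param cohort A [LactationCohort-class] from [simulateCohort()].
#' @param nCases,nControls Requested subset sizes.
#' @param matchingVars Subset of `c("age", "prepregBMI", "race")`.
#' @param seed Seed for the control draw.
#' @return A [LactationCohort-class] restricted to the subset, with
#'   `samplingProb` filled and bin quotas recorded in `metadata`.
#' @export
nestedCaseControlSample <- function(cohort, nCases, nControls,
                                    matchingVars = c("age", "prepregBMI",
                                                     "race"),
                                    seed = 1L) {
  stopifnot(is(cohort, "LactationCohort"))
  part <- participants(cohort)
  cases <- part[part$futureT2d, , drop = FALSE]
  ctrls <- part[!part$futureT2d, , drop = FALSE]
  if (nrow(cases) < nCases)
    stop("requested ", nCases, " cases but only ", nrow(cases),
         " are available")
  if (nrow(ctrls) < nControls)
    stop("requested ", nControls, " controls but only ", nrow(ctrls),
         " are available")
  set.seed(seed)

  if (nCases == nrow(cases)) {
    sampCases <- cases
    sampCases$samplingProb <- 1
  } else {
    idx <- sample.int(nrow(cases), nCases)
    sampCases <- cases[idx, , drop = FALSE]
    sampCases$samplingProb <- nCases / nrow(cases)
  }

  # per-bin quotas proportional to the case distribution (largest remainder),
  # capped at the bin's available controls; surplus reallocated greedily
  caseBins <- .matchingBins(sampCases, matchingVars)
  ctrlBins <- .matchingBins(ctrls, matchingVars)
  avail <- table(ctrlBins)
  binNames <- names(avail)
  caseCount <- table(factor(caseBins, levels = binNames))
  weightRaw <- as.numeric(caseCount)
  if (sum(weightRaw) == 0) weightRaw <- as.numeric(avail)
  target <- nControls * weightRaw / sum(weightRaw)
  quota <- pmin(floor(target), as.numeric(avail))
  frac <- target - floor(target)
  room <- as.numeric(avail) - quota
  while (sum(quota) < nControls) {
    elig <- which(room > 0)
    if (!length(elig)) stop("insufficient eligible controls across bins")
    pick <- elig[order(-frac[elig])][1L]
    quota[pick] <- quota[pick] + 1
    room[pick] <- room[pick] - 1
    frac[pick] <- frac[pick] - 1
  }
  names(quota) <- binNames

  sampCtrlIdx <- unlist(lapply(binNames, function(b) {
    k <- quota[[b]]
    if (k == 0) return(integer())
    inBin <- which(ctrlBins == b)
    if (k == length(inBin)) inBin else inBin[sample.int(length(inBin), k)]
  }))
  sampCtrls <- ctrls[sampCtrlIdx, , drop = FALSE]
  sampCtrls$samplingProb <- (quota / as.numeric(avail))[
    .matchingBins(sampCtrls, matchingVars)]

  sub <- rbind(sampCases, sampCtrls)
  sub <- sub[order(sub$id), , drop = FALSE]
  rownames(sub) <- NULL
  di <- diaries(cohort)
  new("LactationCohort", participants = sub,
      diaries = di[di$id %in% sub$id, , drop = FALSE],
      metadata = c(cohort@metadata,
                   list(sampling = list(matchingVars = matchingVars,
                                        quota = quota,
                                        available = as.numeric(avail),
                                        seed = seed))))
}

#' Simulate two-timepoint omics panels with planted group effects
#'
#' Generates baseline and follow-up analyte tables for a case-control
#' subset. Abundances are log-normal: per-analyte log2 means ~ N(5, 1) and
#' SDs drawn from `config@sdRange`. The planted class effect (`effectMap`)
#' separates intensively breastfeeding (IBF) from formula/mixed-feeding
#' women at baseline; at follow-up effects are multiplied by
#' `followupShrink` (default 0 — differences vanish after lactation ends).
#' In the future-T2D stratum all effects are multiplied by
#' `attenuationT2d`. Cells below the analyte's limit of detection are set
#' missing, plus missing-completely-at-random cells at the panel rate (a
#' per-analyte `missingRate` column in the panel overrides it). Follow-up
#' samples receive a per-analyte batch offset ~ N(0, `batchOffsetSd`) on the
#' log2 scale, and each batch contains a noiseless internal-control sample
#' (`"IC"`) equal to the per-batch panel mean, which makes the offset
#' exactly recoverable by [batchCorrect()].
#'
#' @param subset A [LactationCohort-class] case-control subset (feeding
#'   groups are derived from its diaries via [lir2Month()]).
#' @param panel Panel specification (see [metabolomicsPanel()]).
#' @param config A [SimConfig-class]; `missingRate` chooses
#'   `missingRateMetab` unless `panelType = "lipid"`.
#' @param panelType `"metab"` or `"lipid"` (selects the MCAR rate).
#' @param timepoints Which tables to generate.
#' @return A named list of [AnalyteExperiment-class] objects (one per
#'   timepoint) with the ground truth (planted per-analyte effects, batch
#'   offsets, feeding groups) in each object's `metadata()`.
#' @export
simulateOmics <- function(subset, panel, config, panelType = c("metab",
                                                               "lipid"),
                          timepoints = c("baseline", "followup")) {
  stopifnot(is(subset, "LactationCohort"), is(config, "SimConfig"))
  panelType <- match.arg(panelType)
  .validatePanel(panel)
  part <- participants(subset)
  if (!nrow(part)) stop("subset is empty")
  set.seed(config@seed + 10009L)

  grp <- feedingGroups(subset)[part$id]
  nA <- nrow(panel)
  mu <- stats::rnorm(nA, 5, 1)
  sdA <- stats::runif(nA, config@sdRange[1], config@sdRange[2])
  eff <- unname(config@effectMap[panel$class])
  eff[is.na(eff)] <- 0
  delta <- stats::rnorm(nA, 0, config@batchOffsetSd)
  mcar <- if (panelType == "metab") config@missingRateMetab else
    config@missingRateLipid
  mcarA <- if ("missingRate" %in% names(panel))
    ifelse(is.na(panel$missingRate), mcar, panel$missingRate) else
      rep(mcar, nA)

  attn <- ifelse(part$futureT2d, config@attenuationT2d, 1)
  isIBF <- as.numeric(grp == "IBF")

  makeTable <- function(tp) {
    shrink <- if (tp == "baseline") 1 else config@followupShrink
    off <- if (tp == "baseline") rep(0, nA) else delta
    # analytes x samples on log2 scale
    m <- matrix(stats::rnorm(nA * nrow(part), 0, 1), nA, nrow(part)) * sdA
    m <- m + mu + off +
      outer(eff * shrink, isIBF * attn)
    vals <- 2^m
    # below-LOD censoring, then MCAR at the class rate
    vals[vals < panel$lod] <- NA
    mcarMask <- matrix(stats::runif(nA * nrow(part)), nA) <
      matrix(mcarA, nA, nrow(part))
    vals[mcarMask] <- NA
    ctrl <- 2^(mu + off)
    vals <- cbind(vals, IC = ctrl)
    dimnames(vals) <- list(panel$analyte, c(part$id, "IC"))
    cd <- S4Vectors::DataFrame(
      part[c("id", "age", "prepregBMI", "race", "glucoseTolerance",
             "futureT2d", "lactationDuration", "samplingProb")],
      feedingGroup = grp, timepoint = tp, isControl = FALSE,
      row.names = part$id)
    cd <- rbind(cd, S4Vectors::DataFrame(
      id = "IC", age = NA_real_, prepregBMI = NA_real_, race = NA_character_,
      glucoseTolerance = NA_character_, futureT2d = NA,
      lactationDuration = NA_real_, samplingProb = NA_real_,
      feedingGroup = NA_character_, timepoint = tp, isControl = TRUE,
      row.names = "IC"))
    AnalyteExperiment(vals, analyteClass = panel$class, lod = panel$lod,
                      colData = cd,
                      metadata = list(groundTruth = list(
                        effect = stats::setNames(eff * shrink * 1,
                                                 panel$analyte),
                        attenuationT2d = config@attenuationT2d,
                        batchOffset = stats::setNames(off, panel$analyte),
                        logMu = stats::setNames(mu, panel$analyte),
                        logSd = stats::setNames(sdA, panel$analyte),
                        feedingGroup = grp)))
  }
  out <- lapply(stats::setNames(timepoints, timepoints), makeTable)
  out
}

#' Feeding-group labels for a cohort
#'
#' Applies [lir2Month()] to the first two diary months of every participant
#' and returns the IBF / IFF-Mixed dichotomy.
#'
#' @param cohort A [LactationCohort-class].
#' @return Named character vector (participant id -> group).
#' @export
feedingGroups <- function(cohort) {
  di <- diaries(cohort)
  di <- di[di$month <= 2, , drop = FALSE]
  vapply(split(di, di$id), function(d) {
    d <- d[order(d$month), ]
    lir2Month(list(
      feedingMonth(d$breastFeeds[1], d$formulaFeeds[1], d$formulaOz[1]),
      feedingMonth(d$breastFeeds[2], d$formulaFeeds[2], d$formulaOz[2])
    ))$group
  }, character(1))
}

#' Write cohort artifacts to disk
#'
#' Emits the participant table and feeding diaries as CSV, analyte matrices
#' as wide CSV (first column the sample id), panel metadata as TSV, and a
#' ground-truth JSON (planted effects, batch offsets, sampling
#' probabilities) usable as a test oracle.
#'
#' @param cohort A [LactationCohort-class].
#' @param omics Optional named list of [AnalyteExperiment-class] objects.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
writeCohortArtifacts <- function(cohort, omics = NULL, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character()
  f <- file.path(dir, "participants.csv")
  utils::write.csv(participants(cohort), f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "feeding_diaries.csv")
  utils::write.csv(diaries(cohort), f, row.names = FALSE)
  files <- c(files, f)
  gt <- list(samplingProb = as.list(samplingProbs(cohort)))
  for (nm in names(omics)) {
    ae <- omics[[nm]]
    wide <- data.frame(sample = colnames(ae),
                       t(assay(ae, "abundance")), check.names = FALSE)
    f <- file.path(dir, paste0("analytes_", nm, ".csv"))
    utils::write.csv(wide, f, row.names = FALSE)
    files <- c(files, f)
    f <- file.path(dir, paste0("panel_", nm, ".tsv"))
    utils::write.table(as.data.frame(rowData(ae)), f, sep = "\t",
                       quote = FALSE, row.names = TRUE)
    files <- c(files, f)
    gt[[paste0("groundTruth_", nm)]] <- lapply(
      metadata(ae)$groundTruth,
      function(x) if (is.numeric(x) || is.character(x)) as.list(x) else x)
  }
  f <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(gt, f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  invisible(files)
}
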