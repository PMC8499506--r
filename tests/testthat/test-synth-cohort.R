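test_that("the seed fully determines the simulated cohort and omics", {
  cfg <- simConfig(nCohort = 120, nCases = 15, nControls = 20, seed = 42)
  c1 <- simulateCohort(cfg)
  c2 <- simulateCohort(cfg)
  expect_identical(participants(c1), participants(c2))
  expect_identical(diaries(c1), diaries(c2))

  s1 <- nestedCaseControlSample(c1, 15, 20, seed = 3)
  s2 <- nestedCaseControlSample(c2, 15, 20, seed = 3)
  expect_identical(participants(s1), participants(s2))

  panel <- metabolomicsPanel(scale = 0.1)
  o1 <- simulateOmics(s1, panel, cfg)
  o2 <- simulateOmics(s2, panel, cfg)
  expect_identical(SummarizedExperiment::assay(o1$baseline),
                   SummarizedExperiment::assay(o2$baseline))
  expect_identical(SummarizedExperiment::assay(o1$followup),
                   SummarizedExperiment::assay(o2$followup))
})

test_that("incident-T2D assignment respects the configured rate", {
  none <- simulateCohort(simConfig(nCohort = 200, nCases = 0,
                                   nControls = 0, t2dRate = 0, seed = 1))
  expect_equal(sum(participants(none)$futureT2d), 0)

  coh <- simulateCohort(simConfig(nCohort = 1000, nCases = 100,
                                  nControls = 100, t2dRate = 0.17,
                                  seed = 7))
  cnt <- sum(participants(coh)$futureT2d)
  # the per-participant rates are a two-point mixture with marginal 0.17,
  # so the count is Binomial(1000, 0.17) marginally
  bounds <- qbinom(c(0.0005, 0.9995), 1000, 0.17)
  expect_gte(cnt, bounds[1])
  expect_lte(cnt, bounds[2])
})

test_that("case-control sampling yields exact, known probabilities", {
  coh <- simulateCohort(simConfig(nCohort = 500, nCases = 60,
                                  nControls = 60, t2dRate = 0.2, seed = 9))
  nCasesAvail <- sum(participants(coh)$futureT2d)
  sub <- nestedCaseControlSample(coh, nCasesAvail, 100, seed = 2)
  p <- participants(sub)
  expect_equal(nrow(p), nCasesAvail + 100)
  expect_true(all(p$samplingProb[p$futureT2d] == 1))
  expect_true(all(p$samplingProb > 0 & p$samplingProb <= 1))

  expect_error(nestedCaseControlSample(coh, nCasesAvail + 1, 10),
               "only")
  expect_error(nestedCaseControlSample(coh, 1, 10000), "only")
})

test_that("controls identical on matching variables get probability k/n", {
  part <- data.frame(
    id = sprintf("P%02d", 1:30), age = 34, prepregBMI = 32,
    race = "asian", ogttZsum = 0, gdmTreatment = "diet",
    glucoseTolerance = "NGT",
    futureT2d = rep(c(TRUE, FALSE), c(10, 20)),
    followupMonths = 50, lactationDuration = 6,
    samplingProb = NA_real_, stringsAsFactors = FALSE)
  diary <- data.frame(id = rep(part$id, each = 2), month = c(1, 2),
                      breastFeeds = 8, formulaFeeds = 0, formulaOz = 0)
  coh <- new("LactationCohort", participants = part, diaries = diary,
             metadata = list())
  sub <- nestedCaseControlSample(coh, 10, 5, seed = 4)
  ctrl <- participants(sub)[!participants(sub)$futureT2d, ]
  expect_equal(nrow(ctrl), 5)
  expect_true(all(ctrl$samplingProb == 5 / 20))
})

test_that("inverse-probability weights recover full-cohort stratum counts", {
  # Horvitz-Thompson identity, Monte-Carlo over repeated control draws
  coh <- simulateCohort(simConfig(nCohort = 400, nCases = 40,
                                  nControls = 80, t2dRate = 0.18,
                                  seed = 21))
  full <- participants(coh)
  # request every case so the per-bin quotas are identical across draws;
  # controls in bins with quota zero have inclusion probability 0, and the
  # estimator is unbiased for counts over the covered strata only
  nCasesAvail <- sum(full$futureT2d)
  quota <- nestedCaseControlSample(coh, nCasesAvail, 80,
                                   seed = 1)@metadata$sampling$quota
  bins <- lactomics:::.matchingBins(full, c("age", "prepregBMI", "race"))
  covered <- !full$futureT2d & bins %in% names(quota)[quota > 0]
  trueNGT <- sum(covered & full$glucoseTolerance == "NGT")
  est <- vapply(1:150, function(s) {
    sub <- nestedCaseControlSample(coh, nCasesAvail, 80, seed = s)
    p <- participants(sub)
    ctrl <- p[!p$futureT2d & p$glucoseTolerance == "NGT", ]
    sum(1 / ctrl$samplingProb)
  }, numeric(1))
  expect_lt(abs(mean(est) - trueNGT) / trueNGT, 0.03)
})

test_that("planted class effects appear in the simulated abundances", {
  st <- simulateSmallStudy(seed = 31, nCohort = 600, nCases = 100,
                           nControls = 100,
                           effectMap = c(TAG = -0.5),
                           panel = tagPanel141())
  ae <- st$omics$baseline
  x <- log2(SummarizedExperiment::assay(ae, "abundance"))
  cd <- SummarizedExperiment::colData(ae)
  keep <- !cd$isControl
  g <- cd$feedingGroup[keep]
  d <- rowMeans(x[, keep][, g == "IBF"], na.rm = TRUE) -
    rowMeans(x[, keep][, g == "IFF/Mixed"], na.rm = TRUE)
  tagIdx <- analyteClass(ae) == "TAG"
  expect_lt(abs(mean(d[tagIdx]) - (-0.5)), 0.15)
  # null classes centered at zero
  expect_lt(abs(mean(d[!tagIdx])), 0.1)
})

test_that("null generator centers group differences at zero", {
  st <- simulateSmallStudy(seed = 13, effectMap = c(none = 0))
  ae <- st$omics$baseline
  x <- log2(SummarizedExperiment::assay(ae, "abundance"))
  cd <- SummarizedExperiment::colData(ae)
  keep <- !cd$isControl
  g <- cd$feedingGroup[keep]
  d <- rowMeans(x[, keep][, g == "IBF"], na.rm = TRUE) -
    rowMeans(x[, keep][, g == "IFF/Mixed"], na.rm = TRUE)
  expect_lt(abs(mean(d)), 0.05)
})

test_that("per-analyte missingness overrides make an analyte fully missing", {
  panel <- metabolomicsPanel(scale = 0.1)
  panel$missingRate <- NA_real_
  panel$missingRate[1] <- 1
  st <- simulateSmallStudy(seed = 17, panel = panel)
  a <- SummarizedExperiment::assay(st$omics$baseline, "abundance")
  samples <- !SummarizedExperiment::colData(st$omics$baseline)$isControl
  expect_true(all(is.na(a[1, samples])))
  expect_false(anyNA(a[-1, samples]))  # metab MCAR rate 0 in this fixture
})

test_that("cohort artifacts are written as plain-text files", {
  st <- simulateSmallStudy(seed = 23, nCohort = 80, nCases = 8,
                           nControls = 10,
                           panel = metabolomicsPanel(scale = 0.05))
  dir <- withr::local_tempdir()
  files <- writeCohortArtifacts(st$subset, st$omics, dir)
  expect_true(all(file.exists(files)))
  expect_true(any(grepl("ground_truth.json", files)))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_true(all(unlist(gt$samplingProb) > 0))
})
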