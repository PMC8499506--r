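test_that("sampling weights are inverse probabilities", {
  expect_equal(unname(samplingWeights(c(a = 0.5, b = 1))), c(2, 1))
  expect_error(samplingWeights(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(samplingWeights(c(0.5, NA)), "\\(0, 1\\]")
})

test_that("BH adjustment matches a brute-force step-up reference", {
  expect_equal(bhFDR(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhFDR(0.2), 0.2)
  set.seed(33)
  for (i in 1:200) {
    p <- runif(sample(1:20, 1))
    q <- bhFDR(p)
    expect_equal(q, bruteForceBH(p))
    expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in sorted p
    expect_true(all(q >= p - 1e-15))
  }
  expect_error(bhFDR(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("with unit weights the group test equals the classical linear model", {
  set.seed(3)
  n <- 24
  x <- matrix(rnorm(3 * n), 3, n)
  g <- factor(rep(c("A", "B"), each = n / 2))
  cov <- data.frame(bmi = rnorm(n))
  de <- weightedDiffAbundance(x, g, cov, weights = rep(1, n))
  for (i in 1:3) {
    d <- data.frame(y = x[i, ], g = g, bmi = cov$bmi)
    oracle <- anova(lm(y ~ bmi, d), lm(y ~ g + bmi, d))[2, "Pr(>F)"]
    expect_equal(de$p[i], oracle, tolerance = 1e-12)
  }
  # constant rescaling of weights does not change the fit
  de2 <- weightedDiffAbundance(x, g, cov, weights = rep(7, n))
  expect_equal(de$p, de2$p, tolerance = 1e-12)
  expect_equal(de$log2FC, de2$log2FC, tolerance = 1e-12)
})

test_that("complete-data fast path agrees with the per-analyte fit", {
  set.seed(4)
  n <- 30
  x <- matrix(rnorm(6 * n), 6, n)
  g <- factor(rep(c("A", "B"), each = n / 2))
  w <- runif(n, 1, 5)
  cov <- data.frame(z = rnorm(n))
  fast <- weightedDiffAbundance(x, g, cov, w)
  xna <- x
  xna[6, 1] <- NA  # one missing cell forces the per-analyte route
  slow <- weightedDiffAbundance(xna, g, cov, w)
  expect_equal(fast$p[1:5], slow$p[1:5], tolerance = 1e-10)
  expect_equal(fast$log2FC[1:5], slow$log2FC[1:5], tolerance = 1e-10)
})

test_that("fold change is reported for IBF relative to the reference group", {
  set.seed(6)
  n <- 40
  x <- matrix(rnorm(2 * n, sd = 0.2), 2, n)  # low noise: sign is the point
  g <- factor(rep(c("IBF", "IFF/Mixed"), each = n / 2))
  x[1, g == "IBF"] <- x[1, g == "IBF"] - 1
  de <- weightedDiffAbundance(x, g)
  expect_lt(de$log2FC[1], -0.5)
  expect_identical(de$direction[1], "down")
})

test_that("degenerate analytes are flagged, not fatal", {
  n <- 20
  x <- matrix(rnorm(2 * n), 2, n)
  x[1, ] <- 5  # zero variance
  g <- factor(rep(c("A", "B"), each = n / 2))
  de <- weightedDiffAbundance(x, g)
  expect_identical(de$status[1], "degenerate")
  expect_true(is.na(de$p[1]))
  expect_identical(de$status[2], "ok")
})

test_that("stratified analysis reduces to the unstratified run and skips", {
  set.seed(8)
  n <- 36
  x <- matrix(rnorm(4 * n), 4, n)
  g <- factor(rep(c("A", "B"), n / 2))
  one <- weightedDiffAbundance(x, g)
  strat <- stratifiedDiffAbundance(x, strata = rep("all", n), group = g)
  expect_equal(strat$all$p, one$p)
  expect_equal(strat$all$FDR, one$FDR)

  # a stratum with one group level is skipped with a warning
  s2 <- c(rep("good", n - 4), rep("solo", 4))
  g2 <- g
  g2[s2 == "solo"] <- "A"
  expect_warning(res <- stratifiedDiffAbundance(x, s2, g2),
                 "single group level")
  expect_named(res, "good")
})

test_that("planted attenuation yields fewer discoveries in the T2D stratum", {
  st <- simulateSmallStudy(seed = 44, nCohort = 800, nCases = 130,
                           nControls = 130,
                           effectMap = c(TAG = -0.8),
                           panel = tagPanel141(), attenuationT2d = 0.2)
  ae <- st$omics$baseline
  pp <- preprocessPanel(ae, threshold = 0.40)
  cd <- as.data.frame(SummarizedExperiment::colData(pp))
  keep <- !cd$isControl
  x <- SummarizedExperiment::assay(pp, "log2norm")[, keep]
  res <- stratifiedDiffAbundance(
    x, strata = ifelse(cd$futureT2d[keep], "futureT2D", "noT2D"),
    group = cd$feedingGroup[keep],
    weights = samplingWeights(cd$samplingProb[keep]))
  nT2d <- sum(res$futureT2D$FDR < 0.05, na.rm = TRUE)
  nNo <- sum(res$noT2D$FDR < 0.05, na.rm = TRUE)
  expect_lt(nT2d, nNo)
  expect_gt(nNo, 0)
})
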