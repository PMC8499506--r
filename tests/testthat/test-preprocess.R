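test_that("missingness filter removes analytes strictly above the threshold", {
  vals <- matrix(rlnorm(5 * 20), 5, 20)
  vals[1, 1:9] <- NA    # 45% missing -> removed at 0.40
  vals[2, 1:8] <- NA    # exactly 40% -> retained (strict >)
  ae <- filterMissingness(toyAE(vals), threshold = 0.40)
  expect_false("a1" %in% rownames(ae))
  expect_true("a2" %in% rownames(ae))

  lip <- matrix(rlnorm(2 * 100), 2, 100)
  lip[1, 1:6] <- NA     # 6% missing -> removed at the lipidomics 5% rule
  aeL <- filterMissingness(toyAE(lip), threshold = 0.05)
  expect_false("a1" %in% rownames(aeL))
  expect_true("a2" %in% rownames(aeL))

  allBad <- matrix(NA_real_, 2, 4)
  allBad[, 1] <- 1
  expect_warning(filterMissingness(toyAE(allBad), 0.40), "empty")
})

test_that("longitudinal filter drops an analyte from both timepoints", {
  b <- matrix(rlnorm(3 * 10), 3, 10)
  f <- matrix(rlnorm(3 * 10), 3, 10)
  f[2, 1:5] <- NA  # 50% missing at follow-up only
  filt <- filterMissingnessLongitudinal(toyAE(b), toyAE(f), 0.40)
  expect_identical(rownames(filt$baseline), rownames(filt$followup))
  expect_false("a2" %in% rownames(filt$baseline))
  expect_true(all(c("a1", "a3") %in% rownames(filt$followup)))

  disjointB <- toyAE(matrix(1, 1, 2))
  disjointF <- toyAE(matrix(1, 1, 2))
  rownames(disjointF) <- "zz"
  expect_error(filterMissingnessLongitudinal(disjointB, disjointF),
               "no analytes")
})

test_that("a 188-analyte fixture filters down to its built-in 130 survivors", {
  set.seed(5)
  nS <- 40
  vals <- matrix(rlnorm(188 * nS), 188, nS,
                 dimnames = list(sprintf("m%03d", 1:188), NULL))
  valsF <- matrix(rlnorm(188 * nS), 188, nS,
                  dimnames = list(sprintf("m%03d", 1:188), NULL))
  # plant failures: 30 analytes fail at baseline, 28 more at follow-up
  vals[1:30, seq_len(ceiling(0.5 * nS))] <- NA
  valsF[31:58, seq_len(ceiling(0.5 * nS))] <- NA
  filt <- filterMissingnessLongitudinal(toyAE(vals), toyAE(valsF), 0.40)
  expect_equal(nrow(filt$baseline), 130)
  expect_equal(nrow(filt$followup), 130)
})

test_that("half-LOD imputation fills exactly the missing cells", {
  vals <- matrix(c(NA, 0.5, 0.7, 0.9), 2, 2)
  ae <- toyAE(vals, lods = c(0.2, 5))
  imp <- imputeHalfLOD(ae)
  a <- SummarizedExperiment::assay(imp, "abundance")
  expect_equal(a[1, 1], 0.1)
  expect_equal(a[1, 2], 0.7)
  expect_equal(a[2, ], c(s1 = 0.5, s2 = 0.9))
  expect_equal(sum(SummarizedExperiment::assay(imp, "imputed")), 1)

  # missing LOD only matters when imputation is needed
  okNoLod <- toyAE(matrix(c(1, 2, 3, 4), 2), lods = c(NA, NA))
  expect_s4_class(imputeHalfLOD(okNoLod), "AnalyteExperiment")
  bad <- toyAE(matrix(c(NA, 2, 3, 4), 2), lods = c(NA, 1))
  expect_error(imputeHalfLOD(bad), "no usable LOD")
})

test_that("normalization divides by sample totals, logs, and centers", {
  vals <- matrix(c(1, 1, 2, 2, 2, 4), 3, 2,
                 dimnames = list(paste0("a", 1:3), c("s1", "s2")))
  ae <- normalizeTotalSum(toyAE(vals))
  l2 <- SummarizedExperiment::assay(ae, "log2norm")
  expect_equal(2^l2[, "s1"], c(a1 = 0.25, a2 = 0.25, a3 = 0.5))
  # s2 is a scalar multiple of s1 -> identical normalized columns
  expect_equal(l2[, "s1"], l2[, "s2"])
  norm <- SummarizedExperiment::assay(ae, "normalized")
  expect_true(all(abs(rowMeans(norm)) < 1e-12))
  # pre-log per-sample totals equal one
  expect_equal(unname(colSums(2^l2)), c(1, 1))

  withNeg <- toyAE(matrix(c(1, 2, 3, 4), 2))
  SummarizedExperiment::assay(withNeg, "abundance")[2, 1] <- -1
  expect_error(normalizeTotalSum(withNeg), "a2")
  expect_error(normalizeTotalSum(toyAE(matrix(c(NA, 1, 2, 3), 2))),
               "impute")
})

test_that("internal-control batch correction recovers planted offsets", {
  st <- simulateSmallStudy(seed = 8, nCohort = 150, nCases = 20,
                           nControls = 25, batchOffsetSd = 0.4,
                           panel = metabolomicsPanel(scale = 0.1))
  b <- st$omics$baseline
  f <- st$omics$followup
  truth <- S4Vectors::metadata(f)$groundTruth$batchOffset
  bc <- batchCorrect(b, f)   # log2 abundance scale; control is noiseless
  expect_equal(unname(bc$offset), unname(truth[rownames(b)]),
               tolerance = 1e-12)
  la <- SummarizedExperiment::assays(bc$followup)$log2corrected
  expect_equal(la[, "IC"], log2(SummarizedExperiment::assay(b))[, "IC"],
               tolerance = 1e-12)

  # zero offset leaves follow-up unchanged
  bc0 <- batchCorrect(b, b)
  expect_true(all(abs(bc0$offset) < 1e-12))

  noIC <- b[, colnames(b) != "IC"]
  expect_error(batchCorrect(b, noIC), "missing from a batch")
})

test_that("separation check rejects planted separation, keeps the null level", {
  set.seed(101)
  # planted: 2 SD shift on 30% of analytes
  n <- 15; p <- 30
  x <- rbind(matrix(rnorm(n * p), n, p),
             matrix(rnorm(n * p), n, p))
  x[seq_len(n), seq_len(ceiling(0.3 * p))] <-
    x[seq_len(n), seq_len(ceiling(0.3 * p))] + 2
  g <- rep(c("A", "B"), each = n)
  res <- separationCheck(x, g, nPerm = 199, seed = 1)
  expect_lt(res$pValue, 0.05)

  # null calibration: rejection rate at 0.05 stays within binomial bounds
  rej <- vapply(1:50, function(s) {
    set.seed(s + 500)
    xn <- matrix(rnorm(2 * n * 20), 2 * n, 20)
    separationCheck(xn, g, nPerm = 99, seed = s)$pValue < 0.05
  }, logical(1))
  bounds <- qbinom(c(0.005, 0.995), 50, 0.05)
  expect_gte(sum(rej), bounds[1])
  expect_lte(sum(rej), bounds[2])

  expect_error(separationCheck(x, rep("A", 2 * n)), "two groups")
  expect_error(separationCheck(x[1:4, ], c("A", "A", "B", "B")),
               "at least 3")
})
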