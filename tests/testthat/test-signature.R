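test_that("hold-out split reserves exactly the requested per-class sizes", {
  labels <- factor(rep(c("T2D", "noT2D"), c(98, 118)))
  sp <- splitHoldout(labels, 25, seed = 1)
  expect_equal(as.vector(table(labels[sp$test])), c(25, 25))
  expect_equal(as.vector(table(labels[sp$train])), c(98 - 25, 118 - 25))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_equal(sort(c(sp$train, sp$test)), seq_along(labels))

  sp2 <- splitHoldout(labels, 25, seed = 1)
  expect_identical(sp, sp2)
  expect_error(splitHoldout(factor(rep(c("a", "b"), c(25, 40))), 25),
               "more than")
})

test_that("down-sampling balances at the minority class size", {
  labels <- factor(rep(c("T2D", "noT2D"), c(73, 93)))
  bal <- downsampleBalance(labels, seed = 2)
  expect_equal(as.vector(table(labels[bal])), c(73, 73))

  even <- factor(rep(c("x", "y"), each = 5))
  expect_setequal(downsampleBalance(even), 1:10)

  tiny <- factor(rep(c("x", "y"), c(1, 100)))
  expect_equal(as.vector(table(tiny[downsampleBalance(tiny, seed = 1)])),
               c(1, 1))
  expect_error(downsampleBalance(factor(rep("x", 5))), "both classes")
})

test_that("feature selection takes strictly sub-threshold FDR analytes", {
  de <- data.frame(analyte = paste0("m", 1:100),
                   FDR = c(rep(0.01, 69), rep(0.05, 31)))
  expect_length(selectInputFeatures(de), 69)   # 0.05 itself excluded
  expect_error(selectInputFeatures(data.frame(analyte = "m", FDR = 0.9)),
               "cannot run")
})

test_that("repeated selection conserves frequencies and finds separators", {
  set.seed(12)
  n <- 80
  x <- matrix(rnorm(n * 12), n, 12,
              dimnames = list(NULL, paste0("f", 1:12)))
  labels <- factor(rep(c("ctl", "case"), each = n / 2),
                   levels = c("ctl", "case"))
  x[labels == "case", 1] <- x[labels == "case", 1] + 10  # perfect separator
  cfg <- signatureConfig(nRepeats = 20, holdoutPerClass = 10,
                         topKLogged = 5, signatureSize = 3, nTrees = 100,
                         seed = 5)
  sel <- repeatedSelection(x, labels, cfg)
  expect_equal(sum(sel$frequency), 20 * 5)
  expect_equal(unname(sel$frequency["f1"]), 20)
  expect_equal(sel$skipped, 0)
  sig <- finalizeSignature(sel, 3)
  expect_identical(sig[1], "f1")

  # bit-for-bit reproducibility under the master seed
  sel2 <- repeatedSelection(x, labels, cfg)
  expect_identical(sel$frequency, sel2$frequency)
  expect_identical(finalizeSignature(sel2, 3), sig)
})

test_that("signature finalization breaks ties deterministically", {
  freq <- c(a = 10, b = 10, c = 5, d = 5, e = 1)
  rank <- c(a = 2, b = 1, c = 4, d = 4, e = 5)
  sig <- finalizeSignature(list(frequency = freq,
                                meanImportanceRank = rank), 3)
  expect_identical(sig, c("b", "a", "c"))  # rank, then name, decides ties
  expect_error(finalizeSignature(list(frequency = c(a = 1, b = 0),
                                      meanImportanceRank = rank), 2),
               "nonzero frequency")
})

test_that("the hold-out never leaks into selection", {
  ps <- plantedFeatureSet(seed = 77, nCase = 40, nCtrl = 48, nNoise = 15,
                          nSignal = 5)
  cfg <- signatureConfig(nRepeats = 15, holdoutPerClass = 10,
                         topKLogged = 8, signatureSize = 5, nTrees = 150,
                         seed = 9)
  sel <- repeatedSelection(ps$x, ps$labels, cfg)
  # corrupt a noise feature on hold-out samples only
  x2 <- ps$x
  x2[sel$split$test, "noise1"] <-
    ifelse(ps$labels[sel$split$test] == "T2D", 100, -100)
  sel2 <- repeatedSelection(x2, ps$labels, cfg)
  expect_identical(sel$frequency, sel2$frequency)
  expect_identical(finalizeSignature(sel, 5), finalizeSignature(sel2, 5))
})

test_that("evaluation reports medians and percentile intervals", {
  ps <- plantedFeatureSet(seed = 21, nCase = 40, nCtrl = 48, nNoise = 10,
                          nSignal = 5, delta = 4)  # near-separable
  cfg <- signatureConfig(nRepeats = 10, holdoutPerClass = 10,
                         topKLogged = 8, signatureSize = 5, nTrees = 150,
                         seed = 3)
  ev <- evaluateSignature(ps$planted, ps$x, ps$labels, cfg)
  expect_equal(dim(ev$metrics), c(10, 6))
  expect_true(all(ev$metrics >= 0 & ev$metrics <= 1, na.rm = TRUE))
  expect_equal(unname(ev$summary["median", "AUC"]), 1.0, tolerance = 0.01)
  expect_true(ev$summary["lower", "AUC"] <= ev$summary["median", "AUC"])

  clin <- matrix(rnorm(nrow(ps$x) * 2), ncol = 2,
                 dimnames = list(rownames(ps$x), c("FPG", "PG2h")))
  ev2 <- evaluateSignature(ps$planted, ps$x, ps$labels, cfg,
                           clinicalBaselines = clin)
  expect_named(ev2$baselines, c("FPG", "PG2h"))
  expect_true(all(vapply(ev2$baselines, function(b)
    b[["AUC"]] >= 0 && b[["AUC"]] <= 1, logical(1))))
  expect_false(is.null(ev2$combined))

  expect_error(evaluateSignature(c("absent"), ps$x, ps$labels, cfg),
               "absent")
})
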