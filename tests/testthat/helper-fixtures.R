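# fixtures built in code; no files

# tiny AnalyteExperiment with fully controlled values
toyAE <- function(values, classes = NULL, lods = NULL, timepoint = "baseline",
                  controlCol = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("a", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  if (is.null(classes)) classes <- rep("AA", nrow(values))
  if (is.null(lods)) lods <- rep(0.2, nrow(values))
  cd <- S4Vectors::DataFrame(
    timepoint = timepoint,
    isControl = colnames(values) %in% controlCol,
    row.names = colnames(values))
  AnalyteExperiment(values, analyteClass = classes, lod = lods,
                    colData = cd)
}

# small synthetic subset + omics with chosen effect map
simulateSmallStudy <- function(seed, nCohort = 300, nCases = 50,
                               nControls = 60, effectMap = c(TAG = 0),
                               panel = NULL, attenuationT2d = 1,
                               missingRateMetab = 0,
                               batchOffsetSd = 0.3) {
  cfg <- simConfig(nCohort = nCohort, nCases = nCases,
                   nControls = nControls, effectMap = effectMap,
                   attenuationT2d = attenuationT2d,
                   missingRateMetab = missingRateMetab,
                   batchOffsetSd = batchOffsetSd, seed = seed)
  coh <- simulateCohort(cfg)
  # incident counts are stochastic; never request more than are available
  avail <- sum(participants(coh)$futureT2d)
  sub <- nestedCaseControlSample(coh, min(nCases, avail),
                                 min(nControls, nrow(participants(coh)) - avail),
                                 seed = seed)
  if (is.null(panel)) panel <- metabolomicsPanel(scale = 0.25)
  list(config = cfg, cohort = coh, subset = sub, panel = panel,
       omics = simulateOmics(sub, panel, cfg))
}

# a 141-analyte panel in which 12 TAG lipids can carry a planted effect
tagPanel141 <- function() {
  tag <- data.frame(
    analyte = paste0("TAG", seq(40, 62, by = 2), ":",
                     rep(2:3, length.out = 12)),
    class = "TAG", stringsAsFactors = FALSE)
  other <- data.frame(
    analyte = paste0("PC", seq_len(129) + 27, ":",
                     rep(0:4, length.out = 129)),
    class = "PC", stringsAsFactors = FALSE)
  panel <- rbind(tag, other)
  panel$analyte <- make.unique(panel$analyte, sep = "_")
  panel$lod <- 0.001
  panel
}

# brute-force Benjamini-Hochberg: sort, p*m/rank, cumulative min, unsort
bruteForceBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# design-weighted group labels and matrix for signature tests
plantedFeatureSet <- function(seed, nNoise = 59, nSignal = 10,
                              delta = 0.8, nCase = 98, nCtrl = 118) {
  set.seed(seed)
  n <- nCase + nCtrl
  p <- nNoise + nSignal
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%03d", seq_len(n)),
                              c(paste0("sig", seq_len(nSignal)),
                                paste0("noise", seq_len(nNoise)))))
  labels <- factor(rep(c("noT2D", "T2D"), c(nCtrl, nCase)),
                   levels = c("noT2D", "T2D"))
  x[labels == "T2D", seq_len(nSignal)] <-
    x[labels == "T2D", seq_len(nSignal)] + delta
  list(x = x, labels = labels,
       planted = paste0("sig", seq_len(nSignal)))
}
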