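#' Drop analytes exceeding a missingness threshold
#'
#' Removes analytes whose fraction of missing samples is strictly greater
#' than `threshold` (the published rules: above 40% for the metabolomic
#' panel, above 5% for the lipidomic panel at baseline). Internal-control
#' samples are excluded from the missingness denominator.
#'
#' @param ae An [AnalyteExperiment-class].
#' @param threshold Fraction in (0, 1).
#' @return Filtered [AnalyteExperiment-class]; the removed analytes are
#'   recorded in `metadata(ae)$removedAnalytes`.
#' @export
filterMissingness <- function(ae, threshold = 0.40) {
  stopifnot(is(ae, "AnalyteExperiment"), threshold > 0, threshold < 1)
  keepCols <- !.controlMask(ae)
  frac <- rowMeans(is.na(assay(ae, "abundance")[, keepCols, drop = FALSE]))
  drop <- frac > threshold
  if (all(drop))
    warning("all analytes exceed the missingness threshold; ",
            "returning an empty panel")
  out <- ae[!drop, ]
  metadata(out)$removedAnalytes <- c(metadata(ae)$removedAnalytes,
                                     list(rownames(ae)[drop]))
  out
}

.controlMask <- function(ae) {
  cd <- colData(ae)
  if ("isControl" %in% names(cd)) as.logical(cd$isControl) %in% TRUE
  else rep(FALSE, ncol(ae))
}

#' Longitudinal missingness filter across two timepoints
#'
#' An analyte whose missing fraction exceeds `threshold` at either baseline
#' or follow-up is removed from both tables, so the retained analyte sets
#' are identical (the published rule that left 130 of 188 metabolites).
#'
#' @param baseline,followup [AnalyteExperiment-class] objects sharing an
#'   analyte namespace.
#' @param threshold Fraction in (0, 1).
#' @return List with filtered `baseline` and `followup`.
#' @export
filterMissingnessLongitudinal <- function(baseline, followup,
                                          threshold = 0.40) {
  common <- intersect(rownames(baseline), rownames(followup))
  if (!length(common))
    stop("baseline and follow-up share no analytes")
  b <- baseline[common, ]
  f <- followup[common, ]
  fracB <- rowMeans(is.na(assay(b, "abundance")[, !.controlMask(b),
                                                drop = FALSE]))
  fracF <- rowMeans(is.na(assay(f, "abundance")[, !.controlMask(f),
                                                drop = FALSE]))
  keep <- fracB <= threshold & fracF <= threshold
  list(baseline = b[keep, ], followup = f[keep, ])
}

#' Half-LOD imputation of missing measurements
#'
#' Replaces every missing cell with half the analyte's limit of detection.
#' Analytes that need imputation must have a finite positive LOD; fully
#' observed analytes may lack one. The imputation mask is kept as the
#' logical assay `"imputed"`.
#'
#' @param ae An [AnalyteExperiment-class].
#' @return The imputed [AnalyteExperiment-class].
#' @export
imputeHalfLOD <- function(ae) {
  stopifnot(is(ae, "AnalyteExperiment"))
  a <- assay(ae, "abundance")
  mask <- is.na(a)
  lodv <- lod(ae)
  needs <- rowSums(mask) > 0
  bad <- needs & (!is.finite(lodv) | lodv <= 0)
  if (any(bad))
    stop("missing values but no usable LOD for: ",
         paste(rownames(ae)[bad], collapse = ", "))
  a[mask] <- (lodv / 2)[row(a)[mask]]
  assay(ae, "abundance") <- a
  SummarizedExperiment::assays(ae)$imputed <- mask
  ae
}

#' Total-sum normalization, log2 transform, mean-centering
#'
#' The fixed preprocessing order: (1) divide each sample's values by that
#' sample's total, (2) log2-transform, (3) subtract each analyte's mean
#' across samples. The pre-centering log2 values are kept as assay
#' `"log2norm"` (group differences of these are log2 fold changes; the
#' centering step cancels in any group contrast) and the centered values as
#' assay `"normalized"`.
#'
#' @param ae An [AnalyteExperiment-class] with no missing values (run
#'   [imputeHalfLOD()] first).
#' @param center Subtract per-analyte means (default `TRUE`).
#' @return The [AnalyteExperiment-class] with assays added.
#' @export
normalizeTotalSum <- function(ae, center = TRUE) {
  stopifnot(is(ae, "AnalyteExperiment"))
  a <- assay(ae, "abundance")
  if (anyNA(a))
    stop("missing values present; impute before normalizing")
  if (any(a <= 0)) {
    bad <- which(a <= 0, arr.ind = TRUE)[1, ]
    stop("nonpositive value at analyte '", rownames(a)[bad[1]],
         "', sample '", colnames(a)[bad[2]], "' cannot be log-transformed")
  }
  tot <- colSums(a)
  l2 <- log2(sweep(a, 2, tot, "/"))
  SummarizedExperiment::assays(ae)$log2norm <- l2
  SummarizedExperiment::assays(ae)$normalized <-
    if (center) l2 - rowMeans(l2) else l2
  ae
}

#' Internal-control batch correction between two batches
#'
#' Computes, per analyte, the log2 offset between the internal-control
#' sample's value in the follow-up batch and in the baseline batch, and
#' subtracts it from every follow-up sample. After correction the control's
#' values agree across batches by construction.
#'
#' @param baseline,followup [AnalyteExperiment-class] objects sharing an
#'   analyte set, each containing the control sample.
#' @param controlId Column name of the shared internal control.
#' @param assayName Log-scale assay to correct (default `"log2norm"`, fall
#'   back to log2 of `"abundance"` when absent).
#' @return List with `baseline`, corrected `followup`, and the per-analyte
#'   `offset` that was removed.
#' @export
batchCorrect <- function(baseline, followup, controlId = "IC",
                         assayName = NULL) {
  if (!identical(rownames(baseline), rownames(followup)))
    stop("baseline and follow-up analyte sets differ; filter first")
  for (tb in list(baseline, followup))
    if (!controlId %in% colnames(tb))
      stop("internal control '", controlId, "' missing from a batch")
  getLog <- function(ae) {
    nms <- SummarizedExperiment::assayNames(ae)
    if (!is.null(assayName)) return(assay(ae, assayName))
    if ("log2norm" %in% nms) assay(ae, "log2norm") else
      log2(assay(ae, "abundance"))
  }
  lb <- getLog(baseline)
  lf <- getLog(followup)
  offset <- lf[, controlId] - lb[, controlId]
  lfCorr <- lf - offset
  usedName <- if (!is.null(assayName)) assayName else if ("log2norm" %in%
    SummarizedExperiment::assayNames(followup)) "log2norm" else "log2corrected"
  SummarizedExperiment::assays(followup)[[usedName]] <- lfCorr
  if ("normalized" %in% SummarizedExperiment::assayNames(followup))
    SummarizedExperiment::assays(followup)$normalized <-
      lfCorr - rowMeans(lfCorr)
  list(baseline = baseline, followup = followup,
       offset = stats::setNames(offset, rownames(followup)))
}

# two-component PLS scores by NIPALS on the class-indicator response;
# deterministic and cheap enough to refit inside the permutation loop
.plsScores <- function(x, y, ncomp = 2L) {
  yn <- scale(stats::model.matrix(~ y - 1), center = TRUE, scale = FALSE)
  xc <- scale(x, center = TRUE, scale = FALSE)
  scores <- matrix(0, nrow(x), ncomp)
  for (k in seq_len(ncomp)) {
    cp <- crossprod(xc, yn)
    sv <- svd(cp, nu = 1, nv = 0)
    if (sv$d[1] < 1e-12) break
    w <- sv$u[, 1]
    t_ <- xc %*% w
    p_ <- crossprod(xc, t_) / sum(t_^2)
    xc <- xc - tcrossprod(t_, p_)
    scores[, k] <- t_
  }
  scores
}

.separationStat <- function(scores, y) {
  cent <- rowsum(scores, y) / as.numeric(table(y))
  within <- mean(sqrt(rowSums((scores - cent[y, , drop = FALSE])^2)))
  levs <- rownames(cent)
  between <- mean(stats::dist(cent))
  between / max(within, 1e-12)
}

#' Permutation test of group separation
#'
#' Fits a two-component projection discriminant (PLS-style: latent
#' components maximizing covariance with the group indicator) and scores
#' separation as the ratio of between-group centroid distance to mean
#' within-group distance in the 2-D score space. Significance is the
#' empirical permutation p-value
#' `(1 + #\{permuted >= observed\}) / (1 + nPerm)` under random relabelling.
#'
#' @param ae An [AnalyteExperiment-class] (assay `"normalized"` used when
#'   present, else log2 abundance) or a samples x analytes numeric matrix.
#' @param groups Factor of group labels (>= 2 levels, each with >= 3
#'   samples).
#' @param nPerm Number of permutations (default 1000, as published).
#' @param seed Seed for the permutations.
#' @return List with `statistic`, `pValue`, and the `nPerm` used.
#' @export
separationCheck <- function(ae, groups, nPerm = 1000, seed = 1L) {
  x <- if (is(ae, "AnalyteExperiment")) {
    nms <- SummarizedExperiment::assayNames(ae)
    keep <- !.controlMask(ae)
    m <- if ("normalized" %in% nms) assay(ae, "normalized") else
      log2(assay(ae, "abundance"))
    t(m[, keep, drop = FALSE])
  } else as.matrix(ae)
  groups <- factor(groups)
  if (nlevels(groups) < 2)
    stop("at least two groups are required")
  if (any(table(groups) < 3))
    stop("every group needs at least 3 samples")
  if (length(groups) != nrow(x))
    stop("group labels do not match the number of samples")
  obs <- .separationStat(.plsScores(x, groups), groups)
  set.seed(seed)
  perm <- vapply(seq_len(nPerm), function(i) {
    yp <- sample(groups)
    .separationStat(.plsScores(x, yp), yp)
  }, numeric(1))
  list(statistic = obs,
       pValue = (1 + sum(perm >= obs)) / (1 + nPerm),
       nPerm = nPerm)
}

#' Run the fixed preprocessing chain
#'
#' Convenience wrapper applying the published order: missingness filter,
#' half-LOD imputation, total-sum normalization with log2 transform and
#' mean-centering.
#'
#' @param ae An [AnalyteExperiment-class].
#' @param threshold Missingness threshold (0.40 metabolomics, 0.05
#'   lipidomics).
#' @return Preprocessed [AnalyteExperiment-class].
#' @export
preprocessPanel <- function(ae, threshold = 0.40) {
  normalizeTotalSum(imputeHalfLOD(filterMissingness(ae, threshold)))
}
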