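#' Select input features for the predictive signature
#'
#' Features entering the selector are the analytes differentially abundant
#' (strictly FDR < `alpha`) in the relevant comparison — in the published
#' workflow, future T2D vs no T2D within the intensively breastfeeding
#' group, which yielded 69 analytes.
#'
#' @param de `data.frame` from [weightedDiffAbundance()].
#' @param alpha FDR threshold (default 0.05, strict).
#' @return Character vector of analyte names.
#' @export
selectInputFeatures <- function(de, alpha = 0.05) {
  feats <- de$analyte[!is.na(de$FDR) & de$FDR < alpha]
  if (!length(feats))
    stop("no analyte passes FDR < ", alpha,
         "; the signature procedure cannot run")
  feats
}

#' Single hold-out split with fixed per-class test size
#'
#' Randomly reserves exactly `holdoutPerClass` samples of each class as the
#' hold-out test set; the remainder is the training set.
#'
#' @param labels Two-level factor (or coercible) of class labels, named by
#'   sample id when available.
#' @param holdoutPerClass Test samples per class.
#' @param seed Seed for the draw.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   covering all samples).
#' @export
splitHoldout <- function(labels, holdoutPerClass, seed = 1L) {
  labels <- factor(labels)
  tab <- table(labels)
  if (any(tab <= holdoutPerClass))
    stop("every class must have more than ", holdoutPerClass,
         " members; sizes: ", paste(tab, collapse = "/"))
  set.seed(seed)
  test <- unlist(lapply(levels(labels), function(l) {
    ix <- which(labels == l)
    ix[sample.int(length(ix), holdoutPerClass)]
  }))
  list(train = setdiff(seq_along(labels), test), test = sort(test))
}

#' Down-sample the majority class to a balanced set
#'
#' Samples the majority class without replacement down to the minority
#' class size.
#'
#' @param labels Factor of training labels.
#' @param seed Seed for the draw.
#' @return Integer indices (into `labels`) of the balanced set.
#' @export
downsampleBalance <- function(labels, seed = NULL) {
  labels <- factor(labels)
  tab <- table(labels)
  if (any(tab == 0) || nlevels(labels) < 2)
    stop("both classes must be present for down-sampling")
  if (!is.null(seed)) set.seed(seed)
  k <- min(tab)
  sort(unlist(lapply(levels(labels), function(l) {
    ix <- which(labels == l)
    if (length(ix) == k) ix else ix[sample.int(length(ix), k)]
  })))
}

.rfImportance <- function(fit, measure) {
  imp <- randomForest::importance(
    fit, type = if (measure == "permutation") 1 else 2)
  stats::setNames(imp[, 1], rownames(imp))
}

.binaryMetrics <- function(truth, predClass, score, positive) {
  truth <- factor(truth)
  tp <- sum(predClass == positive & truth == positive)
  tn <- sum(predClass != positive & truth != positive)
  fp <- sum(predClass == positive & truth != positive)
  fn <- sum(predClass != positive & truth == positive)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  auc <- if (length(unique(score)) > 1)
    as.numeric(pROC::auc(pROC::roc(
      response = truth, predictor = score,
      levels = c(setdiff(levels(truth), positive), positive),
      direction = "<", quiet = TRUE))) else NA_real_
  c(AUC = auc, accuracy = (tp + tn) / length(truth), F1 = f1,
    precision = prec, sensitivity = sens, specificity = spec)
}

#' Repeated down-sampled random-forest feature selection
#'
#' The core of the signature procedure: from a fixed hold-out split, repeat
#' `nRepeats` times — draw a fresh balanced down-sample of the training
#' set, fit a random forest, log the `topKLogged` features by variable
#' importance, and record the hold-out metrics. Frequencies of appearance
#' in the per-repeat top-importance lists are tallied across repeats.
#' Repeats whose down-sample degenerates to one class are skipped and
#' counted in `skipped`.
#'
#' @param x Samples x features numeric matrix (no missing values).
#' @param labels Two-level factor aligned to rows of `x`; the second level
#'   is treated as the positive class.
#' @param config A [SignatureConfig-class] from [signatureConfig()].
#' @return List: `frequency` (named integer vector over features),
#'   `meanImportanceRank` (per-feature mean rank across repeats, for tie
#'   breaking), `metrics` (`nRepeats` x 6 matrix: AUC, accuracy, F1,
#'   precision, sensitivity, specificity on the hold-out), `split` (the
#'   hold-out split), `topLists` (list of per-repeat top-k features),
#'   `skipped` (count).
#' @export
repeatedSelection <- function(x, labels, config = signatureConfig()) {
  methods::validObject(config)
  x <- as.matrix(x)
  if (anyNA(x)) stop("features must not contain missing values")
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("exactly two classes are required")
  if (config@topKLogged > ncol(x))
    stop("topKLogged exceeds the number of features")
  set.seed(config@seed)
  split <- splitHoldout(labels, config@holdoutPerClass,
                        seed = config@seed)
  positive <- levels(labels)[2]
  freq <- stats::setNames(integer(ncol(x)), colnames(x))
  rankSum <- stats::setNames(numeric(ncol(x)), colnames(x))
  rankCnt <- stats::setNames(integer(ncol(x)), colnames(x))
  metrics <- matrix(NA_real_, config@nRepeats, 6,
                    dimnames = list(NULL, c("AUC", "accuracy", "F1",
                                            "precision", "sensitivity",
                                            "specificity")))
  topLists <- vector("list", config@nRepeats)
  skipped <- 0L
  for (r in seq_len(config@nRepeats)) {
    if (config@redrawHoldout && r > 1L)
      split <- splitHoldout(labels, config@holdoutPerClass,
                            seed = config@seed + r)
    trainIdx <- split$train
    bal <- trainIdx[downsampleBalance(labels[trainIdx])]
    if (nlevels(droplevels(labels[bal])) < 2L) {
      skipped <- skipped + 1L
      next
    }
    fit <- randomForest::randomForest(
      x = x[bal, , drop = FALSE], y = droplevels(labels[bal]),
      ntree = config@nTrees,
      importance = config@importance == "permutation")
    imp <- .rfImportance(fit, config@importance)
    ord <- order(-imp, names(imp))
    top <- names(imp)[ord][seq_len(config@topKLogged)]
    freq[top] <- freq[top] + 1L
    rk <- rank(-imp, ties.method = "average")
    rankSum <- rankSum + rk
    rankCnt <- rankCnt + 1L
    topLists[[r]] <- top
    pr <- stats::predict(fit, x[split$test, , drop = FALSE],
                         type = "prob")[, positive]
    cl <- stats::predict(fit, x[split$test, , drop = FALSE])
    metrics[r, ] <- .binaryMetrics(labels[split$test], cl, pr, positive)
  }
  list(frequency = freq,
       meanImportanceRank = ifelse(rankCnt > 0, rankSum / pmax(rankCnt, 1),
                                   Inf),
       metrics = metrics, split = split, topLists = topLists,
       skipped = skipped)
}

#' Finalize the predictive signature
#'
#' Picks the `signatureSize` features appearing most often in the
#' per-repeat top-importance lists. Ties at the boundary are broken by the
#' smaller mean importance rank across repeats, then alphabetically, so the
#' result is deterministic.
#'
#' @param selection Result of [repeatedSelection()] (or a named frequency
#'   vector).
#' @param signatureSize Number of features to keep (default 10).
#' @return Character vector of feature names, most frequent first.
#' @export
finalizeSignature <- function(selection, signatureSize = 10) {
  freq <- if (is.list(selection)) selection$frequency else selection
  meanRank <- if (is.list(selection) &&
                  !is.null(selection$meanImportanceRank))
    selection$meanImportanceRank else
      stats::setNames(rep(0, length(freq)), names(freq))
  nz <- freq[freq > 0]
  if (length(nz) < signatureSize)
    stop("only ", length(nz), " features have nonzero frequency; ",
         signatureSize, " required")
  ord <- order(-freq, meanRank[names(freq)], names(freq))
  names(freq)[ord][seq_len(signatureSize)]
}

#' Evaluate a signature (and clinical baselines) on the hold-out
#'
#' Re-runs the repeat loop restricted to the signature features: per
#' repeat, a fresh balanced down-sample of the fixed training set, a random
#' forest on the signature, and hold-out scoring. Reports the median and
#' 2.5/97.5 percentile interval of each metric over repeats. Clinical
#' baseline variables are scored directly as rank classifiers (their raw
#' value is the ROC score; with a fixed hold-out their metrics are constant
#' across repeats), and a combined model (signature + clinical variables)
#' is refit per repeat like the signature model.
#'
#' @param signature Character vector of feature names.
#' @param x Samples x features matrix (must contain the signature columns).
#' @param labels Two-level factor; second level is the positive class.
#' @param config A [SignatureConfig-class]; the hold-out split is redrawn
#'   from `config@seed`, so it matches the [repeatedSelection()] run with
#'   the same configuration.
#' @param clinicalBaselines Optional samples x variables matrix or
#'   `data.frame` of single-variable clinical scores (e.g. fasting and 2-h
#'   post-load glucose).
#' @return List: `metrics` (repeats x 6), `summary` (per-metric median and
#'   percentile interval), `baselines` (per-variable metric summaries),
#'   `combined` (summary for signature + clinical model, when baselines are
#'   given).
#' @export
evaluateSignature <- function(signature, x, labels,
                              config = signatureConfig(),
                              clinicalBaselines = NULL) {
  x <- as.matrix(x)
  miss <- setdiff(signature, colnames(x))
  if (length(miss))
    stop("signature features absent from the table: ",
         paste(miss, collapse = ", "))
  labels <- factor(labels)
  positive <- levels(labels)[2]
  set.seed(config@seed)
  split <- splitHoldout(labels, config@holdoutPerClass, seed = config@seed)
  xs <- x[, signature, drop = FALSE]
  if (!is.null(clinicalBaselines)) {
    clinicalBaselines <- as.matrix(clinicalBaselines)
    xc <- cbind(xs, clinicalBaselines)
  }
  metrics <- matrix(NA_real_, config@nRepeats, 6,
                    dimnames = list(NULL, c("AUC", "accuracy", "F1",
                                            "precision", "sensitivity",
                                            "specificity")))
  combMetrics <- metrics
  for (r in seq_len(config@nRepeats)) {
    bal <- split$train[downsampleBalance(labels[split$train])]
    fit <- randomForest::randomForest(
      x = xs[bal, , drop = FALSE], y = droplevels(labels[bal]),
      ntree = config@nTrees)
    pr <- stats::predict(fit, xs[split$test, , drop = FALSE],
                         type = "prob")[, positive]
    cl <- stats::predict(fit, xs[split$test, , drop = FALSE])
    if (length(unique(pr)) <= 1L)
      warning("constant hold-out predictions in repeat ", r,
              "; AUC undefined")
    metrics[r, ] <- .binaryMetrics(labels[split$test], cl, pr, positive)
    if (!is.null(clinicalBaselines)) {
      fitC <- randomForest::randomForest(
        x = xc[bal, , drop = FALSE], y = droplevels(labels[bal]),
        ntree = config@nTrees)
      prC <- stats::predict(fitC, xc[split$test, , drop = FALSE],
                            type = "prob")[, positive]
      clC <- stats::predict(fitC, xc[split$test, , drop = FALSE])
      combMetrics[r, ] <- .binaryMetrics(labels[split$test], clC, prC,
                                         positive)
    }
  }
  summarize <- function(m) {
    apply(m, 2, function(v) c(
      median = stats::median(v, na.rm = TRUE),
      lower = unname(stats::quantile(v, 0.025, na.rm = TRUE)),
      upper = unname(stats::quantile(v, 0.975, na.rm = TRUE))))
  }
  baselines <- NULL
  if (!is.null(clinicalBaselines)) {
    baselines <- lapply(
      stats::setNames(colnames(clinicalBaselines),
                      colnames(clinicalBaselines)),
      function(v) {
        score <- clinicalBaselines[split$test, v]
        thr <- stats::median(score)
        cl <- factor(ifelse(score > thr, positive,
                            setdiff(levels(labels), positive)),
                     levels = levels(labels))
        .binaryMetrics(labels[split$test], cl, score, positive)
      })
  }
  list(metrics = metrics, summary = summarize(metrics),
       baselines = baselines,
       combined = if (!is.null(clinicalBaselines)) summarize(combMetrics))
}
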