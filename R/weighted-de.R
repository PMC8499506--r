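#' Inverse-probability sampling weights
#'
#' For a nested case-control subset, each participant's design weight is the
#' inverse of their sampling probability, so weighted estimates recover
#' full-cohort (Horvitz-Thompson) quantities.
#'
#' @param subset A [LactationCohort-class] with `samplingProb` filled, or a
#'   numeric vector of sampling probabilities.
#' @return Named numeric vector of weights.
#' @examples
#' samplingWeights(c(a = 0.5, b = 1))  # 2, 1
#' @export
samplingWeights <- function(subset) {
  p <- if (is(subset, "LactationCohort")) samplingProbs(subset) else subset
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("sampling probabilities must lie in (0, 1]")
  1 / p
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with input validation; a single
#' p-value is returned unchanged and adjusted values preserve the input
#' order.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted p-values (q-values), same length and order as `p`.
#' @export
bhFDR <- function(p) {
  if (!is.numeric(p))
    stop("p-values must be numeric")
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# vectorized marginal F-test of `term` for an analytes x samples matrix
# sharing one design; identical to anova(reduced, full) per analyte
.fastWeightedF <- function(x, design, term, w) {
  sw <- sqrt(w)
  Xf <- stats::model.matrix(stats::reformulate(names(design)), design)
  redTerms <- setdiff(names(design), term)
  Xr <- if (length(redTerms))
    stats::model.matrix(stats::reformulate(redTerms), design) else
      matrix(1, nrow(design), 1)
  Y <- t(x) * sw
  qf <- qr(Xf * sw); qrd <- qr(Xr * sw)
  rssF <- colSums(qr.resid(qf, Y)^2)
  rssR <- colSums(qr.resid(qrd, Y)^2)
  df1 <- qf$rank - qrd$rank
  df2 <- nrow(Y) - qf$rank
  if (df1 < 1 || df2 < 1)
    return(list(p = rep(NA_real_, nrow(x)), F = rep(NA_real_, nrow(x))))
  Fst <- ((rssR - rssF) / df1) / (rssF / df2)
  list(p = stats::pf(Fst, df1, df2, lower.tail = FALSE), F = Fst)
}

# marginal (Type III) F-test of `term`: full weighted fit vs the fit with
# the term removed, all other terms retained
.dropTermF <- function(y, design, term, weights) {
  full <- stats::lm(stats::reformulate(names(design), response = "y"),
                    data = cbind(y = y, design), weights = weights)
  redTerms <- setdiff(names(design), term)
  fml <- if (length(redTerms))
    stats::reformulate(redTerms, response = "y") else y ~ 1
  red <- stats::lm(fml, data = cbind(y = y, design), weights = weights)
  a <- stats::anova(red, full)
  list(p = a[2, "Pr(>F)"], F = a[2, "F"], fit = full)
}

.weightedMean <- function(x, w) sum(x * w) / sum(w)

# design-robust (HC3 sandwich) Wald F-test of `term` under weighted least
# squares, vectorized over the rows of `x`. Inverse-probability weights are
# not frequency weights: the model-based variance understates the true
# sampling variance by the design effect of unequal weights, so the
# sandwich estimator is required for calibrated inference.
.fastSandwichF <- function(x, design, term, w) {
  sw <- sqrt(w)
  Xf <- stats::model.matrix(stats::reformulate(names(design)), design)
  Xt <- Xf * sw
  qf <- qr(Xt)
  n <- nrow(Xt)
  pRank <- qf$rank
  df2 <- n - pRank
  naOut <- list(p = rep(NA_real_, nrow(x)), F = rep(NA_real_, nrow(x)))
  if (pRank < ncol(Xt) || df2 < 1) return(naOut)
  idx <- which(attr(Xf, "assign") == match(term, names(design)))
  if (!length(idx)) return(naOut)
  k <- length(idx)

  Y <- t(x) * sw
  B <- qr.coef(qf, Y)
  U <- qr.resid(qf, Y)
  h <- rowSums(qr.Q(qf)[, seq_len(pRank), drop = FALSE]^2)
  Uadj2 <- (U / (1 - h))^2                     # HC3 leverage adjustment
  bread <- solve(crossprod(Xt))
  A <- bread %*% t(Xt)
  M <- A[idx, , drop = FALSE]

  if (k == 1L) {
    varG <- as.numeric(M^2 %*% Uadj2)
    Fst <- as.numeric(B[idx, ])^2 / varG
  } else {
    Fst <- vapply(seq_len(ncol(Y)), function(j) {
      V <- (M * rep(Uadj2[, j], each = k)) %*% t(M)
      b <- B[idx, j]
      as.numeric(t(b) %*% solve(V, b)) / k
    }, numeric(1))
  }
  list(p = stats::pf(Fst, k, df2, lower.tail = FALSE), F = Fst)
}

#' Design-weighted differential abundance
#'
#' Per analyte, fits the weighted linear model
#' `value ~ group + covariates` on log2-normalized abundances with the
#' inverse-probability weights of the nested case-control design, and
#' tests the group term marginally (Type III: covariates retained under
#' the null). With constant weights this is the classical full-vs-reduced
#' F-test; with unequal design weights the model-based variance
#' understates the true sampling variance by the design effect of the
#' weights, so the group test switches to a heteroskedasticity-robust
#' HC3 sandwich Wald F-test (set `robust = TRUE` to force the sandwich
#' even with constant weights). The log2 fold change is the weighted
#' group-mean contrast, which is unaffected by per-analyte
#' mean-centering. Benjamini-Hochberg FDR is computed across the analyte
#' family. Analytes with zero variance or a rank-deficient design are
#' flagged (`status = "degenerate"`) rather than failing the run.
#'
#' @param ae An [AnalyteExperiment-class] (assay `"log2norm"` preferred,
#'   else log2 abundance) or an analytes x samples numeric matrix of
#'   log-scale values.
#' @param group Factor (>= 2 levels), or the name of a `colData` column.
#' @param covariates `data.frame` of adjustment covariates (e.g.
#'   pre-pregnancy BMI), or character vector of `colData` column names; may
#'   be `NULL`.
#' @param weights Numeric design weights aligned to samples (default all 1);
#'   see [samplingWeights()].
#' @param robust Force the sandwich variance even when weights are
#'   constant (it is used automatically when they are not).
#' @param ref Reference group level for the fold change: `log2FC` is the
#'   weighted mean of the first non-reference level minus the weighted mean
#'   of `ref`. Defaults to the last factor level, so with the usual
#'   `IBF` / `IFF/Mixed` labels the fold change is IBF relative to
#'   IFF/Mixed.
#' @return `data.frame` with columns `analyte`, `class`, `log2FC`, `p`,
#'   `FDR`, `direction`, `status`.
#' @export
weightedDiffAbundance <- function(ae, group, covariates = NULL,
                                  weights = NULL, robust = FALSE,
                                  ref = NULL) {
  prep <- .deInputs(ae, group, covariates, weights)
  x <- prep$x; grp <- prep$group; cov <- prep$cov; w <- prep$w
  cls <- prep$class
  if (nlevels(grp) < 2)
    stop("group factor needs at least two levels")
  design <- data.frame(group = grp)
  if (!is.null(cov)) design <- cbind(design, cov)

  lev <- levels(grp)
  if (is.null(ref)) ref <- lev[length(lev)]
  if (!ref %in% lev) stop("ref is not a group level")
  target <- setdiff(lev, ref)[1]

  # unequal inverse-probability weights require the sandwich variance:
  # treating them as precision weights understates the sampling variance
  # by the design effect and inflates the test
  useSandwich <- robust || diff(range(w)) > 1e-8 * max(w)

  if (!anyNA(x)) {
    # complete data: all analytes share one design, so the marginal test
    # reduces to shared QR decompositions and matrix residuals
    out <- if (useSandwich) .fastSandwichF(x, design, "group", w) else
      .fastWeightedF(x, design, "group", w)
    zv <- apply(x, 1, stats::var) < 1e-12
    out$p[zv] <- NA_real_
    tw <- w[grp == target]; rw <- w[grp == ref]
    l2fc <- as.numeric(x[, grp == target, drop = FALSE] %*% tw) / sum(tw) -
      as.numeric(x[, grp == ref, drop = FALSE] %*% rw) / sum(rw)
    res <- data.frame(analyte = rownames(x), class = cls,
                      log2FC = ifelse(zv, NA_real_, l2fc), p = out$p,
                      stringsAsFactors = FALSE)
    res$FDR <- bhFDR(res$p)
    res$direction <- ifelse(is.na(res$log2FC), NA_character_,
                            ifelse(res$log2FC >= 0, "up", "down"))
    res$status <- ifelse(is.na(res$p) | zv, "degenerate", "ok")
    rownames(res) <- NULL
    return(res)
  }

  res <- lapply(seq_len(nrow(x)), function(i) {
    y <- x[i, ]
    ok <- is.finite(y)
    if (stats::var(y[ok]) < 1e-12 || !all(table(grp[ok]) >= 2))
      return(list(l2fc = NA_real_, p = NA_real_, status = "degenerate"))
    p <- tryCatch({
      if (useSandwich)
        .fastSandwichF(matrix(y[ok], 1), design[ok, , drop = FALSE],
                       "group", w[ok])$p
      else
        .dropTermF(y[ok], design[ok, , drop = FALSE], "group", w[ok])$p
    }, error = function(e) NA_real_)
    if (is.na(p))
      return(list(l2fc = NA_real_, p = NA_real_, status = "degenerate"))
    l2fc <- .weightedMean(y[ok][grp[ok] == target],
                          w[ok][grp[ok] == target]) -
      .weightedMean(y[ok][grp[ok] == ref], w[ok][grp[ok] == ref])
    list(l2fc = l2fc, p = p, status = "ok")
  })
  out <- data.frame(
    analyte = rownames(x),
    class = cls,
    log2FC = vapply(res, `[[`, numeric(1), "l2fc"),
    p = vapply(res, `[[`, numeric(1), "p"),
    stringsAsFactors = FALSE)
  out$FDR <- bhFDR(out$p)
  out$direction <- ifelse(is.na(out$log2FC), NA_character_,
                          ifelse(out$log2FC >= 0, "up", "down"))
  out$status <- vapply(res, `[[`, character(1), "status")
  rownames(out) <- NULL
  out
}

.deInputs <- function(ae, group, covariates, weights) {
  if (is(ae, "AnalyteExperiment")) {
    keep <- !.controlMask(ae)
    nms <- SummarizedExperiment::assayNames(ae)
    x <- if ("log2norm" %in% nms) assay(ae, "log2norm") else
      log2(assay(ae, "abundance"))
    x <- x[, keep, drop = FALSE]
    cd <- as.data.frame(colData(ae))[keep, , drop = FALSE]
    if (is.character(group) && length(group) == 1L)
      group <- cd[[group]]
    if (is.character(covariates))
      covariates <- cd[, covariates, drop = FALSE]
    if (is.character(weights) && length(weights) == 1L)
      weights <- samplingWeights(cd[[weights]])
    cls <- analyteClass(ae)
  } else {
    x <- as.matrix(ae)
    if (is.null(rownames(x)))
      rownames(x) <- paste0("analyte", seq_len(nrow(x)))
    cls <- rep(NA_character_, nrow(x))
  }
  if (is.null(weights)) weights <- rep(1, ncol(x))
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be finite and positive")
  if (length(weights) != ncol(x))
    stop("weights must align with samples")
  grp <- droplevels(factor(group))
  if (length(grp) != ncol(x))
    stop("group labels must align with samples")
  if (!is.null(covariates)) covariates <- as.data.frame(covariates)
  list(x = x, group = grp, cov = covariates, w = weights, class = cls)
}

#' Stratified design-weighted differential abundance
#'
#' Runs [weightedDiffAbundance()] within each stratum (e.g. future T2D vs
#' no T2D, or NGT vs IFG/IGT), with Benjamini-Hochberg correction within
#' each stratum's analyte family. Strata in which the group factor has a
#' single level are skipped with a warning.
#'
#' @inheritParams weightedDiffAbundance
#' @param strata Factor of stratum labels (or `colData` column name).
#' @return Named list of per-stratum result `data.frame`s.
#' @export
stratifiedDiffAbundance <- function(ae, strata, group, covariates = NULL,
                                    weights = NULL) {
  prep <- .deInputs(ae, group, covariates, weights)
  if (is(ae, "AnalyteExperiment") && is.character(strata) &&
      length(strata) == 1L)
    strata <- as.data.frame(colData(ae))[!.controlMask(ae), ][[strata]]
  strata <- factor(strata)
  if (length(strata) != ncol(prep$x))
    stop("strata labels must align with samples")
  out <- list()
  for (s in levels(strata)) {
    sel <- strata == s
    if (!sum(sel)) { warning("stratum '", s, "' is empty; skipped"); next }
    if (nlevels(droplevels(prep$group[sel])) < 2) {
      warning("stratum '", s, "' has a single group level; skipped")
      next
    }
    m <- prep$x[, sel, drop = FALSE]
    res <- weightedDiffAbundance(
      m, group = prep$group[sel],
      covariates = if (is.null(prep$cov)) NULL else
        prep$cov[sel, , drop = FALSE],
      weights = prep$w[sel])
    res$class <- prep$class
    out[[s]] <- res
  }
  out
}

#' Write differential-abundance results as TSV
#'
#' @param de Result of [weightedDiffAbundance()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
writeDEResults <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
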