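#' Build longitudinal records from two timepoints
#'
#' Assembles a long-format table (participant, timepoint, group, lactation
#' duration, one column per analyte) from baseline and follow-up
#' [AnalyteExperiment-class] objects. Participants present at only one
#' timepoint are excluded, as are internal-control samples.
#'
#' @param baseline,followup [AnalyteExperiment-class] objects with identical
#'   analyte sets (apply [filterMissingnessLongitudinal()] and
#'   [batchCorrect()] first) and `colData` columns `feedingGroup` and
#'   `lactationDuration`.
#' @param assayName Assay holding the analysis-ready values (default
#'   `"normalized"`, falling back to `"log2norm"`).
#' @return Long `data.frame`: `id`, `timepoint`, `group`, `duration`, then
#'   one column per analyte.
#' @export
makeLongitudinalRecords <- function(baseline, followup,
                                    assayName = NULL) {
  if (!identical(rownames(baseline), rownames(followup)))
    stop("analyte sets differ between timepoints")
  pick <- function(ae) {
    nms <- SummarizedExperiment::assayNames(ae)
    an <- if (!is.null(assayName)) assayName else
      if ("normalized" %in% nms) "normalized" else "log2norm"
    if (!an %in% nms) stop("assay '", an, "' not found")
    keep <- !.controlMask(ae)
    list(x = assay(ae, an)[, keep, drop = FALSE],
         cd = as.data.frame(colData(ae))[keep, , drop = FALSE])
  }
  b <- pick(baseline); f <- pick(followup)
  both <- intersect(colnames(b$x), colnames(f$x))
  if (!length(both)) stop("no participant appears at both timepoints")
  one <- function(p, tp) {
    data.frame(id = both, timepoint = tp,
               group = p$cd[both, "feedingGroup"],
               duration = p$cd[both, "lactationDuration"],
               t(p$x[, both, drop = FALSE]),
               check.names = FALSE, stringsAsFactors = FALSE)
  }
  out <- rbind(one(b, "baseline"), one(f, "followup"))
  rownames(out) <- NULL
  out
}

#' Per-analyte mixed-model screen of longitudinal dynamics
#'
#' For each analyte fits the linear mixed model
#' `value ~ group + time + group:time + duration + (1 | id)` by REML and
#' reports the marginal (Type III) test of the group-by-time interaction —
#' the term asking whether the between-group difference changes from
#' baseline to follow-up. Inference uses Satterthwaite degrees of freedom
#' (lmerTest); p-values are Benjamini-Hochberg corrected across analytes.
#' Analytes whose fit fails to converge fall back to the paired-difference
#' model (per-participant follow-up minus baseline regressed on group and
#' duration, in which the group coefficient is the interaction) and are
#' flagged `status = "paired-fallback"`.
#'
#' @param records Long `data.frame` from [makeLongitudinalRecords()] (or
#'   with the same columns).
#' @param analytes Analyte column names to screen (default: all columns
#'   after `id`, `timepoint`, `group`, `duration`).
#' @return `data.frame`: `analyte`, `estimate` (interaction, log2 units),
#'   `p`, `FDR`, `status`.
#' @export
mixedModelScreen <- function(records, analytes = NULL) {
  meta <- c("id", "timepoint", "group", "duration")
  miss <- setdiff(meta, names(records))
  if (length(miss))
    stop("records lack columns: ", paste(miss, collapse = ", "))
  if (is.null(analytes)) analytes <- setdiff(names(records), meta)
  cnt <- table(records$id)
  keepIds <- names(cnt)[cnt == 2L]
  rec <- records[records$id %in% keepIds, , drop = FALSE]
  rec$group <- factor(rec$group)
  rec$timepoint <- factor(rec$timepoint,
                          levels = c("baseline", "followup"))
  res <- lapply(analytes, function(an) {
    d <- data.frame(y = rec[[an]], id = rec$id, group = rec$group,
                    time = rec$timepoint, duration = rec$duration)
    d <- d[stats::complete.cases(d), ]
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lmerTest::lmer(y ~ group * time + duration + (1 | id), data = d,
                       REML = TRUE))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      co <- tryCatch(stats::coef(summary(fit)), error = function(e) NULL)
      ix <- if (!is.null(co)) grep(":", rownames(co)) else integer()
      if (length(ix) == 1L && is.finite(co[ix, "Pr(>|t|)"]))
        return(data.frame(analyte = an, estimate = co[ix, "Estimate"],
                          p = co[ix, "Pr(>|t|)"], status = "ok",
                          stringsAsFactors = FALSE))
    }
    # paired-difference fallback: diff ~ group + duration
    wide <- stats::reshape(d[c("id", "time", "y", "group", "duration")],
                           idvar = "id", timevar = "time",
                           direction = "wide")
    wide <- wide[stats::complete.cases(wide), ]
    pd <- tryCatch({
      dd <- wide$y.followup - wide$y.baseline
      fitp <- stats::lm(dd ~ wide$group.baseline + wide$duration.baseline)
      cop <- stats::coef(summary(fitp))
      gi <- grep("group", rownames(cop))[1]
      data.frame(analyte = an, estimate = cop[gi, "Estimate"],
                 p = cop[gi, "Pr(>|t|)"], status = "paired-fallback",
                 stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(analyte = an, estimate = NA_real_, p = NA_real_,
                 status = "failed", stringsAsFactors = FALSE))
    pd
  })
  out <- do.call(rbind, res)
  out$FDR <- bhFDR(out$p)
  rownames(out) <- NULL
  out[, c("analyte", "estimate", "p", "FDR", "status")]
}
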