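#' Cohort characteristics table with group comparisons
#'
#' Summarizes each requested variable by group and attaches the
#' corresponding test: chi-square (without continuity correction) for
#' categorical variables reported as n (%), Welch t-test for approximately
#' normal continuous variables reported as mean (SD), and Mann-Whitney U
#' (Wilcoxon rank-sum) for skewed continuous variables reported as median
#' (IQR).
#'
#' @param data `data.frame` of participant-level variables (e.g.
#'   `participants(cohort)`).
#' @param grouping Name of the two-level grouping column, or a factor.
#' @param varTypes Named character vector mapping variable names to one of
#'   `"categorical"`, `"normal"`, `"skewed"`.
#' @return `data.frame`: `variable`, `type`, one summary column per group,
#'   `p`.
#' @examples
#' d <- data.frame(g = rep(c("A", "B"), each = 20),
#'                 age = rnorm(40, 34, 5),
#'                 race = sample(c("x", "y"), 40, TRUE))
#' summarizeCohort(d, "g", c(age = "normal", race = "categorical"))
#' @export
summarizeCohort <- function(data, grouping, varTypes) {
  grp <- if (is.character(grouping) && length(grouping) == 1L)
    data[[grouping]] else grouping
  grp <- factor(grp)
  if (any(table(grp) == 0) || nlevels(grp) < 2)
    stop("every group must be non-empty")
  levs <- levels(grp)
  rows <- lapply(names(varTypes), function(v) {
    type <- match.arg(varTypes[[v]], c("categorical", "normal", "skewed"))
    x <- data[[v]]
    if (type == "categorical") {
      tab <- table(factor(x), grp)
      p <- stats::chisq.test(tab, correct = FALSE)$p.value
      summ <- vapply(levs, function(l) {
        cnt <- tab[, l]
        paste(paste0(rownames(tab), " ", cnt, " (",
                     sprintf("%.1f%%", 100 * cnt / sum(cnt)), ")"),
              collapse = "; ")
      }, character(1))
    } else if (type == "normal") {
      p <- stats::t.test(x ~ grp)$p.value
      summ <- vapply(levs, function(l)
        sprintf("%.2f (%.2f)", mean(x[grp == l], na.rm = TRUE),
                stats::sd(x[grp == l], na.rm = TRUE)), character(1))
    } else {
      p <- stats::wilcox.test(x ~ grp, exact = NULL)$p.value
      summ <- vapply(levs, function(l) {
        q <- stats::quantile(x[grp == l], c(0.25, 0.5, 0.75), na.rm = TRUE)
        sprintf("%.2f (%.2f-%.2f)", q[2], q[1], q[3])
      }, character(1))
    }
    out <- data.frame(variable = v, type = type, stringsAsFactors = FALSE)
    for (l in levs) out[[l]] <- summ[[l]]
    out$p <- p
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
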