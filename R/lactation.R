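#' Monthly feeding-diary record
#'
#' One participant-month of feeding behaviour: average counts of breast-milk
#' and formula feeds per 24 h over the reporting window, and average ounces
#' of formula per 24 h.
#'
#' @param breastFeeds,formulaFeeds Nonnegative average feeds per 24 h.
#' @param formulaOz Nonnegative average ounces of formula per 24 h.
#' @return A `FeedingMonth` list (fields as above).
#' @examples
#' feedingMonth(8, 0, 0)
#' @export
feedingMonth <- function(breastFeeds, formulaFeeds, formulaOz = 0) {
  vals <- c(breastFeeds = breastFeeds, formulaFeeds = formulaFeeds,
            formulaOz = formulaOz)
  if (any(!is.finite(vals)))
    stop("feeding diary values must be finite")
  if (any(vals < 0))
    stop("feeding diary values must be nonnegative; got ",
         paste(names(vals)[vals < 0], collapse = ", "))
  structure(list(breastFeeds = breastFeeds, formulaFeeds = formulaFeeds,
                 formulaOz = formulaOz), class = "FeedingMonth")
}

#' Monthly breastfeeding intensity ratio
#'
#' Number of breast-milk feeds divided by the total number of liquid feeds
#' (breast + formula), both averaged per 24 h: 1 means exclusive
#' breastfeeding, 0 exclusive formula feeding.
#'
#' @param month A [feedingMonth()].
#' @return Ratio in `[0, 1]`.
#' @examples
#' monthlyIntensityRatio(feedingMonth(8, 0))   # 1
#' monthlyIntensityRatio(feedingMonth(3, 3))   # 0.5
#' @export
monthlyIntensityRatio <- function(month) {
  stopifnot(inherits(month, "FeedingMonth"))
  total <- month$breastFeeds + month$formulaFeeds
  if (total <= 0)
    stop("undefined intensity ratio: no liquid feeds recorded this month")
  month$breastFeeds / total
}

#' Two-month lactation intensity/duration ratio (LIR) score
#'
#' Sums the monthly intensity ratios of the first two postpartum months to
#' a score in `[0, 2]` and dichotomizes at the 1.45 cut-off: scores >= 1.45
#' are intensive breastfeeding (IBF), scores below are intensive
#' formula/mixed feeding (IFF/Mixed).
#'
#' @param months List of exactly two [feedingMonth()] records, delivery to
#'   2 months postpartum.
#' @param cutoff IBF cut-off on the summed score (default 1.45).
#' @return List with `monthlyRatios` (length 2), `score`, `group`
#'   (`"IBF"` or `"IFF/Mixed"`) and `category` (see [feedingCategory()]).
#' @examples
#' lir2Month(list(feedingMonth(8, 0), feedingMonth(8, 0)))  # score 2, IBF
#' @export
lir2Month <- function(months, cutoff = 1.45) {
  if (!is.list(months) || length(months) != 2L)
    stop("exactly two monthly records are required")
  ratios <- vapply(months, monthlyIntensityRatio, numeric(1))
  score <- sum(ratios)
  list(monthlyRatios = ratios, score = score,
       group = if (score >= cutoff) "IBF" else "IFF/Mixed",
       category = feedingCategory(months))
}

#' Four-level feeding category from formula volume
#'
#' Classifies the first two postpartum months into exclusive breastfeeding
#' (no formula or other feeds), mostly breastfeeding (<= 6 oz of formula per
#' 24 h), mostly formula / mixed feeding (> 6 oz with some breastfeeding;
#' the published bins are mixed 7-17 oz and mostly formula > 17 oz, and the
#' unstated 6-7 oz interval is assigned to mixed so the partition is
#' contiguous), and exclusive formula feeding (no breast-milk feeds).
#'
#' @param months List of one or two [feedingMonth()] records; volumes and
#'   counts are averaged across them.
#' @return One of `"exclusive BF"`, `"mostly BF"`, `"mostly FF/Mixed"`,
#'   `"exclusive FF"`.
#' @export
feedingCategory <- function(months) {
  if (inherits(months, "FeedingMonth")) months <- list(months)
  stopifnot(length(months) >= 1L,
            all(vapply(months, inherits, logical(1), "FeedingMonth")))
  breast <- mean(vapply(months, `[[`, numeric(1), "breastFeeds"))
  formulaFeeds <- mean(vapply(months, `[[`, numeric(1), "formulaFeeds"))
  oz <- mean(vapply(months, `[[`, numeric(1), "formulaOz"))
  if (breast <= 0 && (formulaFeeds > 0 || oz > 0)) return("exclusive FF")
  if (breast <= 0) stop("no feeds recorded; category undefined")
  if (oz <= 0 && formulaFeeds <= 0) return("exclusive BF")
  if (oz <= 6) return("mostly BF")
  "mostly FF/Mixed"
}

#' Score a feeding-diary table
#'
#' Computes the 2-month LIR score, group, and feeding category for every
#' participant in a long-format diary table. Participants whose first two
#' months are not both present (or have a month with no recorded feeds) are
#' flagged `inconsistent = TRUE` and given `NA` scores rather than being
#' silently dropped or imputed.
#'
#' @param diary `data.frame` with columns `id`, `month`, `breastFeeds`,
#'   `formulaFeeds`, `formulaOz` (as read by [readFeedingDiary()]).
#' @param cutoff IBF cut-off (default 1.45).
#' @return `data.frame` with one row per participant: `id`, `ratio1`,
#'   `ratio2`, `score`, `group`, `category`, `inconsistent`.
#' @export
scoreLactation <- function(diary, cutoff = 1.45) {
  need <- c("id", "month", "breastFeeds", "formulaFeeds", "formulaOz")
  miss <- setdiff(need, names(diary))
  if (length(miss))
    stop("diary lacks columns: ", paste(miss, collapse = ", "))
  out <- lapply(split(diary, diary$id), function(d) {
    d <- d[d$month %in% c(1, 2), , drop = FALSE]
    d <- d[order(d$month), ]
    base <- data.frame(id = d$id[1], ratio1 = NA_real_, ratio2 = NA_real_,
                       score = NA_real_, group = NA_character_,
                       category = NA_character_, inconsistent = TRUE,
                       stringsAsFactors = FALSE)
    if (!identical(as.numeric(d$month), c(1, 2))) return(base)
    res <- tryCatch(
      lir2Month(list(feedingMonth(d$breastFeeds[1], d$formulaFeeds[1],
                                  d$formulaOz[1]),
                     feedingMonth(d$breastFeeds[2], d$formulaFeeds[2],
                                  d$formulaOz[2])), cutoff = cutoff),
      error = function(e) NULL)
    if (is.null(res)) return(base)
    data.frame(id = d$id[1], ratio1 = res$monthlyRatios[1],
               ratio2 = res$monthlyRatios[2], score = res$score,
               group = res$group, category = res$category,
               inconsistent = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Read a feeding-diary CSV
#'
#' Expects columns `participant_id` (or `id`), `month`, `breast_feeds`,
#' `formula_feeds`, `formula_oz` (snake_case or camelCase accepted).
#'
#' @param path CSV path.
#' @return Canonical diary `data.frame` for [scoreLactation()].
#' @export
readFeedingDiary <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  alias <- c(participant_id = "id", breast_feeds = "breastFeeds",
             formula_feeds = "formulaFeeds", formula_oz = "formulaOz")
  for (nm in names(alias))
    if (nm %in% names(d)) names(d)[names(d) == nm] <- alias[[nm]]
  need <- c("id", "month", "breastFeeds", "formulaFeeds", "formulaOz")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("diary file lacks columns: ", paste(miss, collapse = ", "))
  d
}
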