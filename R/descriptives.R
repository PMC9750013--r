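#' Empirical support curves by scenario grouping
#'
#' For each group, the share of responses supporting a contribution of at
#' most each threshold (an empirical CDF evaluated on a threshold grid).
#' Built-in groupings follow the descriptive analysis of the vignette
#' experiment:
#' \describe{
#'   \item{`"costs"`}{`high costs` = both the economy-shrinks and the
#'     mutation-risk scenarios active (trade = 1 and risk = 1);
#'     `low costs` = neither active. Mixed cells (exactly one active) are
#'     excluded from this grouping by design.}
#'   \item{`"multilateralism"`}{`high multilateralism` = some
#'     international deal (deal != 0); `low multilateralism` = no deal.}
#' }
#' A custom grouping can be supplied as a function of the data returning
#' a label per row (`NA` rows are excluded).
#'
#' @param data Data frame with the outcome column and, for the built-in
#'   groupings, `trade`, `risk`, `deal` (e.g. responses joined with their
#'   vignette assignments).
#' @param grouping `"costs"`, `"multilateralism"`, or a function.
#' @param thresholds Ascending numeric grid; defaults to the sorted
#'   unique observed outcome values.
#' @param outcome Name of the outcome column (default `"cash"`).
#' @return Long data frame of class `"support_curve"`: `group`,
#'   `threshold`, `share`, `n`. Empty groups are kept with `n = 0` and
#'   `share = NA` rather than dropped silently.
#' @export
support_cdf <- function(data, grouping = c("costs", "multilateralism"),
                        thresholds = NULL, outcome = "cash") {
  y <- data[[outcome]]
  if (is.null(y)) stop("no outcome column `", outcome, "` in `data`")
  if (is.function(grouping)) {
    lab <- grouping(data)
    levels_ <- unique(stats::na.omit(lab))
  } else {
    grouping <- match.arg(grouping)
    lab <- if (grouping == "costs") {
      ifelse(data$trade == 1 & data$risk == 1, "high costs",
             ifelse(data$trade == 0 & data$risk == 0, "low costs", NA))
    } else {
      ifelse(data$deal != 0, "high multilateralism", "low multilateralism")
    }
    levels_ <- if (grouping == "costs") c("low costs", "high costs")
               else c("low multilateralism", "high multilateralism")
  }
  if (is.null(thresholds)) {
    thresholds <- sort(unique(y[!is.na(lab)]))
    if (length(thresholds) == 0L) thresholds <- sort(unique(y))
  } else if (is.unsorted(thresholds, strictly = FALSE)) {
    stop("`thresholds` must be sorted ascending")
  }
  out <- do.call(rbind, lapply(levels_, function(g) {
    yy <- y[!is.na(lab) & lab == g]
    data.frame(group = g, threshold = thresholds,
               share = if (length(yy)) stats::ecdf(yy)(thresholds)
                       else NA_real_,
               n = length(yy))
  }))
  structure(out, class = c("support_curve", "data.frame"))
}

#' Central tendencies of stated support
#'
#' @param responses Numeric vector, or a data frame whose numeric columns
#'   (e.g. `cash`, `doses`) are each summarized.
#' @return Data frame with columns `outcome`, `median`, `mean` (units
#'   preserved).
#' @export
summarize_central <- function(responses) {
  if (is.data.frame(responses)) {
    num <- names(responses)[vapply(responses, is.numeric, logical(1))]
    num <- setdiff(num, c("vignette_index"))
    if (!length(num)) stop("no numeric outcome columns to summarize")
    do.call(rbind, lapply(num, function(v)
      data.frame(outcome = v, median = stats::median(responses[[v]]),
                 mean = mean(responses[[v]]))))
  } else {
    if (!length(responses)) stop("empty input")
    data.frame(outcome = "value", median = stats::median(responses),
               mean = mean(responses))
  }
}

#' Beneficiary prioritization shares
#'
#' @param table Data frame with a `priority` column whose values are
#'   `"higher"`, `"equal"` or `"lower"` (priority of the foreign
#'   beneficiary relative to the domestic one).
#' @return Named numeric: `share_geq` (at least as high: strictly higher
#'   plus equal) and `share_strictly_higher`.
#' @export
priorities_shares <- function(table) {
  pr <- table$priority
  if (is.null(pr) || !length(pr)) stop("`table` must have `priority` rows")
  bad <- setdiff(unique(as.character(pr)), c("higher", "equal", "lower"))
  if (length(bad))
    stop("unknown priority categor(ies): ", paste(bad, collapse = ", "))
  c(share_geq = mean(pr %in% c("higher", "equal")),
    share_strictly_higher = mean(pr == "higher"))
}

#' Fair-share benchmark arithmetic
#'
#' A country's benchmark contribution as its donor-share fraction of an
#' estimated global funding need, e.g. 8\% of EUR 63bn ~ EUR 5bn.
#'
#' @param total_cost Estimated global cost, billion EUR (`>= 0`).
#' @param donor_share Country share of donor contributions, in `[0, 1]`.
#' @return List with `value` (exact product, billion EUR) and `presented`
#'   (rounded to the nearest billion for reporting).
#' @examples
#' fair_share(63, 0.08)
#' @export
fair_share <- function(total_cost, donor_share) {
  if (total_cost < 0) stop("`total_cost` must be >= 0")
  if (donor_share < 0 || donor_share > 1)
    stop("`donor_share` must be in [0, 1]")
  v <- total_cost * donor_share
  list(value = v, presented = round(v))
}
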