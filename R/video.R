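#' Average treatment effect of the information video
#'
#' Difference in means (treated minus control) for a two-arm randomized
#' experiment with one observation per respondent. The robust standard
#' error is HC2, which for a binary regressor reduces to the Welch form
#' `sqrt(s1^2/n1 + s0^2/n0)`; inference uses the normal reference
#' (samples here are in the thousands). The donation outcome is reported
#' in percentage points of the 50-point endowment (0-100 scale), so a
#' 2-point shift reads as a 4 pp effect.
#'
#' @param table Data frame with `treated` (0/1) and the outcome columns
#'   `attitude` and/or `donation_points`.
#' @param outcome `"attitude"`, `"donation"`, or the name of any numeric
#'   column in `table`.
#' @param level Confidence level.
#' @return One-row estimate table (term, estimate, std.error, statistic,
#'   p.value, conf.low, conf.high, n_treated, n_control, degenerate).
#'   `degenerate` flags a zero standard error (perfect separation).
#' @export
estimate_ate <- function(table, outcome = c("attitude", "donation"),
                         level = 0.95) {
  outcome <- outcome[1]
  if (!"treated" %in% names(table)) stop("`table` must have a `treated` column")
  z <- table$treated
  if (!all(z %in% 0:1)) stop("`treated` must be 0/1")
  y <- switch(outcome,
              donation = {
                if (!"donation_points" %in% names(table))
                  stop("no `donation_points` column")
                table$donation_points / 50 * 100
              },
              attitude = table[["attitude"]],
              table[[outcome]])
  if (is.null(y)) stop("unknown outcome column: ", outcome)
  n1 <- sum(z == 1); n0 <- sum(z == 0)
  if (n1 == 0L || n0 == 0L)
    stop("both arms must be nonempty (treated: ", n1, ", control: ", n0, ")")
  y1 <- y[z == 1]; y0 <- y[z == 0]
  ate <- mean(y1) - mean(y0)
  v1 <- if (n1 > 1) stats::var(y1) else 0
  v0 <- if (n0 > 1) stats::var(y0) else 0
  se <- sqrt(v1 / n1 + v0 / n0)
  degenerate <- se == 0
  stat <- if (degenerate) {
    if (ate == 0) 0 else sign(ate) * Inf
  } else ate / se
  zq <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(term = outcome, estimate = ate, std.error = se,
             statistic = stat,
             p.value = if (degenerate) NA_real_ else 2 * stats::pnorm(-abs(stat)),
             conf.low = ate - zq * se, conf.high = ate + zq * se,
             n_treated = n1, n_control = n0, degenerate = degenerate)
}

#' Summarize the donation distribution
#'
#' @param table Data frame with a `donation_points` column (0-50).
#' @return List with `median_share` (median donation as a percentage of
#'   the 50-point endowment), `modal_points` (most frequent point value;
#'   ties broken toward the smallest), and `share_full` (fraction
#'   donating all 50 points).
#' @examples
#' donation_distribution(data.frame(donation_points = c(0, 20, 50)))
#' @export
donation_distribution <- function(table) {
  pts <- table$donation_points
  if (is.null(pts) || length(pts) == 0L)
    stop("`table` must have a nonempty `donation_points` column")
  if (any(pts < 0 | pts > 50)) stop("donation points must lie in [0, 50]")
  tab <- table(pts)
  list(median_share = stats::median(pts) / 50 * 100,
       modal_points = as.numeric(names(tab)[which.max(tab)]),
       share_full = mean(pts == 50))
}
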