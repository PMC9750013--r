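#' Fixed-effects factorial regression
#'
#' Estimates the interacted factorial regression
#' `Y_ij = b0 + b1 X1 + ... + b14 X2X3X4 + nu_i + eps_ij`
#' with respondent fixed effects `nu_i` absorbed by within-respondent
#' demeaning. Because every condition column is centered, the main-term
#' coefficients read as average effects of each condition. Coefficients
#' equal those of the least-squares fit including one indicator column
#' per respondent (Frisch-Waugh); the demeaning route scales to large
#' panels without forming the dummy matrix.
#'
#' Robust variance options:
#' \describe{
#'   \item{`"cluster"` (default)}{CR1 cluster-robust by respondent, with a
#'     t reference on (clusters - 1) degrees of freedom; each respondent
#'     contributes two vignettes, so clustering is the defensible
#'     default.}
#'   \item{`"hc"`}{HC2 heteroskedasticity-robust on the absorbed model
#'     (leverages add the 1/n_i contribution of the absorbed respondent
#'     intercepts), t reference on n - rank - n_respondents df.}
#' }
#' The degrees of freedom count the absorbed intercepts in both flavors.
#' After demeaning the intercept is reported as the grand mean of the
#' outcome (`$grand_mean`), preserving its average-support reading.
#'
#' @param design A `"vs_design"` from [build_design_matrix()].
#' @param outcomes Numeric outcome vector, one value per design row.
#' @param se_flavor `"cluster"` or `"hc"`.
#' @param outcome_label Label stored with the fit (e.g. `"cash"`).
#' @param level Confidence level.
#' @return Object of class `"factorial_fit"`: `table` (term, estimate,
#'   std.error, statistic, p.value, conf.low, conf.high), `grand_mean`,
#'   `n_obs`, `n_respondents`, `df`, `se_flavor`, `outcome`,
#'   `main_terms`.
#' @export
fit_factorial_fe <- function(design, outcomes,
                             se_flavor = c("cluster", "hc"),
                             outcome_label = "cash", level = 0.95) {
  stopifnot(inherits(design, "vs_design"))
  se_flavor <- match.arg(se_flavor)
  X <- design$X
  n <- nrow(X)
  if (length(outcomes) != n)
    stop("`outcomes` must have one value per design row")
  if (anyNA(outcomes)) stop("`outcomes` contains missing values")
  id <- factor(design$respondent_id)
  G <- nlevels(id)
  sizes <- tabulate(id)
  if (any(sizes < 2L))
    stop("every respondent needs >= 2 observations for within-variation; ",
         sum(sizes < 2L), " respondent(s) have only one")

  # within-respondent demeaning (the absorbed nu_i)
  demean <- function(v) v - stats::ave(v, id)
  Xd <- apply(X, 2L, demean)
  Yd <- demean(outcomes)

  no_within <- apply(Xd, 2L, function(x) max(abs(x)) < 1e-12)
  if (any(no_within))
    stop("no within-respondent variation in regressor(s): ",
         paste(colnames(X)[no_within], collapse = ", "))

  qrx <- qr(Xd)
  k <- ncol(Xd)
  if (qrx$rank < k) {
    drop_cols <- colnames(Xd)[qrx$pivot[(qrx$rank + 1L):k]]
    stop("rank-deficient design after demeaning; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  beta <- qr.coef(qrx, Yd)
  resid <- Yd - Xd %*% beta
  XtXinv <- chol2inv(qr.R(qrx))
  unpiv <- order(qrx$pivot)
  XtXinv <- XtXinv[unpiv, unpiv, drop = FALSE]
  dimnames(XtXinv) <- list(colnames(Xd), colnames(Xd))
  k_total <- k + G  # slopes + absorbed intercepts

  if (se_flavor == "cluster") {
    # CR1: meat from cluster score sums, small-sample scale, t on G-1 df.
    # The absorbed respondent intercepts are nested within clusters, so they
    # are excluded from the (n-1)/(n-k) factor (else the variance roughly
    # doubles with two observations per respondent).
    Xe <- Xd * as.vector(resid)
    Sg <- rowsum(Xe, id)
    meat <- crossprod(Sg)
    scale <- (G / (G - 1)) * ((n - 1) / (n - k - 1))
    V <- scale * XtXinv %*% meat %*% XtXinv
    df <- G - 1
  } else {
    # HC2 on the absorbed model: hat of [dummies, X] splits as 1/n_i + h_x
    hx <- rowSums(qr.qy(qrx, diag(1, n, qrx$rank))^2)
    h <- hx + 1 / sizes[as.integer(id)]
    w <- pmin(h, 1 - 1e-8)
    omega <- as.vector(resid)^2 / (1 - w)
    meat <- crossprod(Xd * sqrt(omega))
    V <- XtXinv %*% meat %*% XtXinv
    df <- n - k_total
  }
  se <- sqrt(pmax(diag(V), 0))
  stat <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, sign(beta) * Inf))
  p <- 2 * stats::pt(-abs(stat), df = max(df, 1))
  tq <- stats::qt(1 - (1 - level) / 2, df = max(df, 1))
  out <- data.frame(term = colnames(X), estimate = as.vector(beta),
                    std.error = se, statistic = stat, p.value = p,
                    conf.low = as.vector(beta) - tq * se,
                    conf.high = as.vector(beta) + tq * se,
                    row.names = NULL)

  structure(list(table = out, grand_mean = mean(outcomes), n_obs = n,
                 n_respondents = G, df = df, se_flavor = se_flavor,
                 outcome = outcome_label, level = level,
                 main_terms = design$main_terms, vcov = V),
            class = "factorial_fit")
}

#' @export
print.factorial_fit <- function(x, ...) {
  cat("Factorial fixed-effects fit: outcome =", x$outcome,
      "| SE =", x$se_flavor, "\n")
  cat("  n_obs =", x$n_obs, " n_respondents =", x$n_respondents,
      " grand mean =", format(x$grand_mean, digits = 4), "\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Average marginal effects of the conditions
#'
#' With every condition centered at its sample mean, the four main-term
#' coefficients of the interacted model are the average effects of the
#' amount given by others (per billion EUR), the number of others giving
#' (per country), the mutation-risk scenario and the trade-loss scenario.
#' Returns those four rows with their confidence intervals.
#'
#' @param fit A `"factorial_fit"`.
#' @return The main-term subset of the estimate table, with a `label`
#'   column in natural units.
#' @export
marginal_effects_table <- function(fit) {
  stopifnot(inherits(fit, "factorial_fit"))
  lab <- c(amount = "Amount given by other countries (per billion EUR)",
           n_countries = "Number of others giving (per country)",
           risk = "Mutation risk increases (0/1)",
           trade = "Economy shrinks 5% (0/1)")
  tab <- fit$table[fit$table$term %in% fit$main_terms, , drop = FALSE]
  tab <- tab[match(fit$main_terms, tab$term), ]
  tab$label <- unname(lab[tab$term])
  rownames(tab) <- NULL
  tab
}
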