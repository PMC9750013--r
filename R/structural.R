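#' Structural parameter set for the public-goods contribution model
#'
#' The model assumes a respondent evaluates an own contribution `y`
#' (billion EUR), given other countries' total `S` and average `ybar`, by
#'
#'   u(y) = (alpha + beta * E + delta * H) * log(S + y)
#'          - gamma * (y - kappa * ybar)^2 - y^2
#'
#' where `E` and `H` are the 0/1 economic-risk and health-risk scenario
#' indicators. `alpha` is the baseline marginal benefit of total
#' contributions, `beta` and `delta` its increments under economic and
#' health risk, `gamma >= 0` weights peer benchmarking, `kappa` is the
#' multiple of the peer average the respondent targets, and `sigma > 0`
#' is the SD of the Gaussian reporting noise around the optimum.
#'
#' @param alpha,beta,delta Marginal-benefit parameters (billion-EUR scale).
#' @param gamma Peer-alignment weight, must be `>= 0`.
#' @param kappa Peer-benchmark multiplier.
#' @param sigma Reporting noise SD in billion EUR, must be `> 0`.
#' @return Object of class `"vs_params"` (a named list).
#' @examples
#' structural_params(alpha = 240, beta = 0, delta = 38,
#'                   gamma = 0.6, kappa = 5, sigma = 16)
#' @export
structural_params <- function(alpha, beta = 0, delta = 0, gamma = 0,
                              kappa = 1, sigma = 1) {
  p <- list(alpha = alpha, beta = beta, delta = delta,
            gamma = gamma, kappa = kappa, sigma = sigma)
  if (!all(vapply(p, function(v) is.numeric(v) && length(v) == 1L &&
                    is.finite(v), logical(1))))
    stop("all structural parameters must be finite scalars")
  if (sigma <= 0) stop("`sigma` must be > 0")
  if (gamma < 0) stop("`gamma` must be >= 0")
  structure(p, class = "vs_params")
}

#' Reference structural parameter values
#'
#' The parameter sextet used throughout as the generator's default truth:
#' alpha = 240.62, beta = -10.32, delta = 37.79, gamma = 0.61,
#' kappa = 5.22, sigma = 15.98 (billion-EUR scale).
#'
#' @return A [structural_params()] object.
#' @export
reference_params <- function() {
  structural_params(alpha = 240.62, beta = -10.32, delta = 37.79,
                    gamma = 0.61, kappa = 5.22, sigma = 15.98)
}

#' Scenario context for the structural model
#'
#' Maps factorial factor levels to the quantities entering the utility:
#' economic-risk indicator `E` (the trade factor), health-risk indicator
#' `H` (the risk factor), others' total contribution `S` (billion EUR) and
#' others' average contribution `ybar = S / n_countries` (0 when there is
#' no deal).
#'
#' @param trade,risk 0/1 factor indicators (vectors allowed).
#' @param deal Deal levels in 0..4.
#' @return Data frame with columns `econ_risk`, `health_risk`,
#'   `others_total`, `others_mean`.
#' @export
scenario_context <- function(trade, risk, deal) {
  stopifnot(all(trade %in% 0:1), all(risk %in% 0:1))
  cond <- deal_to_conditions(deal)
  data.frame(econ_risk = as.numeric(trade),
             health_risk = as.numeric(risk),
             others_total = as.numeric(cond$total_amount),
             others_mean = ifelse(cond$n_countries > 0,
                                  cond$total_amount / cond$n_countries, 0))
}

.ctx_check <- function(ctx) {
  req <- c("econ_risk", "health_risk", "others_total", "others_mean")
  miss <- setdiff(req, names(ctx))
  if (length(miss))
    stop("scenario context is missing: ", paste(miss, collapse = ", "))
  ctx
}

.marginal_benefit <- function(params, ctx) {
  params$alpha + params$beta * ctx$econ_risk + params$delta * ctx$health_risk
}

#' Evaluate the public-goods utility
#'
#' Computes `u(y) = M log(S + y) - gamma (y - kappa ybar)^2 - y^2` with
#' `M = alpha + beta E + delta H` and natural logarithm. `y` may be a
#' vector against a single-row context, or match the number of context
#' rows.
#'
#' @param y Own contribution(s), billion EUR, `>= 0`.
#' @param params A [structural_params()] object.
#' @param ctx A single-row (or recycled) [scenario_context()] data frame.
#' @return Numeric utility value(s).
#' @export
utility <- function(y, params, ctx) {
  stopifnot(inherits(params, "vs_params"))
  ctx <- .ctx_check(ctx)
  if (any(y < 0)) stop("`y` must be >= 0")
  S <- ctx$others_total
  if (any(S + y <= 0))
    stop("log domain error: need S + y > 0 (no deal and zero contribution)")
  M <- .marginal_benefit(params, ctx)
  M * log(S + y) - params$gamma * (y - params$kappa * ctx$others_mean)^2 - y^2
}

#' Optimal own contribution
#'
#' Maximizes the utility over `y >= 0`. The first-order condition
#' `M/(S+y) = 2 gamma (y - kappa ybar) + 2 y` expands to the quadratic
#' `2(gamma+1) y^2 + 2[(gamma+1) S - gamma kappa ybar] y
#'  - (2 gamma kappa ybar S + M) = 0`; with `M > 0` the constant term is
#' negative so there is exactly one positive root, which is the global
#' maximum on `y > max(0, -S)` (the objective is strictly concave there).
#'
#' @inheritParams utility
#' @param ctx A [scenario_context()] data frame (any number of rows).
#' @return `y*` in billion EUR, one value per context row.
#' @examples
#' p <- reference_params()
#' optimal_contribution(p, scenario_context(0, 0, 0))   # ~8.64
#' optimal_contribution(p, scenario_context(0, 0, 1))   # ~4.97
#' @export
optimal_contribution <- function(params, ctx) {
  stopifnot(inherits(params, "vs_params"))
  ctx <- .ctx_check(ctx)
  M <- .marginal_benefit(params, ctx)
  if (any(M <= 0))
    stop("marginal benefit alpha + beta*E + delta*H must be > 0 at every ",
         "design cell (violated for ", sum(M <= 0), " context row(s))")
  g <- params$gamma
  k <- params$kappa
  S <- ctx$others_total
  yb <- ctx$others_mean
  a <- 2 * (g + 1)
  b <- 2 * ((g + 1) * S - g * k * yb)
  cc <- -(2 * g * k * yb * S + M)
  root <- (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
  pmax(root, 0)
}

.join_experiment <- function(responses, assignments) {
  key_r <- paste(responses$respondent_id, responses$vignette_index, sep = "\r")
  key_a <- paste(assignments$respondent_id, assignments$vignette_index,
                 sep = "\r")
  idx <- match(key_r, key_a)
  if (anyNA(idx))
    stop("responses contain (respondent_id, vignette_index) pairs with no ",
         "matching vignette assignment")
  cbind(responses,
        assignments[idx, c("trade", "risk", "deal"), drop = FALSE])
}

#' Gaussian reporting log-likelihood
#'
#' The model assumes respondents report `y* + eps`, `eps ~ N(0, sigma^2)`,
#' independently across observations. Returns the summed Normal log-density
#' of the observed cash responses at the cell-specific optima.
#'
#' @param responses Data frame with `respondent_id`, `vignette_index`,
#'   `cash` (billion EUR).
#' @param assignments Data frame with `respondent_id`, `vignette_index`,
#'   `trade`, `risk`, `deal`.
#' @param params A [structural_params()] object.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(responses, assignments, params) {
  stopifnot(inherits(params, "vs_params"))
  dat <- .join_experiment(responses, assignments)
  ctx <- scenario_context(dat$trade, dat$risk, dat$deal)
  ystar <- optimal_contribution(params, ctx)
  sum(stats::dnorm(dat$cash, mean = ystar, sd = params$sigma, log = TRUE))
}

# negative log-likelihood on a pre-digested dataset: y, and the cell index
# into the 20-cell context grid, so y* is computed once per cell per call
.make_nll <- function(y, cell_idx, cell_ctx, fix_gamma = FALSE) {
  force(y); force(cell_idx); force(cell_ctx)
  # theta on optimizer scale: alpha, beta, delta, log(gamma), kappa, log(sigma)
  function(theta) {
    if (fix_gamma) {
      p <- list(alpha = theta[1], beta = theta[2], delta = theta[3],
                gamma = 0, kappa = theta[4], sigma = exp(theta[5]))
    } else {
      p <- list(alpha = theta[1], beta = theta[2], delta = theta[3],
                gamma = exp(theta[4]), kappa = theta[5],
                sigma = exp(theta[6]))
    }
    M <- p$alpha + p$beta * cell_ctx$econ_risk + p$delta * cell_ctx$health_risk
    if (any(!is.finite(M)) || any(M <= 0) || !is.finite(p$sigma) ||
        p$sigma <= 0 || !is.finite(p$gamma))
      return(1e10)
    g <- p$gamma; k <- p$kappa
    S <- cell_ctx$others_total; yb <- cell_ctx$others_mean
    a <- 2 * (g + 1)
    b <- 2 * ((g + 1) * S - g * k * yb)
    cc <- -(2 * g * k * yb * S + M)
    ystar <- pmax((-b + sqrt(b^2 - 4 * a * cc)) / (2 * a), 0)
    if (any(!is.finite(ystar))) return(1e10)
    nll <- -sum(stats::dnorm(y, ystar[cell_idx], p$sigma, log = TRUE))
    if (!is.finite(nll)) 1e10 else nll
  }
}

.theta_to_params <- function(theta, fix_gamma = FALSE) {
  if (fix_gamma)
    structural_params(theta[1], theta[2], theta[3], 0, theta[4], exp(theta[5]))
  else
    structural_params(theta[1], theta[2], theta[3], exp(theta[4]), theta[5],
                      exp(theta[6]))
}

#' Fit the structural model by maximum likelihood
#'
#' Maximizes the Gaussian reporting likelihood over
#' `(alpha, beta, delta, gamma, kappa, sigma)` with `gamma` and `sigma`
#' optimized on the log scale (keeping the optimizer in an open box),
#' using BFGS from several starting points. Standard errors come from the
#' inverse observed information (numeric Hessian of the negative
#' log-likelihood at the optimum, on the natural parameter scale);
#' statistics, two-sided normal p-values and Wald confidence intervals are
#' derived per row.
#'
#' @inheritParams log_likelihood
#' @param starts Number of starting points (first is a data-driven
#'   heuristic, the rest jittered).
#' @param seed Integer seed controlling the start-point jitter.
#' @param fix_gamma If `TRUE`, fixes `gamma = 0` (no peer benchmarking)
#'   and estimates the remaining five parameters.
#' @param level Confidence level for the Wald intervals.
#' @param min_per_cell Minimum observations required per occupied design
#'   cell before fitting.
#' @param control Passed to [stats::optim()].
#' @return Object of class `"structural_fit"`: `table` (term, estimate,
#'   std.error, statistic, p.value, conf.low, conf.high), `params` (the
#'   estimates as a [structural_params()] object), `loglik`,
#'   `convergence`, `se_ok`, `starts` (start-point record), `n_obs`.
#' @export
fit_mle <- function(responses, assignments, starts = 5, seed = 1L,
                    fix_gamma = FALSE, level = 0.95, min_per_cell = 2L,
                    control = list(maxit = 1000, reltol = 1e-10)) {
  dat <- .join_experiment(responses, assignments)
  if (!is.numeric(dat$cash)) stop("responses must carry a numeric `cash`")
  cell <- interaction(dat$trade, dat$risk, dat$deal, drop = TRUE)
  tab <- table(cell)
  if (any(tab < min_per_cell))
    stop("design cell(s) with fewer than ", min_per_cell, " observations: ",
         paste(names(tab)[tab < min_per_cell], collapse = ", "))
  cell_idx <- as.integer(cell)
  first <- !duplicated(cell_idx)
  cell_ctx <- scenario_context(dat$trade[first], dat$risk[first],
                               dat$deal[first])[order(cell_idx[first]), ]
  y <- dat$cash

  nll <- .make_nll(y, cell_idx, cell_ctx, fix_gamma = fix_gamma)

  # heuristic start: with gamma ~ 0.5 and no deal, y* ~ sqrt(M / (2(g+1)))
  g0 <- 0.5
  a0 <- max(2 * (g0 + 1) * mean(y)^2, 1)
  s0 <- max(stats::sd(y), 1e-3)
  base <- if (fix_gamma) c(a0, 0, 0, 1, log(s0))
          else c(a0, 0, 0, log(g0), 1, log(s0))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  start_list <- c(list(base), lapply(seq_len(max(starts - 1L, 0L)),
    function(i) base + stats::rnorm(length(base), 0, 0.4) *
                  pmax(abs(base), 1)))

  runs <- lapply(start_list, function(st) {
    tryCatch(stats::optim(st, nll, method = "BFGS", control = control),
             error = function(e) NULL)
  })
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok))
    stop("structural MLE failed on all ", length(runs), " starts")
  vals <- vapply(runs, function(r) if (is.null(r)) Inf else r$value,
                 numeric(1))
  best <- runs[[which.min(vals)]]
  if (min(vals) >= 1e10)
    stop("structural MLE did not reach an admissible parameter region ",
         "(marginal benefit must stay positive at all used cells)")

  est <- .theta_to_params(best$par, fix_gamma)
  terms <- if (fix_gamma) c("alpha", "beta", "delta", "kappa", "sigma")
           else c("alpha", "beta", "delta", "gamma", "kappa", "sigma")
  est_vec <- unlist(est[terms])

  # observed information on the natural scale
  nll_nat <- function(p_nat) {
    th <- if (fix_gamma) {
      if (p_nat[5] <= 0) return(1e10)
      c(p_nat[1:4], log(p_nat[5]))
    } else {
      if (p_nat[4] <= 0 || p_nat[6] <= 0) return(1e10)
      c(p_nat[1:3], log(p_nat[4]), p_nat[5], log(p_nat[6]))
    }
    nll(th)
  }
  se <- rep(NA_real_, length(est_vec))
  se_ok <- FALSE
  H <- tryCatch(stats::optimHess(est_vec, nll_nat), error = function(e) NULL)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && all(is.finite(diag(V))) && all(diag(V) > 0)) {
      se <- sqrt(diag(V))
      se_ok <- TRUE
    }
  }

  ci <- wald_ci(est_vec, ifelse(is.na(se), 1, se), level = level)
  stat <- est_vec / se
  out <- data.frame(term = terms,
                    estimate = unname(est_vec),
                    std.error = unname(se),
                    statistic = unname(stat),
                    p.value = 2 * stats::pnorm(-abs(unname(stat))),
                    conf.low = ifelse(is.na(se), NA_real_, ci$conf.low),
                    conf.high = ifelse(is.na(se), NA_real_, ci$conf.high))

  start_rec <- data.frame(start = seq_along(start_list),
                          value = vals,
                          convergence = vapply(runs, function(r)
                            if (is.null(r)) NA_integer_ else r$convergence,
                            integer(1)))
  structure(list(table = out, params = est, loglik = -best$value,
                 convergence = best$convergence, se_ok = se_ok,
                 starts = start_rec, n_obs = length(y),
                 fix_gamma = fix_gamma, seed = seed),
            class = "structural_fit")
}

#' @export
print.structural_fit <- function(x, ...) {
  cat("Structural public-goods model fit (MLE",
      if (x$fix_gamma) ", gamma fixed at 0" else "", ")\n", sep = "")
  cat("  n =", x$n_obs, " logLik =", format(x$loglik, digits = 8),
      " convergence =", x$convergence, "\n")
  if (!x$se_ok)
    cat("  WARNING: observed information not positive definite; ",
        "std. errors unavailable\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Wald confidence interval
#'
#' `estimate +/- z * std_error` with the full-precision normal quantile
#' (`qnorm(0.975) = 1.959964...` at the default level).
#'
#' @param estimate,std_error Numeric vectors (recycled).
#' @param level Confidence level in (0, 1).
#' @return Data frame with columns `conf.low`, `conf.high`.
#' @examples
#' wald_ci(240.62, 2.01)   # 236.68, 244.56
#' @export
wald_ci <- function(estimate, std_error, level = 0.95) {
  if (any(std_error <= 0)) stop("`std_error` must be > 0")
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)")
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(conf.low = estimate - z * std_error,
             conf.high = estimate + z * std_error)
}
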