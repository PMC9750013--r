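#' Default German demographic marginals
#'
#' Quota-style marginal distributions for age group (18-29 ... 60-75), sex
#' and the 16 federal states, taken from official national statistics for
#' the 18-75 population. Printed to two decimals the region column sums to
#' 1.01, so each table is renormalized to sum exactly to one.
#'
#' @return Named list of three named probability vectors: `age`, `sex`,
#'   `region`.
#' @export
german_margins <- function() {
  age <- c("18-29" = 0.18, "30-39" = 0.18, "40-49" = 0.16,
           "50-59" = 0.22, "60-75" = 0.26)
  sex <- c(female = 0.50, male = 0.50, other = 0.00)
  region <- c("Baden-Wurttemberg" = 0.13, "Bavaria" = 0.16, "Berlin" = 0.04,
              "Brandenburg" = 0.03, "Bremen" = 0.01, "Hamburg" = 0.02,
              "Hesse" = 0.08, "Mecklenburg-Vorpommern" = 0.02,
              "Lower Saxony" = 0.10, "North Rhine-Westphalia" = 0.22,
              "Rhineland-Palatinate" = 0.05, "Saarland" = 0.01,
              "Saxony" = 0.05, "Saxony-Anhalt" = 0.03,
              "Schleswig-Holstein" = 0.03, "Thuringia" = 0.03)
  lapply(list(age = age, sex = sex, region = region),
         function(m) m / sum(m))
}

.check_margin <- function(m, what) {
  if (any(m < 0)) stop(what, " margins contain negative probabilities")
  if (abs(sum(m) - 1) > 1e-9)
    stop(what, " margins must sum to 1 (got ", format(sum(m)), ")")
  if (is.null(names(m))) stop(what, " margins must be named")
  m
}

#' Simulation configuration
#'
#' Bundles everything the synthetic panel generator needs: cohort size,
#' the structural truth, respondent heterogeneity, censoring behaviour,
#' the cash-to-doses companion scaling, demographic margins and the master
#' seed. All downstream randomness is derived from `seed` via fixed
#' per-stage offsets, so identical configs reproduce identical tables.
#'
#' @param n_respondents Number of respondents (>= 1).
#' @param params True [structural_params()] generating the contributions.
#' @param heterogeneity_sd SD (billion EUR) of the additive respondent
#'   intercept `u_i`; set to 0 for data matching the iid reporting model.
#' @param censor_at_zero Censor negative simulated contributions at zero
#'   (stated contributions cannot be negative).
#' @param doses_per_billion Scaling from cash (billion EUR) to the doses
#'   outcome (million doses); default 12.5 reflects roughly EUR 80bn
#'   buying ~1bn doses at ~EUR 6-8 per dose.
#' @param doses_noise_sd SD (million doses) of the independent noise added
#'   to the doses outcome.
#' @param seed Master integer seed.
#' @param margins Demographic margins as from [german_margins()].
#' @return Object of class `"vs_config"`.
#' @export
sim_config <- function(n_respondents,
                       params = reference_params(),
                       heterogeneity_sd = 5,
                       censor_at_zero = TRUE,
                       doses_per_billion = 12.5,
                       doses_noise_sd = 25,
                       seed = 1L,
                       margins = german_margins()) {
  stopifnot(inherits(params, "vs_params"))
  if (n_respondents < 1) stop("`n_respondents` must be >= 1")
  if (heterogeneity_sd < 0) stop("`heterogeneity_sd` must be >= 0")
  if (doses_per_billion <= 0 || doses_noise_sd < 0)
    stop("invalid doses scaling/noise")
  for (w in c("age", "sex", "region")) .check_margin(margins[[w]], w)
  structure(list(n_respondents = as.integer(n_respondents), params = params,
                 heterogeneity_sd = heterogeneity_sd,
                 censor_at_zero = isTRUE(censor_at_zero),
                 doses_per_billion = doses_per_billion,
                 doses_noise_sd = doses_noise_sd,
                 seed = as.integer(seed), margins = margins),
            class = "vs_config")
}

# fixed per-stage seed streams derived from the master seed
.stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + stage * 1000003) %% .Machine$integer.max)
}

#' Generate a synthetic respondent roster
#'
#' Draws `n_respondents` respondents with age group, sex and federal state
#' sampled independently from the configured marginals (quotas in the real
#' survey target marginals, not joints), plus a latent mean-zero Normal
#' heterogeneity `u_i` in billion EUR that shifts all of a respondent's
#' stated contributions.
#'
#' @param config A [sim_config()] object.
#' @return Data frame: `respondent_id`, `age_group`, `sex`, `region`,
#'   `u_i`.
#' @export
generate_respondents <- function(config) {
  stopifnot(inherits(config, "vs_config"))
  n <- config$n_respondents
  m <- config$margins
  set.seed(.stage_seed(config$seed, 1L))
  data.frame(
    respondent_id = sprintf("R%06d", seq_len(n)),
    age_group = sample(names(m$age), n, TRUE, prob = m$age),
    sex = sample(names(m$sex), n, TRUE, prob = m$sex),
    region = sample(names(m$region), n, TRUE, prob = m$region),
    u_i = stats::rnorm(n, 0, config$heterogeneity_sd)
  )
}

#' Assign factorial vignettes
#'
#' Each respondent receives two vignettes in sequence, each drawn
#' uniformly and independently from the 20 cells of the 2 x 2 x 5 design.
#'
#' @param respondents Roster from [generate_respondents()].
#' @param seed Integer seed for the assignment draw.
#' @return Data frame: `respondent_id`, `vignette_index` (1 or 2),
#'   `trade`, `risk`, `deal`.
#' @export
assign_vignettes <- function(respondents, seed = 1L) {
  if (nrow(respondents) == 0L) stop("empty respondent roster")
  n <- nrow(respondents)
  grid <- vignette_grid()
  set.seed(.stage_seed(seed, 2L))
  cells <- sample.int(nrow(grid), 2L * n, replace = TRUE)
  out <- data.frame(
    respondent_id = rep(respondents$respondent_id, each = 2L),
    vignette_index = rep(1:2, n))
  cbind(out, grid[cells, c("trade", "risk", "deal")], row.names = NULL)
}

#' Simulate stated contributions
#'
#' Generates the two stated-support outcomes for each vignette from the
#' structural model: `cash = y*(cell) + u_i + eps`, `eps ~ N(0, sigma^2)`,
#' optionally censored at zero; and a doses companion
#' `doses = cash * doses_per_billion + noise` (million doses), censored
#' at zero alongside cash.
#'
#' @param assignments Output of [assign_vignettes()].
#' @param respondents Roster carrying `u_i`.
#' @param config A [sim_config()] object (its `params` are the truth).
#' @return Data frame: `respondent_id`, `vignette_index`, `cash`
#'   (billion EUR), `doses` (million doses).
#' @export
simulate_contributions <- function(assignments, respondents, config) {
  stopifnot(inherits(config, "vs_config"))
  p <- config$params  # structural_params() already enforced sigma>0, gamma>=0
  ctx <- scenario_context(assignments$trade, assignments$risk,
                          assignments$deal)
  ystar <- optimal_contribution(p, ctx)
  u <- respondents$u_i[match(assignments$respondent_id,
                             respondents$respondent_id)]
  if (anyNA(u)) stop("assignments reference unknown respondent ids")
  n <- nrow(assignments)
  set.seed(.stage_seed(config$seed, 3L))
  cash <- ystar + u + stats::rnorm(n, 0, p$sigma)
  doses <- cash * config$doses_per_billion +
    stats::rnorm(n, 0, config$doses_noise_sd)
  if (config$censor_at_zero) {
    cash <- pmax(cash, 0)
    doses <- pmax(doses, 0)
  }
  data.frame(respondent_id = assignments$respondent_id,
             vignette_index = assignments$vignette_index,
             cash = cash, doses = doses)
}

#' Simulate the information-video experiment
#'
#' Two-arm randomized design with Bernoulli(1/2) treatment. The
#' attitudinal outcome is `baseline + ate_attitude * Z + Normal noise`,
#' clipped to the scale bounds. The donation outcome (0-50 points, each
#' point worth 1.5 EUR to UNICEF in the real design) is a mixture: with
#' probability `p_full` the respondent donates the full 50 points
#' (mimicking the roughly one third of respondents who gave everything);
#' otherwise the donation is Binomial(49, p_z), whose mean is shifted by
#' `ate_donation_points / (1 - p_full)` under treatment so that the
#' marginal treated-minus-control mean equals `ate_donation_points`
#' exactly in expectation, with no boundary clipping.
#'
#' @param n Number of respondents.
#' @param ate_attitude True treatment effect on the attitudinal scale.
#' @param ate_donation_points True ATE on the 0-50 point scale (2 points
#'   = 4 percentage points of the endowment).
#' @param seed Integer seed.
#' @param p_full Probability of donating the full 50 points.
#' @param attitude_bounds Length-2 bounds of the attitudinal scale
#'   (default 1-7; the real scale lives in supplementary material, the
#'   default is arbitrary and documented as such).
#' @param attitude_baseline,attitude_sd Control-arm mean and noise SD of
#'   the attitude.
#' @param donation_mean Control-arm mean of the non-full donation (points).
#' @return Data frame: `respondent_id`, `treated`, `attitude`,
#'   `donation_points`, `donation_share`.
#' @export
simulate_video_experiment <- function(n, ate_attitude = 0.069,
                                      ate_donation_points = 2, seed = 1L,
                                      p_full = 1 / 3,
                                      attitude_bounds = c(1, 7),
                                      attitude_baseline = 4,
                                      attitude_sd = 1,
                                      donation_mean = 17.5) {
  if (ate_donation_points < 0 || ate_donation_points > 50)
    stop("`ate_donation_points` must be in [0, 50]")
  if (p_full < 0 || p_full >= 1) stop("`p_full` must be in [0, 1)")
  shift <- ate_donation_points / (1 - p_full)
  p0 <- donation_mean / 49
  p1 <- (donation_mean + shift) / 49
  if (p1 > 1 || p0 < 0)
    stop("donation mean/ATE incompatible with the 0-50 point scale")
  set.seed(.stage_seed(seed, 4L))
  z <- stats::rbinom(n, 1L, 0.5)
  att <- attitude_baseline + ate_attitude * z + stats::rnorm(n, 0, attitude_sd)
  att <- pmin(pmax(att, attitude_bounds[1]), attitude_bounds[2])
  full <- stats::rbinom(n, 1L, p_full) == 1L
  pts <- integer(n)
  pts[full] <- 50L
  pz <- ifelse(z == 1L, p1, p0)[!full]
  pts[!full] <- stats::rbinom(sum(!full), 49L, pz)
  data.frame(respondent_id = sprintf("V%06d", seq_len(n)),
             treated = z, attitude = att,
             donation_points = pts, donation_share = pts / 50)
}

#' Simulate beneficiary-prioritization responses
#'
#' Three-category answer to whether an older woman in a poorer country
#' should be prioritized strictly higher than, equal to, or lower than a
#' younger woman at home: P(higher) = `p_gt`, P(equal) = `p_geq - p_gt`,
#' P(lower) = `1 - p_geq`. The defaults use the observed 57% at-least /
#' 38% strictly-higher shares as simulation truth.
#'
#' @param n Number of respondents.
#' @param p_geq Probability of priority at least as high.
#' @param p_gt Probability of strictly higher priority (`<= p_geq`).
#' @param seed Integer seed.
#' @return Data frame: `respondent_id`, `priority` in
#'   `{"higher","equal","lower"}`.
#' @export
simulate_priorities <- function(n, p_geq = 0.57, p_gt = 0.38, seed = 1L) {
  if (!(p_gt >= 0 && p_gt <= p_geq && p_geq <= 1))
    stop("need 0 <= p_gt <= p_geq <= 1")
  set.seed(.stage_seed(seed, 5L))
  lev <- c("higher", "equal", "lower")
  pr <- c(p_gt, p_geq - p_gt, 1 - p_geq)
  data.frame(respondent_id = sprintf("P%06d", seq_len(n)),
             priority = sample(lev, n, TRUE, prob = pr))
}
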