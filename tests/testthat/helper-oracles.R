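# Independent oracles and small fixtures used across test files.

# Brute-force grid maximization of the public-goods utility over y in
# [0, upper]. Codes the objective directly; independent of the
# closed-form first-order-condition root used in production.
grid_argmax_utility <- function(params, ctx, upper = 100, step = 1e-3) {
  y <- seq(0, upper, by = step)
  S <- ctx$others_total
  if (S == 0) y <- y[y > 0]  # log(0) at the no-deal boundary
  M <- params$alpha + params$beta * ctx$econ_risk +
    params$delta * ctx$health_risk
  u <- M * log(S + y) - params$gamma * (y - params$kappa * ctx$others_mean)^2 -
    y^2
  y[which.max(u)]
}

# Hand-coded Normal log-density sum (no dnorm): the density-evaluation
# oracle for the reporting likelihood.
density_sum_oracle <- function(y, mu, sigma) {
  sum(-0.5 * log(2 * pi * sigma^2) - (y - mu)^2 / (2 * sigma^2))
}

# Small synthetic panel: roster + assignments + contribution responses.
make_panel <- function(n = 100, seed = 1, params = reference_params(),
                       heterogeneity_sd = 5, censor = TRUE) {
  cfg <- sim_config(n, params = params, heterogeneity_sd = heterogeneity_sd,
                    censor_at_zero = censor, seed = seed)
  roster <- generate_respondents(cfg)
  asg <- assign_vignettes(roster, seed = seed)
  resp <- simulate_contributions(asg, roster, cfg)
  list(config = cfg, roster = roster, assignments = asg, responses = resp)
}

# Hand-built assignments on given cells (row indices into vignette_grid()).
assignments_from_cells <- function(cells) {
  stopifnot(length(cells) %% 2 == 0)
  n <- length(cells) / 2
  grid <- vignette_grid()
  data.frame(respondent_id = rep(sprintf("T%04d", seq_len(n)), each = 2),
             vignette_index = rep(1:2, n),
             grid[cells, c("trade", "risk", "deal")], row.names = NULL)
}
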