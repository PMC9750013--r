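test_that("respondent roster honors size, margins and determinism", {
  cfg <- sim_config(5, seed = 42)
  r <- generate_respondents(cfg)
  expect_equal(nrow(r), 5L)
  expect_false(anyDuplicated(r$respondent_id) > 0)
  expect_true(all(r$age_group %in% names(german_margins()$age)))
  expect_true(all(r$region %in% names(german_margins()$region)))

  # default female probability is 0.50; binomial concentration at n = 1e5
  cfg <- sim_config(100000, seed = 7)
  r <- generate_respondents(cfg)
  expect_lt(abs(mean(r$sex == "female") - 0.50), 0.01)
  expect_lt(abs(mean(r$u_i)), 3 * cfg$heterogeneity_sd / sqrt(100000))

  # identical config + seed -> identical table
  expect_identical(generate_respondents(cfg), generate_respondents(cfg))

  bad <- german_margins()
  bad$age[1] <- bad$age[1] + 0.1
  expect_error(sim_config(10, margins = bad), "sum to 1")
  expect_error(sim_config(0), "n_respondents")
  expect_error(sim_config(10, heterogeneity_sd = -1), "heterogeneity_sd")
})

test_that("vignette assignment is two-per-respondent, uniform over 20 cells", {
  cfg <- sim_config(3, seed = 1)
  a <- assign_vignettes(generate_respondents(cfg), seed = 1)
  expect_equal(nrow(a), 6L)
  expect_equal(as.integer(table(a$respondent_id)), rep(2L, 3))
  expect_equal(sort(unique(a$vignette_index)), 1:2)
  expect_error(assign_vignettes(generate_respondents(cfg)[0, ]), "empty")

  cfg <- sim_config(20000, seed = 5)
  r <- generate_respondents(cfg)
  a <- assign_vignettes(r, seed = 5)
  freq <- table(interaction(a$trade, a$risk, a$deal)) / nrow(a)
  expect_equal(length(freq), 20L)
  expect_lt(max(abs(freq - 0.05)), 0.006)  # ~5 binomial SDs at n = 40000
  expect_identical(a, assign_vignettes(r, seed = 5))
})

test_that("contributions follow the structural mechanism", {
  # noiseless limit: cash equals the cell optimum exactly
  p0 <- structural_params(240.62, -10.32, 37.79, 0.61, 5.22, sigma = 1e-9)
  cfg <- sim_config(40, params = p0, heterogeneity_sd = 0, seed = 2)
  r <- generate_respondents(cfg)
  a <- assign_vignettes(r, seed = 2)
  resp <- simulate_contributions(a, r, cfg)
  ystar <- optimal_contribution(p0, scenario_context(a$trade, a$risk, a$deal))
  expect_equal(resp$cash, ystar, tolerance = 1e-6)
  # the reference cell value: no deal, no risks -> 8.64 (2 dp)
  i <- which(a$deal == 0 & a$risk == 0 & a$trade == 0)
  if (length(i)) expect_equal(round(resp$cash[i[1]], 2), 8.64)

  # censoring contract and mean ordering on the same draws
  cfg_on <- sim_config(400, heterogeneity_sd = 30, seed = 3,
                       censor_at_zero = TRUE)
  cfg_off <- sim_config(400, heterogeneity_sd = 30, seed = 3,
                        censor_at_zero = FALSE)
  r <- generate_respondents(cfg_off)
  a <- assign_vignettes(r, seed = 3)
  on <- simulate_contributions(a, generate_respondents(cfg_on), cfg_on)
  off <- simulate_contributions(a, r, cfg_off)
  expect_gte(min(on$cash), 0)
  expect_gte(min(on$doses), 0)
  expect_gte(mean(on$cash), mean(off$cash))
  expect_lt(min(off$cash), 0)  # censoring was doing real work

  expect_error(simulate_contributions(a[1:4, ],
                                      r[r$respondent_id == "zzz", ], cfg_off),
               "unknown respondent")
})

test_that("within-cell means converge to the cell optimum with censoring off", {
  p <- make_panel(n = 6000, seed = 8, heterogeneity_sd = 0, censor = FALSE)
  dat <- merge_experiment(p$responses, p$assignments)
  cellmean <- aggregate(cash ~ trade + risk + deal, dat, mean)
  ystar <- optimal_contribution(
    reference_params(),
    scenario_context(cellmean$trade, cellmean$risk, cellmean$deal))
  ncell <- aggregate(cash ~ trade + risk + deal, dat, length)$cash
  tol <- 4.5 * 15.98 / sqrt(min(ncell))
  expect_lt(max(abs(cellmean$cash - ystar)), tol)
})

test_that("video experiment generator matches its contracts", {
  v <- simulate_video_experiment(2000, ate_attitude = 0, ate_donation_points = 0,
                                 seed = 6)
  expect_true(all(v$donation_points >= 0 & v$donation_points <= 50))
  expect_true(all(v$attitude >= 1 & v$attitude <= 7))
  expect_equal(v$donation_share, v$donation_points / 50)
  # null: group means equal within Monte-Carlo error
  d0 <- mean(v$donation_points[v$treated == 1]) -
    mean(v$donation_points[v$treated == 0])
  expect_lt(abs(d0), 4 * 15 / sqrt(500))

  v <- simulate_video_experiment(50000, ate_donation_points = 2, seed = 9)
  est <- mean(v$donation_points[v$treated == 1]) -
    mean(v$donation_points[v$treated == 0])
  expect_lt(abs(est - 2), 0.3)
  expect_lt(abs(mean(v$donation_points == 50) - 1 / 3), 0.01)

  expect_error(simulate_video_experiment(10, ate_donation_points = 60),
               "ate_donation_points")
})

test_that("prioritization generator matches the three-category law", {
  expect_true(all(simulate_priorities(50, p_geq = 1, p_gt = 0)$priority == "equal"))
  expect_true(all(simulate_priorities(50, p_geq = 0, p_gt = 0)$priority == "lower"))
  pr <- simulate_priorities(100000, p_geq = 0.57, p_gt = 0.38, seed = 10)
  expect_lt(abs(mean(pr$priority %in% c("higher", "equal")) - 0.57), 0.01)
  expect_lt(abs(mean(pr$priority == "higher") - 0.38), 0.01)
  expect_error(simulate_priorities(10, p_geq = 0.3, p_gt = 0.5), "p_gt")
})
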