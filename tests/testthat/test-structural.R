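ref <- reference_params()
nodeal <- scenario_context(0, 0, 0)

test_that("utility evaluates the stated objective exactly", {
  p <- structural_params(alpha = 1, sigma = 1)
  expect_equal(utility(1, p, nodeal), -1)  # log(1) = 0, cost -1
  p0 <- structural_params(alpha = 0, sigma = 1)
  ctx <- data.frame(econ_risk = 0, health_risk = 0, others_total = 1,
                    others_mean = 1)
  expect_equal(utility(2, p0, ctx), -4)
  # reference parameters, no deal / no risks, y = 8.644
  expect_equal(round(utility(8.644, ref, nodeal), 1), 398.7)
  u_oracle <- 240.62 * log(8.644) - 0.61 * 8.644^2 - 8.644^2
  expect_equal(utility(8.644, ref, nodeal), u_oracle)
  expect_error(utility(0, p, nodeal), "log domain")
  expect_error(utility(-1, p, nodeal), ">= 0")
})

test_that("closed-form optimum matches the grid oracle and the anchors", {
  p <- structural_params(alpha = 2, sigma = 1)  # gamma=0, S=0, M=2
  expect_equal(optimal_contribution(p, nodeal), 1)
  expect_equal(round(optimal_contribution(ref, nodeal), 2), 8.64)
  expect_equal(round(optimal_contribution(ref, scenario_context(0, 0, 1)), 2),
               4.97)
  expect_equal(optimal_contribution(ref, nodeal),
               grid_argmax_utility(ref, nodeal), tolerance = 1e-3)

  bad <- structural_params(alpha = 5, beta = -10, sigma = 1)
  expect_error(optimal_contribution(bad, scenario_context(1, 0, 0)),
               "marginal benefit")
})

test_that("optimum properties: oracle equivalence, maximality, monotonicity", {
  set.seed(31)
  grid <- vignette_grid()
  for (i in 1:200) {
    p <- structural_params(alpha = runif(1, 50, 400), beta = runif(1, -40, 40),
                           delta = runif(1, -40, 80), gamma = runif(1, 0, 2),
                           kappa = runif(1, 0, 8), sigma = 1)
    cell <- grid[sample.int(20, 1), ]
    ctx <- scenario_context(cell$trade, cell$risk, cell$deal)
    M <- p$alpha + p$beta * ctx$econ_risk + p$delta * ctx$health_risk
    if (M <= 0) next
    ys <- optimal_contribution(p, ctx)
    expect_equal(ys, grid_argmax_utility(p, ctx, upper = 60),
                 tolerance = 1e-3)
    h <- 1e-4
    u0 <- utility(ys, p, ctx)
    expect_gte(u0, utility(ys + h, p, ctx))
    if (ys > h) expect_gte(u0, utility(ys - h, p, ctx))
  }

  # y* strictly increasing in the marginal benefit (here via delta at H=1)
  ctx <- scenario_context(0, 1, 2)
  ys <- vapply(c(0, 20, 40, 60), function(d)
    optimal_contribution(structural_params(200, 0, d, 0.5, 2, 1), ctx),
    numeric(1))
  expect_true(all(diff(ys) > 0))
  # and increasing in kappa when gamma > 0 and ybar > 0
  ys <- vapply(c(0.5, 2, 5, 8), function(k)
    optimal_contribution(structural_params(200, 0, 0, 0.8, k, 1), ctx),
    numeric(1))
  expect_true(all(diff(ys) > 0))
})

test_that("log-likelihood is the Normal density sum at the cell optima", {
  p <- structural_params(240.62, -10.32, 37.79, 0.61, 5.22, sigma = 1)
  a <- assignments_from_cells(c(1, 6, 11, 20))
  ystar <- optimal_contribution(p, scenario_context(a$trade, a$risk, a$deal))
  one <- data.frame(respondent_id = a$respondent_id[1],
                    vignette_index = a$vignette_index[1], cash = ystar[1])
  expect_equal(log_likelihood(one, a, p), -0.5 * log(2 * pi))

  set.seed(12)
  resp <- data.frame(respondent_id = a$respondent_id,
                     vignette_index = a$vignette_index,
                     cash = ystar + rnorm(4, 0, 3))
  ll <- log_likelihood(resp, a, p)
  expect_equal(ll, density_sum_oracle(resp$cash, ystar, 1), tolerance = 1e-10)
  # duplicating the dataset doubles the log-likelihood exactly
  a2 <- rbind(a, transform(a, respondent_id = paste0("d", respondent_id)))
  r2 <- rbind(resp, transform(resp, respondent_id = paste0("d", respondent_id)))
  expect_equal(log_likelihood(r2, a2, p), 2 * ll)

  orphan <- transform(resp, respondent_id = "nobody")
  expect_error(log_likelihood(orphan, a, p), "no matching")
})

test_that("Wald intervals use the full-precision normal quantile", {
  expect_equal(round(unlist(wald_ci(240.62, 2.01)), 2),
               c(conf.low = 236.68, conf.high = 244.56))
  expect_equal(round(unlist(wald_ci(5.22, 0.40)), 2),
               c(conf.low = 4.44, conf.high = 6.00))
  ci <- wald_ci(0, 1)
  expect_equal(ci$conf.low, -qnorm(0.975))
  expect_equal(round(ci$conf.high, 2), 1.96)
  expect_error(wald_ci(1, 0), "std_error")
  expect_error(wald_ci(1, 1, level = 1.2), "level")
})

test_that("MLE recovers a well-identified truth and reports coherent inference", {
  # low reporting noise keeps the likelihood well curved; see the methods
  # vignette for why the published noise level makes the surface a ridge
  truth <- structural_params(240.62, -10.32, 37.79, 0.61, 5.22, sigma = 2)
  p <- make_panel(n = 800, seed = 21, params = truth, heterogeneity_sd = 0,
                  censor = FALSE)
  fit <- fit_mle(p$responses, p$assignments, starts = 4, seed = 21)
  expect_s3_class(fit, "structural_fit")
  expect_equal(fit$convergence, 0)
  expect_true(fit$se_ok)
  tv <- unlist(truth)[fit$table$term]
  expect_true(all(abs(fit$table$estimate - tv) <= 3 * fit$table$std.error))
  # statistic and CI arithmetic per row
  expect_equal(fit$table$statistic,
               fit$table$estimate / fit$table$std.error)
  expect_equal((fit$table$conf.low + fit$table$conf.high) / 2,
               fit$table$estimate, tolerance = 1e-8)
  # noiseless identifiability: truth beats perturbed vectors
  ystar <- optimal_contribution(truth, scenario_context(
    p$assignments$trade, p$assignments$risk, p$assignments$deal))
  exact <- data.frame(respondent_id = p$assignments$respondent_id,
                      vignette_index = p$assignments$vignette_index,
                      cash = ystar)
  t_small <- structural_params(240.62, -10.32, 37.79, 0.61, 5.22, sigma = 0.05)
  ll0 <- log_likelihood(exact, p$assignments, t_small)
  for (j in 1:5) {
    pert <- structural_params(240.62 * 1.1, -10.32, 37.79 + 2 * j, 0.61,
                              5.22 - 0.1 * j, sigma = 0.05)
    expect_gt(ll0, log_likelihood(exact, p$assignments, pert))
  }
})

test_that("MLE estimation error shrinks with sample size", {
  truth <- structural_params(240.62, -10.32, 37.79, 0.61, 5.22, sigma = 2)
  err <- vapply(c(300, 3000), function(n) {
    p <- make_panel(n = n, seed = 22, params = truth, heterogeneity_sd = 0,
                    censor = FALSE)
    fit <- fit_mle(p$responses, p$assignments, starts = 3, seed = 22)
    tv <- unlist(truth)[fit$table$term]
    sqrt(mean(((fit$table$estimate - tv) / tv)^2))
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("gamma can be fixed at zero", {
  truth <- structural_params(200, 0, 30, 0, 1, sigma = 2)
  p <- make_panel(n = 400, seed = 23, params = truth, heterogeneity_sd = 0,
                  censor = FALSE)
  fit <- fit_mle(p$responses, p$assignments, starts = 3, seed = 23,
                 fix_gamma = TRUE)
  expect_equal(fit$table$term, c("alpha", "beta", "delta", "kappa", "sigma"))
  expect_equal(fit$params$gamma, 0)
})
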