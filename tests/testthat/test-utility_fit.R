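test_that("the weighting function obeys its closed-form anchors", {
  p <- seq(0, 1, by = 0.05)
  expect_equal(prospect_weight(p, 1), p)
  for (g in c(0.3, 0.6, 1, 2.5)) {
    expect_equal(prospect_weight(0, g), 0)
    expect_equal(prospect_weight(1, g), 1)
    expect_true(all(diff(prospect_weight(p, g)) > -1e-12)) # monotone
  }
  expect_equal(prospect_weight(0.1, 0.6), 0.18797, tolerance = 1e-4)
  # inverse-S for gamma < 1: overweight low, underweight high probabilities
  expect_gt(prospect_weight(0.05, 0.5), 0.05)
  expect_lt(prospect_weight(0.95, 0.5), 0.95)
  expect_error(prospect_weight(0.5, 0), "gamma")
  expect_error(prospect_weight(1.5, 1), "\\[0, 1\\]")
})

test_that("gamma fitting recovers noiseless curves and the identity", {
  p <- c(0.05, 0.2, 0.35, 0.5, 0.65, 0.8, 0.95)
  ident <- fit_gamma(data.frame(p = p, w = p))
  expect_lt(abs(ident$log_gamma), 0.05)

  exact <- fit_gamma(data.frame(p = p, w = prospect_weight(p, 0.6)))
  expect_equal(exact$gamma, 0.6, tolerance = 1e-3)

  # scale stability: duplicating every pair changes nothing
  dup <- fit_gamma(data.frame(p = rep(p, 2), w = rep(prospect_weight(p, 0.6), 2)))
  expect_equal(dup$gamma, exact$gamma, tolerance = 1e-6)

  expect_error(fit_gamma(data.frame(p = rep(0.5, 5), w = runif(5))),
               "not identifiable")
})

test_that("gamma fitting finds the global minimum on S-shaped data", {
  p <- c(0.2, 0.35, 0.5, 0.65, 0.8)
  for (g in c(0.3, 2, 5)) {
    fit <- fit_gamma(data.frame(p = p, w = prospect_weight(p, g)))
    expect_equal(fit$gamma, g, tolerance = 1e-2)
  }
})

test_that("empirical choice curves reflect the choice policy", {
  fu <- make_followup(c(0.5, 0.55, 0.65, 0.78, 0.89, 0.95, 0.97, 0.99),
                      coherence = task_config()$coherence_levels)
  offers <- expand.grid(coherence = task_config()$coherence_levels,
                        p_external = task_config()$external_probabilities)
  base <- make_trials(nrow(offers), coherence = offers$coherence,
                      p_external = offers$p_external)

  always <- base
  always$chose_internal <- TRUE
  cv <- empirical_choice_curve(always, fu, "internal")
  expect_true(all(cv$w == 1))

  optimal <- base
  optimal$chose_internal <- followup_p_correct(fu, base$coherence) >= base$p_external
  for (side in c("internal", "external")) {
    cv <- empirical_choice_curve(optimal, fu, side)
    expect_equal(cv$w, cv$p)
  }
})

test_that("a distorted stochastic chooser produces an inverse-S empirical curve", {
  fu <- make_followup(c(0.5, 0.55, 0.65, 0.78, 0.89, 0.95, 0.97, 0.99),
                      coherence = task_config()$coherence_levels)
  offers <- expand.grid(coherence = task_config()$coherence_levels,
                        p_external = task_config()$external_probabilities)
  set.seed(61)
  reps <- 60
  tr <- make_trials(nrow(offers) * reps,
                    coherence = rep(offers$coherence, reps),
                    p_external = rep(offers$p_external, reps))
  # choice probability probability-matched through the distorted optimality rate
  p_opt <- ave(as.numeric(followup_p_correct(fu, tr$coherence) >= tr$p_external),
               tr$coherence)
  tr$chose_internal <- runif(nrow(tr)) < prospect_weight(p_opt, 0.6)
  cv <- empirical_choice_curve(tr, fu, "internal")
  fit <- fit_gamma(cv)
  expect_lt(fit$gamma, 0.85)
  # overestimation at low p, underestimation at high p
  expect_gt(cv$w[which.min(cv$p)], cv$p[which.min(cv$p)] - 0.05)
  expect_lt(cv$w[which.max(cv$p)], cv$p[which.max(cv$p)])
})

test_that("risk metrics are the Bernoulli moments of the reward stream", {
  tr <- make_trials(10, rewarded = TRUE)
  expect_equal(risk_metrics(tr, "internal")[c("reward_rate", "outcome_variance")],
               list(reward_rate = 1, outcome_variance = 0))
  tr2 <- make_trials(10, perceptual_correct = rep(c(TRUE, FALSE), 5))
  tr2$rewarded <- tr2$perceptual_correct
  expect_equal(risk_metrics(tr2, "internal")$reward_rate, 0.5)
  expect_equal(risk_metrics(tr2, "internal")$outcome_variance, 0.25)
  expect_error(risk_metrics(tr, "external"), "no trials")
})

test_that("simulated reward rates are matched across options within a few points", {
  sim <- sim_with_followup(n_sessions = 6, seed = 67)
  ri <- risk_metrics(sim$main, "internal")$reward_rate
  re <- risk_metrics(sim$main, "external")$reward_rate
  expect_lt(abs(ri - re), 0.15)
  expect_gt(ri, 0.6); expect_lt(ri, 0.95)
})
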