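make_history_log <- function() {
  # crafted encounter sequence: I I E I E E I I ... with known outcomes
  chose <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE)
  correct <- c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE)
  rewarded <- correct & c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE)
  tr <- make_trials(10, coherence = rep(c(0.06, 0.25), 5),
                    p_external = rep(c(0.3, 0.8), 5),
                    chose_internal = chose)
  tr$perceptual_correct <- correct
  tr$rewarded <- rewarded & correct
  session_log(tr)
}

test_that("lagged design uses encounters of the matching task type", {
  log <- make_history_log()
  d <- build_lagged_design(log, "choice", n_lags = 1)
  # first usable trial needs one internal and one external encounter:
  # internal encounters at 1,2,4,7,8,10; external at 3,5,6,9 -> usable from trial 4
  expect_equal(nrow(d$X), 7)
  # reconstruct unscaled lag-1 internal outcome for trial 4..10
  tr <- log$trials
  outcome <- ifelse(tr$chose_internal, tr$perceptual_correct, tr$rewarded)
  expected_o_int1 <- outcome[c(2, 4, 4, 4, 7, 8, 8)] # most recent internal encounter
  # z-scoring is affine, so correlation with the expected raw lags must be 1
  expect_equal(abs(cor(d$X[, "o_int_1"], as.numeric(expected_o_int1))), 1)
})

test_that("rows with incomplete histories are dropped, never imputed", {
  tr <- make_trials(8, chose_internal = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
                    coherence = 0.12, p_external = 0.5)
  d <- build_lagged_design(session_log(tr), "choice", n_lags = 3)
  # three external encounters exist only after trial 3; three internal after trial 6
  expect_equal(nrow(d$X), 2) # trials 7 and 8
  expect_equal(d$n_dropped, 6)
})

test_that("predictors are z-scored within session and degenerate columns flagged", {
  sim <- sim_with_followup(n_sessions = 2, seed = 31)
  d <- build_lagged_design(sim$main, "choice")
  for (s in unique(d$session)) {
    sub <- d$X[d$session == s, ]
    expect_equal(unname(colMeans(sub)), rep(0, ncol(sub)), tolerance = 1e-10)
    expect_equal(unname(apply(sub, 2, sd)), rep(1, ncol(sub)), tolerance = 1e-10)
  }
  expect_length(d$degenerate, 0)

  tr <- make_trials(30, coherence = 0.12, p_external = 0.5,
                    chose_internal = rep(c(TRUE, FALSE), 15),
                    perceptual_correct = rep(c(TRUE, FALSE), 15))
  tr$rewarded <- tr$perceptual_correct
  d2 <- build_lagged_design(session_log(tr), "choice", n_lags = 1)
  expect_true("x_int" %in% d2$degenerate) # single coherence -> constant
  expect_error(fit_logistic(d2$X, d2$y), "degenerate")
})

test_that("lag histories never cross session boundaries", {
  log <- make_history_log()
  tr2 <- log$trials
  tr2$session_id <- "s2"
  both <- session_log(rbind(log$trials, tr2))
  d_both <- build_lagged_design(both, "choice", n_lags = 1)
  d_one <- build_lagged_design(log, "choice", n_lags = 1)
  expect_equal(nrow(d_both$X), 2 * nrow(d_one$X))
  expect_equal(d_both$X[d_both$session == "s2", ], d_one$X, ignore_attr = TRUE)
})

test_that("coherence linearization maps the ladder onto [0, 1]", {
  levels <- task_config()$coherence_levels
  r <- coherence_transform(levels, levels, "rank")
  expect_equal(r, (0:7) / 7)
  l <- coherence_transform(levels, levels, "log")
  expect_equal(range(l), c(0, 1))
  expect_true(all(diff(l) > 0))
  expect_error(coherence_transform(0.2, levels), "not on the configured ladder")
})

test_that("the IRLS fitter agrees with glm to high precision", {
  set.seed(51)
  n <- 800
  X <- cbind(a = rnorm(n), b = rnorm(n), c = runif(n))
  y <- as.numeric(runif(n) < plogis(0.3 + 0.8 * X[, 1] - 1.2 * X[, 2]))
  fit <- fit_logistic(X, y)
  ref <- glm(y ~ X, family = binomial())
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(summary(ref)$coefficients[, 2]),
               tolerance = 1e-4)
})

test_that("null predictors yield near-zero slopes and separation is detected", {
  set.seed(52)
  n <- 5000
  X <- cbind(u = rnorm(n), v = rnorm(n))
  y <- rbinom(n, 1, 0.5)
  fit <- fit_logistic(X, y)
  expect_true(all(abs(fit$coefficients[-1]) < 3 * fit$se[-1]))

  Xs <- cbind(z = c(rnorm(50, -3), rnorm(50, 3)))
  ys <- rep(c(0, 1), each = 50)
  expect_error(fit_logistic(Xs, ys), "perfect separation.*z")
})

test_that("simulated choices recover the paper-pattern coefficient signs", {
  sim <- sim_with_followup(n_sessions = 8, seed = 53)
  fit <- fit_logistic(build_lagged_design(sim$main, "choice"))
  expect_gt(fit$coefficients[["x_int"]], 0)
  expect_lt(fit$coefficients[["x_ext"]], 0)

  perf <- fit_logistic(build_lagged_design(sim$main, "performance", side = "internal"))
  expect_gt(perf$coefficients[["x_int"]], 0)
  # selection effect: a better rejected external offer predicts better
  # internal performance
  expect_gt(perf$coefficients[["x_ext"]], 0)
})

test_that("the decision-variable model behaves as a choice readout", {
  fu <- make_followup(c(0.55, 0.70, 0.80, 0.95),
                      coherence = c(0.03, 0.06, 0.12, 0.25))
  # deterministic sign(DV) chooser -> separation
  offers <- expand.grid(coherence = c(0.03, 0.06, 0.12, 0.25),
                        p_external = c(0.1, 0.3, 0.5, 0.9))
  tr <- make_trials(nrow(offers), coherence = offers$coherence,
                    p_external = offers$p_external)
  dv <- followup_p_correct(fu, tr$coherence) - tr$p_external
  tr <- tr[abs(dv) > 1e-9, ]
  tr$chose_internal <- (followup_p_correct(fu, tr$coherence) - tr$p_external) > 0
  expect_error(fit_dv_model(session_log(tr), fu), "separation")

  # slope grows with the generating inverse temperature
  slopes <- vapply(c(2, 8), function(b) {
    sim <- sim_with_followup(agent = agent_params(choice_beta = b),
                             n_sessions = 3, seed = 57)
    fit_dv_model(sim$main, sim$fu)$coefficients[["dv"]]
  }, numeric(1))
  expect_gt(slopes[1], 0)
  expect_gt(slopes[2], slopes[1])
})

test_that("per-session averaging matches the per-session fits", {
  sim <- sim_with_followup(n_sessions = 2, seed = 58)
  m <- fit_lagged_model(sim$main, "choice")
  expect_equal(m$n_sessions, 2)
  manual <- rowMeans(sapply(m$fits, `[[`, "coefficients"))
  expect_equal(m$coefficients, manual)
})
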