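test_that("optimality classification applies the baseline rule and tie convention", {
  fu <- make_followup(c(0.55, 0.70, 0.80, 0.95))
  tr <- make_trials(3, coherence = c(0.12, 0.25, 0.06),
                    p_external = c(0.9, 0.5, 0.7))
  lab <- classify_optimality(tr, fu)
  expect_equal(lab$internal_optimal, c(FALSE, TRUE, TRUE)) # tie -> internal
  lab2 <- classify_optimality(tr, fu, tie = "external")
  expect_equal(lab2$internal_optimal, c(FALSE, TRUE, FALSE))

  # only the four intermediate coherences are classified
  tr$coherence <- c(0, 0.5, 0.12)
  expect_equal(nrow(classify_optimality(tr, fu)), 1)
  expect_error(classify_optimality(make_trials(2, coherence = 0.06),
                                   make_followup(0.8, coherence = 0.12)),
               "no follow-up entry")
})

test_that("ROC area matches the brute-force trapezoid oracle on random point sets", {
  set.seed(101)
  for (i in 1:300) {
    k <- sample(1:6, 1)
    fa <- runif(k); hit <- runif(k)
    expect_equal(roc_area(fa, hit), oracle_roc_area(fa, hit), tolerance = 1e-12)
    expect_equal(roc_area(fa, hit, anchors = FALSE),
                 oracle_roc_area(fa, hit, anchors = FALSE), tolerance = 1e-12)
  }
  # frozen hand-checked case (anchors added)
  expect_equal(roc_area(c(0.1, 0.3, 0.6, 0.9), c(0.6, 0.8, 0.9, 1.0)), 0.81,
               tolerance = 1e-12)
})

test_that("degenerate selection policies give the expected type II areas", {
  fu <- make_followup(c(0.55, 0.70, 0.80, 0.95))
  offers <- expand.grid(coherence = c(0.03, 0.06, 0.12, 0.25),
                        p_external = task_config()$external_probabilities)
  n <- nrow(offers)
  always <- make_trials(n, coherence = offers$coherence,
                        p_external = offers$p_external, chose_internal = TRUE)
  expect_equal(type_two_aroc(always, fu)$area, 0.5)

  perfect <- always
  perfect$chose_internal <- classify_optimality(perfect, fu)$internal_optimal
  expect_equal(type_two_aroc(perfect, fu)$area, 1.0)

  one_class <- make_trials(4, coherence = 0.25, p_external = 0.1)
  expect_error(type_two_aroc(one_class, fu), "one\\s+optimality class|one optimality class")
})

test_that("type I area follows the Gaussian identity on constructed rates", {
  # hit = 18/20 left correct, fa = 2/20 right answered left
  tr <- make_trials(40,
                    true_direction = rep(c("left", "right"), each = 20),
                    response_direction = c(rep("left", 18), rep("right", 2),
                                           rep("left", 2), rep("right", 18)))
  tr$perceptual_correct <- tr$true_direction == tr$response_direction
  tr$rewarded <- tr$perceptual_correct
  r <- type_one_aroc(tr, correct_edges = FALSE)
  expect_equal(r$hit_rate, 0.9)
  expect_equal(r$fa_rate, 0.1)
  expect_equal(r$area, 0.96501, tolerance = 1e-4)

  # hit = fa -> chance
  tr2 <- make_trials(40, true_direction = rep(c("left", "right"), each = 20),
                     response_direction = rep(c("left", "right"), 20))
  tr2$perceptual_correct <- tr2$true_direction == tr2$response_direction
  tr2$rewarded <- tr2$perceptual_correct
  expect_equal(type_one_aroc(tr2, correct_edges = FALSE)$area, 0.5)

  # perfect observer stays interior after edge correction
  tr3 <- make_trials(40, true_direction = rep(c("left", "right"), each = 20))
  tr3$response_direction <- tr3$true_direction
  r3 <- type_one_aroc(tr3)
  expect_lt(r3$area, 1)
  expect_gt(r3$area, 0.95)

  tr4 <- make_trials(5, true_direction = "left")
  expect_error(type_one_aroc(tr4), "both motion directions")
})

test_that("coherence-0 trials are excluded from type I scoring by default", {
  tr <- make_trials(20, coherence = rep(c(0, 0.12), each = 10),
                    true_direction = rep(c("left", "right"), 10))
  tr$response_direction <- ifelse(tr$coherence == 0,
                                  "left", tr$true_direction)
  tr$perceptual_correct <- tr$true_direction == tr$response_direction
  tr$rewarded <- tr$perceptual_correct
  r <- type_one_aroc(tr)
  expect_equal(r$n_left + r$n_right, 10)
})

test_that("M-ratio identities hold", {
  for (a in c(0.55, 0.72, 0.9, 0.99))
    expect_equal(m_ratio(a, a)$m_ratio, 1.0)
  expect_equal(m_ratio(0.5, 0.84)$m_ratio, 0.0)
  # cohort-level means reported for the task: A_II = 0.72, A_I = 0.84
  expect_equal(m_ratio(0.72, 0.84)$m_ratio, 0.58609, tolerance = 1e-4)
  expect_equal(m_ratio(0.72, 0.84)$d_prime, sqrt(2) * qnorm(0.84))
  expect_error(m_ratio(0.7, 0.5), "chance")
})

test_that("edge correction maps extreme rates into the open interval", {
  expect_equal(edge_corrected_rate(0, 20), 0.5 / 21)
  expect_equal(edge_corrected_rate(20, 20), 20.5 / 21)
  expect_true(all(edge_corrected_rate(0:10, 10) > 0 &
                    edge_corrected_rate(0:10, 10) < 1))
})
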