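make_events <- function(n = 24, seed = 1) {
  set.seed(seed)
  simulate_roi_events(n)
}

test_that("event tables enforce onset uniqueness and regressor exclusivity", {
  expect_error(roi_events(c(1, 1), c(0.5, NA), c(NA, 0.5)), "identical onsets")
  expect_error(roi_events(c(1, 2), c(0.5, 0.4), c(NA, 0.5)), "mutually exclusive")
  ev <- make_events()
  expect_true(all(xor(is.na(ev$chosen_internal_prob),
                      is.na(ev$unchosen_internal_prob))))
})

test_that("the synthetic signal is linear in the regressors and flat at zero", {
  ev <- make_events()
  zero <- ev
  zero$chosen_internal_prob <- ifelse(is.na(zero$chosen_internal_prob), NA, 0)
  zero$unchosen_internal_prob <- ifelse(is.na(zero$unchosen_internal_prob), NA, 0)
  set.seed(5)
  tc0 <- simulate_roi_timecourse(zero, noise_sd = 0)
  expect_true(all(tc0$signal == 0))

  set.seed(5); tc1 <- simulate_roi_timecourse(ev, noise_sd = 0)
  dbl <- ev
  dbl$chosen_internal_prob <- 2 * dbl$chosen_internal_prob
  dbl$unchosen_internal_prob <- 2 * dbl$unchosen_internal_prob
  set.seed(5); tc2 <- simulate_roi_timecourse(dbl, noise_sd = 0)
  expect_equal(tc2$signal, 2 * tc1$signal, tolerance = 1e-12)
})

test_that("per-timepoint regression recovers constant and null couplings", {
  set.seed(7)
  ev <- simulate_roi_events(40)
  # signal equal to the defined regressor value, held constant over each epoch
  dt <- 1
  time <- seq(0, max(ev$onset_s) + 15, by = dt)
  vals <- ifelse(is.na(ev$chosen_internal_prob),
                 ev$unchosen_internal_prob, ev$chosen_internal_prob)
  signal <- numeric(length(time))
  for (i in seq_len(nrow(ev)))
    signal[time >= ev$onset_s[i] & time < ev$onset_s[i] + 12] <- vals[i]
  tc <- structure(list(time = time, signal = signal, dt = dt, events = ev,
                       oversample = 4L), class = "roi_timecourse")
  bt <- beta_timecourse(tc)
  # identity regression up to the global normalization of the signal
  expect_lt(diff(range(bt$beta_chosen)), 0.1)
  expect_gt(mean(bt$beta_chosen), 0.5)

  # uncorrelated noise signal -> betas near zero
  tc$signal <- rnorm(length(time))
  bt0 <- beta_timecourse(tc)
  expect_lt(max(abs(bt0$beta_chosen)), 0.8)
  expect_lt(abs(mean(bt0$beta_chosen)), 0.25)
})

test_that("beta timecourses are invariant to adding a constant to the signal", {
  set.seed(8)
  ev <- simulate_roi_events(30)
  tc <- simulate_roi_timecourse(ev, noise_sd = 0.3)
  bt1 <- beta_timecourse(tc)
  tc$signal <- tc$signal + 42
  bt2 <- beta_timecourse(tc)
  expect_equal(bt1$beta_chosen, bt2$beta_chosen, tolerance = 1e-10)
})

test_that("regression preconditions are enforced", {
  set.seed(9)
  ev <- simulate_roi_events(12)
  tc <- simulate_roi_timecourse(ev)
  expect_error(beta_timecourse(tc, min_events = 10), "usable events")
  ev2 <- simulate_roi_events(40, prob_levels = 0.7)
  tc2 <- simulate_roi_timecourse(ev2)
  expect_error(beta_timecourse(tc2), "constant")
})

test_that("slope statistic matches analytic cases and the exhaustive oracle", {
  tt <- seq(0, 11, by = 0.1)
  lin <- slope_stat(tt, tt)
  expect_equal(lin$slope, 1.0)
  expect_equal(lin$t_min, 0.1)
  expect_equal(lin$t_max, 10.9)

  const <- slope_stat(tt, rep(2, length(tt)))
  expect_equal(const$slope, 0)
  expect_equal(const$magnitude, 0)

  set.seed(10)
  for (i in 1:300) {
    beta <- cumsum(rnorm(length(tt)))
    expect_equal(slope_stat(tt, beta), oracle_slope(tt, beta),
                 tolerance = 1e-12)
  }
  # window constraints hold by construction
  r <- slope_stat(tt, -tt) # decreasing curve
  expect_gt(r$t_min, 0); expect_lt(r$t_min, 4)
  expect_gt(r$t_max, r$t_min); expect_lt(r$t_max, 11)
  expect_equal(sign(r$slope), sign(r$magnitude))
})

test_that("a faster-ramping chosen response yields a slope but not a peak contrast", {
  set.seed(11)
  bts <- lapply(1:6, function(i) {
    ev <- simulate_roi_events(150)
    tc <- simulate_roi_timecourse(ev)
    beta_timecourse(tc)
  })
  r <- chosen_unchosen_slope_contrast(bts)
  expect_gt(r$slope_contrast, 0)
  expect_lt(abs(r$peak_contrast), 0.25 * mean(c(r$per_session$peak_chosen,
                                                r$per_session$peak_unchosen)))

  # swapped condition labels negate both contrasts exactly
  swapped <- lapply(bts, function(bt) {
    s <- bt
    s$beta_chosen <- bt$beta_unchosen
    s$beta_unchosen <- bt$beta_chosen
    s
  })
  r2 <- chosen_unchosen_slope_contrast(swapped)
  expect_equal(r2$slope_contrast, -r$slope_contrast)
  expect_equal(r2$peak_contrast, -r$peak_contrast)

  # matched generators -> both contrasts near zero
  set.seed(12)
  bts_eq <- lapply(1:6, function(i) {
    ev <- simulate_roi_events(150)
    tc <- simulate_roi_timecourse(ev, time_to_peak_chosen = 5.5,
                                  time_to_peak_unchosen = 5.5)
    beta_timecourse(tc)
  })
  r3 <- chosen_unchosen_slope_contrast(bts_eq)
  expect_lt(abs(r3$slope_contrast), 0.6 * abs(r$slope_contrast))
})

test_that("ROI files round-trip through TSV", {
  set.seed(13)
  ev <- simulate_roi_events(25)
  tc <- simulate_roi_timecourse(ev)
  sp <- withr::local_tempfile(fileext = ".tsv")
  ep <- withr::local_tempfile(fileext = ".tsv")
  write_roi_timecourse(tc, sp, ep)
  back <- read_roi_timecourse(sp, ep)
  expect_equal(back$signal, tc$signal, tolerance = 1e-12)
  expect_equal(back$events$chosen_internal_prob, ev$chosen_internal_prob)
  expect_equal(back$dt, tc$dt, tolerance = 1e-9)
})
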