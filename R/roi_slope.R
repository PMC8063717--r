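#' Event table for an ROI timecourse
#'
#' One row per trial: the onset (seconds) of the phase the analysis is
#' time-locked to, and the two parametric regressors. The chosen- and
#' unchosen-internal-probability regressors are mutually exclusive: on a
#' trial where the internal option was chosen only `chosen_internal_prob` is
#' defined, on a trial where it was rejected only `unchosen_internal_prob`;
#' the other is `NA`.
#'
#' @param onset_s Event onsets in seconds, strictly increasing.
#' @param chosen_internal_prob,unchosen_internal_prob Per-trial regressor
#'   values (probabilities), `NA` where undefined.
#' @return `data.frame` of class `roi_events`.
#' @export
roi_events <- function(onset_s, chosen_internal_prob, unchosen_internal_prob) {
  stopifnot(length(onset_s) == length(chosen_internal_prob),
            length(onset_s) == length(unchosen_internal_prob))
  if (any(duplicated(onset_s)))
    stop("overlapping identical onsets in event table")
  if (any(!is.na(chosen_internal_prob) & !is.na(unchosen_internal_prob)))
    stop("chosen and unchosen regressors are mutually exclusive per trial")
  out <- data.frame(onset_s = onset_s,
                    chosen_internal_prob = chosen_internal_prob,
                    unchosen_internal_prob = unchosen_internal_prob)
  out <- out[order(out$onset_s), ]
  rownames(out) <- NULL
  class(out) <- c("roi_events", "data.frame")
  out
}

# Gamma-variate impulse response, peak value 1 at t = time_to_peak.
gamma_response <- function(t, time_to_peak, shape = 3) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- (t[pos] / time_to_peak)^shape * exp(shape * (1 - t[pos] / time_to_peak))
  out
}

#' Simulate an event schedule for an ROI analysis
#'
#' Trial onsets are spaced by one nominal trial length plus a jittered
#' stimulus-onset asynchrony drawn from a Poisson distribution (mean 3 s)
#' clipped to 2.5-8.5 s. Regressor values are drawn from the task's
#' probability levels; each trial is randomly a chosen-internal or
#' unchosen-internal (i.e. external-chosen) trial.
#'
#' @param n_trials Number of events.
#' @param p_chosen Probability that a trial is a chosen-internal trial.
#' @param prob_levels Values the parametric regressors are drawn from.
#' @param trial_length_s Nominal trial duration before the jitter.
#' @return A [roi_events()] table.
#' @export
simulate_roi_events <- function(n_trials, p_chosen = 0.5,
                                prob_levels = seq(0.5, 1, by = 0.1),
                                trial_length_s = 11) {
  soa <- pmin(pmax(stats::rpois(n_trials, 3), 2.5), 8.5)
  onsets <- cumsum(trial_length_s + soa)
  chosen <- stats::runif(n_trials) < p_chosen
  vals <- sample(prob_levels, n_trials, replace = TRUE)
  roi_events(onsets,
             chosen_internal_prob = ifelse(chosen, vals, NA_real_),
             unchosen_internal_prob = ifelse(chosen, NA_real_, vals))
}

#' Simulate a synthetic ROI signal from an event table
#'
#' The signal is a sum over trials of a gamma-variate impulse response
#' scaled by the trial's regressor value, plus Gaussian noise. The response
#' for chosen- and unchosen-internal trials can ramp at different speeds
#' (`time_to_peak_chosen` vs `time_to_peak_unchosen`) while sharing the same
#' peak amplitude, which is the generative pattern the slope statistic is
#' designed to detect: different accumulation speed, matched peak signal.
#' This is a synthetic stand-in for a preprocessed BOLD timecourse; no
#' hemodynamic pipeline is modeled.
#'
#' @param events A [roi_events()] table.
#' @param time_to_peak_chosen,time_to_peak_unchosen Seconds to the response
#'   peak per condition (smaller = faster ramp).
#' @param amplitude Response scale per unit regressor value.
#' @param noise_sd Sd of the additive Gaussian noise.
#' @param dt Sampling interval in seconds (defaults to a 1.23 s repetition
#'   time).
#' @param padding_s Signal continues this long after the last onset.
#' @return Object of class `roi_timecourse`: `time`, `signal`, `dt`,
#'   `events`, `oversample` (recorded analysis factor, 20).
#' @export
simulate_roi_timecourse <- function(events,
                                    time_to_peak_chosen = 4,
                                    time_to_peak_unchosen = 7,
                                    amplitude = 1, noise_sd = 0.15,
                                    dt = 1.23, padding_s = 15) {
  stopifnot(inherits(events, "roi_events"))
  time <- seq(0, max(events$onset_s) + padding_s, by = dt)
  signal <- numeric(length(time))
  for (i in seq_len(nrow(events))) {
    chosen <- !is.na(events$chosen_internal_prob[i])
    val <- if (chosen) events$chosen_internal_prob[i] else events$unchosen_internal_prob[i]
    if (is.na(val)) next
    tp <- if (chosen) time_to_peak_chosen else time_to_peak_unchosen
    signal <- signal + amplitude * val * gamma_response(time - events$onset_s[i], tp)
  }
  signal <- signal + stats::rnorm(length(time), 0, noise_sd)
  structure(list(time = time, signal = signal, dt = dt, events = events,
                 oversample = 20L),
            class = "roi_timecourse")
}

#' Per-timepoint regression of an ROI signal on trial regressors
#'
#' The signal is normalized (mean 0, sd 1), oversampled by the recorded
#' factor (default 20) through linear interpolation, and epoched on a
#' 0-`window_s` second grid after each event onset. At every post-onset
#' time t, the epoched signal values across trials are regressed (ordinary
#' least squares with intercept) on the trial's regressor values, separately
#' for the chosen- and unchosen-internal-probability regressors over the
#' trials on which each is defined. Regressor values are normalized (mean 0,
#' sd 1) before the fit.
#'
#' @param tc A `roi_timecourse` (or a list with `time`, `signal`, `dt`,
#'   `events`, `oversample`).
#' @param window_s Post-onset epoch length in seconds (default 11).
#' @param min_events Minimum number of defined trials per regressor.
#' @return Object of class `beta_timecourse`: `time` (post-onset grid),
#'   `beta_chosen`, `beta_unchosen`, `n_chosen`, `n_unchosen`.
#' @export
beta_timecourse <- function(tc, window_s = 11, min_events = 10L) {
  signal <- (tc$signal - mean(tc$signal)) / stats::sd(tc$signal)
  step <- tc$dt / tc$oversample
  tau <- seq(0, window_s, by = step)
  betas <- lapply(c("chosen_internal_prob", "unchosen_internal_prob"), function(col) {
    keep <- !is.na(tc$events[[col]]) &
      (tc$events$onset_s + window_s) <= max(tc$time)
    n <- sum(keep)
    if (n < min_events)
      stop("beta_timecourse: only ", n, " usable events for ", col,
           " (need >= ", min_events, ")")
    x <- tc$events[[col]][keep]
    if (stats::sd(x) < 1e-12)
      stop("beta_timecourse: regressor ", col, " is constant (rank-deficient)")
    x <- (x - mean(x)) / stats::sd(x)
    onsets <- tc$events$onset_s[keep]
    # epoch matrix: trials x post-onset timepoints, linear interpolation
    vapply(tau, function(tt) {
      y <- stats::approx(tc$time, signal, xout = onsets + tt, rule = 2)$y
      # OLS with intercept on a z-scored regressor
      sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    }, numeric(1))
  })
  structure(list(time = tau, beta_chosen = betas[[1]], beta_unchosen = betas[[2]],
                 n_chosen = sum(!is.na(tc$events$chosen_internal_prob)),
                 n_unchosen = sum(!is.na(tc$events$unchosen_internal_prob))),
            class = "beta_timecourse")
}

#' Slope and magnitude of a beta timecourse
#'
#' Finds the minimum beta weight strictly inside the early window
#' (`0 < t < t_min_max`, default 4 s, within which the next trial phase
#' cannot yet have started) and the maximum strictly inside
#' (`t_min < t < t_max_max`, default 11 s), ties broken to the earliest
#' time, and returns
#' \deqn{slope = \frac{\beta_{max} - \beta_{min}}{t_{max} - t_{min}}, \qquad
#'       magnitude = \beta_{max} - \beta_{min}.}
#'
#' @param time Post-onset time grid (seconds).
#' @param beta Beta weights on that grid.
#' @param t_min_max Upper bound (exclusive) of the search window for the
#'   minimum.
#' @param t_max_max Upper bound (exclusive) of the search window for the
#'   maximum.
#' @return List with `t_min`, `beta_min`, `t_max`, `beta_max`, `slope`,
#'   `magnitude`.
#' @export
slope_stat <- function(time, beta, t_min_max = 4, t_max_max = 11) {
  stopifnot(length(time) == length(beta))
  win_min <- which(time > 0 & time < t_min_max)
  if (length(win_min) == 0) stop("slope_stat: empty search window for the minimum")
  i_min <- win_min[which.min(beta[win_min])]
  win_max <- which(time > time[i_min] & time < t_max_max)
  if (length(win_max) == 0) stop("slope_stat: empty search window for the maximum")
  i_max <- win_max[which.max(beta[win_max])]
  b_min <- beta[i_min]; b_max <- beta[i_max]
  list(t_min = time[i_min], beta_min = b_min,
       t_max = time[i_max], beta_max = b_max,
       slope = (b_max - b_min) / (time[i_max] - time[i_min]),
       magnitude = b_max - b_min)
}

#' Slope statistics for both regressors of a beta timecourse
#'
#' @param bt A [beta_timecourse()].
#' @param ... Passed to [slope_stat()].
#' @return List with `chosen` and `unchosen` slope results.
#' @export
slope_stats <- function(bt, ...) {
  list(chosen = slope_stat(bt$time, bt$beta_chosen, ...),
       unchosen = slope_stat(bt$time, bt$beta_unchosen, ...))
}

#' Chosen-versus-unchosen slope and peak contrast across sessions
#'
#' Per session, extracts the slope and peak (beta_max) of the chosen- and
#' unchosen-internal-probability beta timecourses; averages each within
#' condition across sessions (as session-level statistics are averaged
#' within a participant) and reports the contrasts.
#'
#' @param bts List of [beta_timecourse()] objects, one per session.
#' @param ... Passed to [slope_stat()].
#' @return List with per-session tables and `slope_contrast`
#'   (mean slope_chosen - mean slope_unchosen), `peak_contrast`
#'   (mean beta_max difference).
#' @export
chosen_unchosen_slope_contrast <- function(bts, ...) {
  if (inherits(bts, "beta_timecourse")) bts <- list(bts)
  if (length(bts) == 0) stop("no sessions supplied")
  per <- do.call(rbind, lapply(bts, function(bt) {
    s <- slope_stats(bt, ...)
    data.frame(slope_chosen = s$chosen$slope, slope_unchosen = s$unchosen$slope,
               peak_chosen = s$chosen$beta_max, peak_unchosen = s$unchosen$beta_max)
  }))
  list(per_session = per,
       slope_chosen = mean(per$slope_chosen),
       slope_unchosen = mean(per$slope_unchosen),
       slope_contrast = mean(per$slope_chosen) - mean(per$slope_unchosen),
       peak_contrast = mean(per$peak_chosen) - mean(per$peak_unchosen))
}

#' Write / read an ROI timecourse and its event table as TSV
#'
#' The timecourse file has columns `time_s`, `value`; the events file has
#' `onset_s`, `chosen_internal_prob`, `unchosen_internal_prob` with empty
#' cells where a regressor is undefined.
#'
#' @param tc A `roi_timecourse`.
#' @param signal_path,events_path Output paths.
#' @param dt,oversample Sampling interval and analysis oversampling factor
#'   (read side).
#' @return Paths (write) or a `roi_timecourse` (read).
#' @export
write_roi_timecourse <- function(tc, signal_path, events_path) {
  utils::write.table(data.frame(time_s = tc$time, value = tc$signal),
                     signal_path, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(tc$events, events_path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(c(signal_path, events_path))
}

#' @rdname write_roi_timecourse
#' @export
read_roi_timecourse <- function(signal_path, events_path, dt = NULL,
                                oversample = 20L) {
  sig <- utils::read.delim(signal_path)
  ev <- utils::read.delim(events_path)
  if (!all(c("time_s", "value") %in% names(sig)))
    stop("timecourse file must have columns time_s, value")
  if (!all(c("onset_s", "chosen_internal_prob", "unchosen_internal_prob") %in% names(ev)))
    stop("events file must have columns onset_s, chosen_internal_prob, unchosen_internal_prob")
  if (is.null(dt)) dt <- stats::median(diff(sig$time_s))
  structure(list(time = sig$time_s, signal = sig$value, dt = dt,
                 events = roi_events(ev$onset_s, ev$chosen_internal_prob,
                                     ev$unchosen_internal_prob),
                 oversample = as.integer(oversample)),
            class = "roi_timecourse")
}
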