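#' Parameters of the simulated observer
#'
#' The observer is a signed-evidence (cumulative-Gaussian) model of the
#' two-stage task. On each trial the internal option's stimulus gives rise to
#' a latent evidence sample
#' \deqn{z = (c/\alpha)^{s} + \epsilon_{share} + \epsilon_{resp},}
#' where \eqn{c} is coherence, \eqn{\alpha} the psychometric width (the
#' coherence at which accuracy reaches about 84%), \eqn{s} a slope exponent,
#' and the two noise terms are Gaussian. The shared term
#' \eqn{\epsilon_{share}} (sd `evidence_sd`, coherence units) is a property
#' of the particular stimulus instance and is therefore common to the
#' metacognitive judgment and the later perceptual decision on the same
#' trial; the response term \eqn{\epsilon_{resp}} is fresh at the perceptual
#' stage. The perceptual response is the sign of \eqn{z} (with lapse rate
#' `lapse`), so accuracy at coherence \eqn{c} is exactly
#' \eqn{\lambda/2 + (1-\lambda)\Phi((c/\alpha)^s)}: chance-anchored at
#' \eqn{c = 0} and saturating near 1 at high coherence.
#'
#' At the metacognitive stage the observer reads out the shared evidence with
#' additional noise `meta_noise` (coherence units), converts the readout to a
#' forecast probability correct through its own psychometric curve, distorts
#' both that forecast and the offered external probability through
#' prospect-theory weighting ([prospect_weight()]) with exponents
#' `gamma_internal` and `gamma_external`, and chooses the internal option
#' with probability `plogis(choice_beta * (w_int - w_ext))`. Because the
#' shared evidence survives into the perceptual stage, trials on which the
#' observer elects the internal option are trials on which it is genuinely
#' more likely to succeed: this single channel generates trial-level
#' metacognitive sensitivity and the challenge-trial benefit.
#'
#' When the external option is chosen, the perceptual decision is correct
#' with probability `external_accuracy` (the near-ceiling rate observed for
#' 100% coherent stimuli) and reward is then delivered with the offered
#' external probability.
#'
#' Defaults are calibrated so the simulated follow-up accuracy spans chance
#' to near-ceiling across the coherence grid with the moderate levels (0.06,
#' 0.12) landing midway between adjacent external-probability grid values,
#' and so reward rates for the two options are roughly matched in the
#' mid-seventies of percent, as in the cohort the task was designed for.
#'
#' @param alpha Psychometric width in coherence units (> `evidence_sd`).
#' @param slope Psychometric slope exponent (1 = linear evidence scaling).
#' @param lapse Lapse rate in \[0, 1\].
#' @param gamma_internal,gamma_external Probability-weighting exponents
#'   (> 0); 1 means no distortion, smaller values mean stronger inverse-S
#'   distortion.
#' @param choice_beta Inverse temperature (>= 0) of the metacognitive choice.
#' @param evidence_sd Sd of the shared trial evidence, coherence units.
#' @param meta_noise Sd of the extra noise on the metacognitive readout of
#'   the shared evidence, coherence units.
#' @param external_accuracy Probability of a correct perceptual decision on
#'   external-option trials.
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(alpha = 0.22, slope = 1.6, lapse = 0.02,
                         gamma_internal = 0.8, gamma_external = 0.8,
                         choice_beta = 8, evidence_sd = 0.176,
                         meta_noise = 0.12, external_accuracy = 0.979) {
  stopifnot(alpha > 0, slope > 0, lapse >= 0, lapse < 1,
            gamma_internal > 0, gamma_external > 0, choice_beta >= 0,
            evidence_sd >= 0, meta_noise >= 0,
            external_accuracy >= 0, external_accuracy <= 1)
  if (evidence_sd >= alpha)
    stop("evidence_sd must be smaller than alpha: the shared evidence is one ",
         "component of the total psychometric noise")
  structure(list(alpha = alpha, slope = slope, lapse = lapse,
                 gamma_internal = gamma_internal, gamma_external = gamma_external,
                 choice_beta = choice_beta, evidence_sd = evidence_sd,
                 meta_noise = meta_noise, external_accuracy = external_accuracy),
            class = "agent_params")
}

#' Psychometric accuracy curve of the simulated observer
#'
#' Marginal probability of a correct perceptual decision on an
#' internal-option trial at coherence `c`:
#' `lapse/2 + (1 - lapse) * pnorm((c / alpha)^slope)`.
#'
#' @param c Coherence(s) in \[0, 1\].
#' @param params An [agent_params()].
#' @return Probability correct, same length as `c`.
#' @export
perceptual_accuracy <- function(c, params = agent_params()) {
  if (any(c < 0 | c > 1)) stop("coherence must lie in [0, 1]")
  params$lapse / 2 + (1 - params$lapse) * stats::pnorm((c / params$alpha)^params$slope)
}

# Forecast probability correct from a (signed, standardized) evidence readout.
forecast_accuracy <- function(z, params) {
  params$lapse / 2 + (1 - params$lapse) * stats::pnorm(z)
}

#' Balanced offer schedule over the coherence x external-probability grid
#'
#' Builds `n_trials` offers: as many complete repetitions of the full grid as
#' fit, plus a random subset of grid cells for the remainder, all shuffled.
#' Sessions shorter than one full grid cannot cover the design and trigger a
#' warning.
#'
#' @param config A [task_config()].
#' @param n_trials Number of offers (defaults to the configured session
#'   length).
#' @return `data.frame` with columns `coherence`, `p_external`.
#' @export
offer_schedule <- function(config = task_config(),
                           n_trials = config$n_trials_per_session) {
  grid <- expand.grid(coherence = config$coherence_levels,
                      p_external = config$external_probabilities,
                      KEEP.OUT.ATTRS = FALSE)
  ncell <- nrow(grid)
  if (n_trials < ncell)
    warning("session of ", n_trials, " trials cannot cover the full ",
            ncell, "-cell offer grid")
  reps <- n_trials %/% ncell
  rem <- n_trials %% ncell
  idx <- c(rep(seq_len(ncell), reps),
           if (rem > 0) sample.int(ncell, rem))
  grid <- grid[idx[sample.int(length(idx))], , drop = FALSE]
  rownames(grid) <- NULL
  grid
}

# Vectorized trial engine. All random draws are made for every trial in a
# fixed order regardless of which option is chosen, so two conditions that
# differ only in a parameter multiplier consume the RNG stream identically.
simulate_trials_core <- function(offers, agent, session_id = "s1",
                                 meta_noise_mult = 1) {
  n <- nrow(offers)
  c_lev <- offers$coherence
  p_ext <- offers$p_external
  true_dir <- sample(c("left", "right"), n, replace = TRUE)
  eps_share <- stats::rnorm(n, 0, agent$evidence_sd / agent$alpha)
  eps_meta <- stats::rnorm(n, 0, 1) # scaled below; drawn unscaled for stream parity
  u_choice <- stats::runif(n)
  eps_resp <- stats::rnorm(n, 0, sqrt(pmax(1 - (agent$evidence_sd / agent$alpha)^2, 0)))
  u_lapse <- stats::runif(n)
  u_extcor <- stats::runif(n)
  u_reward <- stats::runif(n)

  drift <- (c_lev / agent$alpha)^agent$slope
  z_meta <- drift + eps_share +
    eps_meta * (agent$meta_noise * meta_noise_mult) / agent$alpha
  p_hat <- forecast_accuracy(z_meta, agent)
  w_int <- prospect_weight(p_hat, agent$gamma_internal)
  w_ext <- prospect_weight(p_ext, agent$gamma_external)
  p_choose_int <- stats::plogis(agent$choice_beta * (w_int - w_ext))
  chose_internal <- u_choice < p_choose_int

  # Internal perceptual outcome: sign of shared + fresh response evidence.
  z_perc <- drift + eps_share + eps_resp
  internal_correct <- ifelse(u_lapse < agent$lapse, u_extcor < 0.5, z_perc > 0)
  external_correct <- u_extcor < agent$external_accuracy

  perceptual_correct <- ifelse(chose_internal, internal_correct, external_correct)
  rewarded <- ifelse(chose_internal, perceptual_correct,
                     perceptual_correct & (u_reward < p_ext))
  response_direction <- ifelse(perceptual_correct, true_dir,
                               ifelse(true_dir == "left", "right", "left"))
  data.frame(session_id = session_id, trial_index = seq_len(n),
             coherence = c_lev, p_external = p_ext,
             chose_internal = chose_internal,
             true_direction = true_dir, response_direction = response_direction,
             perceptual_correct = perceptual_correct, rewarded = rewarded,
             stringsAsFactors = FALSE)
}

#' Simulate a single two-stage trial
#'
#' @param coherence,p_external The offered internal coherence and external
#'   reward probability (must come from the task grid for downstream
#'   analyses).
#' @param agent An [agent_params()].
#' @param session_id Session label.
#' @return A one-row trial `data.frame` in trial-log format.
#' @export
simulate_trial <- function(coherence, p_external, agent = agent_params(),
                           session_id = "s1") {
  simulate_trials_core(data.frame(coherence = coherence, p_external = p_external),
                       agent, session_id = session_id)
}

#' Specification of a simulated experiment
#'
#' @param task A [task_config()].
#' @param agent An [agent_params()].
#' @param n_sessions Number of main-task sessions.
#' @param include_followup Also simulate one follow-up session (internal-only
#'   perceptual trials, same coherence schedule length) per main session.
#' @param tms_condition `"none"`, `"alpfc"` (multiplies `meta_noise` by
#'   `tms_factor`, modeling disrupted metacognitive readout), or `"vertex"`
#'   (control site; identical to `"none"`, including the random stream).
#' @param tms_factor Multiplier on `meta_noise` under `"alpfc"`.
#' @param seed Integer seed; the whole experiment is reproducible from it.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(task = task_config(), agent = agent_params(),
                            n_sessions = 2L, include_followup = TRUE,
                            tms_condition = c("none", "alpfc", "vertex"),
                            tms_factor = 3, seed = 1L) {
  tms_condition <- match.arg(tms_condition)
  stopifnot(n_sessions >= 1, tms_factor > 0)
  structure(list(task = task, agent = agent, n_sessions = as.integer(n_sessions),
                 include_followup = isTRUE(include_followup),
                 tms_condition = tms_condition, tms_factor = tms_factor,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate one main-task session (and optionally its follow-up)
#'
#' The offer schedule covers the full coherence x probability grid in
#' balanced, shuffled repetitions. The follow-up session re-uses the same
#' coherence levels with the same trial count but has no choice stage: every
#' trial is an internal perceptual decision (recorded with
#' `chose_internal = TRUE` and `p_external = 1`, the internal option's own
#' reward probability).
#'
#' @param spec A [simulation_spec()].
#' @param session_id Session label.
#' @param seed Session seed (integer).
#' @return List with `main` (a [session_log()]) and `followup` (a
#'   [session_log()] or `NULL`).
#' @export
simulate_session <- function(spec = simulation_spec(), session_id = "s1",
                             seed = spec$seed) {
  set.seed(seed)
  mult <- if (spec$tms_condition == "alpfc") spec$tms_factor else 1
  offers <- offer_schedule(spec$task)
  trials <- simulate_trials_core(offers, spec$agent, session_id, mult)
  meta <- list(agent = unclass(spec$agent), seed = seed,
               tms_condition = spec$tms_condition)
  main <- session_log(trials, spec$task, metadata = meta)
  followup <- NULL
  if (spec$include_followup) {
    f_offers <- offer_schedule(spec$task)
    f <- simulate_trials_core(f_offers, spec$agent, paste0(session_id, "_followup"), mult)
    # no choice stage: internal option performed on every trial
    f$chose_internal <- TRUE
    f$p_external <- 1
    z <- (f$coherence / spec$agent$alpha)^spec$agent$slope
    # recompute outcome as internal for all trials (same draws as main engine)
    set.seed(seed + 1L)
    n <- nrow(f)
    eps_share <- stats::rnorm(n, 0, spec$agent$evidence_sd / spec$agent$alpha)
    eps_resp <- stats::rnorm(n, 0, sqrt(pmax(1 - (spec$agent$evidence_sd / spec$agent$alpha)^2, 0)))
    u_lapse <- stats::runif(n)
    u_guess <- stats::runif(n)
    correct <- ifelse(u_lapse < spec$agent$lapse, u_guess < 0.5,
                      z + eps_share + eps_resp > 0)
    f$perceptual_correct <- correct
    f$rewarded <- correct
    f$response_direction <- ifelse(correct, f$true_direction,
                                   ifelse(f$true_direction == "left", "right", "left"))
    followup <- session_log(f, spec$task, metadata = meta)
  }
  list(main = main, followup = followup)
}

#' Simulate a whole experiment
#'
#' Runs `n_sessions` main sessions (each with its follow-up if requested) and
#' concatenates them into one main-task [session_log()] and one follow-up
#' log. Per-session seeds are derived deterministically from the experiment
#' seed.
#'
#' @param spec A [simulation_spec()].
#' @return List with `main`, `followup` (session logs) and `session_seeds`.
#' @export
simulate_experiment <- function(spec = simulation_spec()) {
  set.seed(spec$seed)
  seeds <- sample.int(.Machine$integer.max - 2L, spec$n_sessions)
  out <- lapply(seq_len(spec$n_sessions), function(i)
    simulate_session(spec, session_id = paste0("s", i), seed = seeds[i]))
  main <- do.call(rbind, lapply(out, function(x) x$main$trials))
  res <- list(main = session_log(main, spec$task,
                                 metadata = list(seed = spec$seed,
                                                 tms_condition = spec$tms_condition)),
              followup = NULL, session_seeds = seeds)
  if (spec$include_followup) {
    fu <- do.call(rbind, lapply(out, function(x) x$followup$trials))
    res$followup <- session_log(fu, spec$task,
                                metadata = list(seed = spec$seed,
                                                tms_condition = spec$tms_condition))
  }
  res
}
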