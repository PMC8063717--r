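#' Classify trials as challenge or inevitable
#'
#' A trial is a *challenge* trial when the external option's reward
#' probability exceeds the reward expected from the internal option (the
#' participant's own follow-up accuracy at that coherence): taking the
#' internal option then means deliberately rejecting the on-average better
#' offer. It is *inevitable* when the external probability is lower, and
#' *excluded* on exact ties. The baseline is per participant, from their own
#' follow-up table, mirroring the optimality classification.
#'
#' @param trials Trial `data.frame` or [session_log()].
#' @param followup A [followup_table()] covering every coherence present.
#' @param moderate_coherences Levels flagged as "moderate" (where perceptual
#'   performance is off both floor and ceiling).
#' @return The trials with columns `expected_internal_reward`,
#'   `challenge_class` (factor: challenge/inevitable/excluded) and
#'   `moderate` (logical).
#' @export
classify_challenge <- function(trials, followup,
                               moderate_coherences = c(0.06, 0.12)) {
  if (inherits(trials, "session_log")) trials <- trials$trials
  p_int <- followup_p_correct(followup, trials$coherence) * 1.0
  cls <- ifelse(trials$p_external > p_int, "challenge",
                ifelse(trials$p_external < p_int, "inevitable", "excluded"))
  out <- trials
  out$expected_internal_reward <- p_int
  out$challenge_class <- factor(cls, levels = c("challenge", "inevitable", "excluded"))
  out$moderate <- near_in(out$coherence, moderate_coherences)
  out
}

#' Challenge versus inevitable perceptual performance
#'
#' Among trials on which the internal option was chosen at the given
#' coherence set, compares the perceptual accuracy of challenge trials
#' (internal chosen despite a better external offer) with inevitable trials.
#' Accuracies are computed per coherence level and the per-level differences
#' averaged with equal weight: the two classes have different coherence
#' compositions (challenge trials skew toward harder coherences), which
#' would confound a pooled difference. A positive difference is the
#' behavioral signature of trial-level prospective metacognition: the
#' observer takes on challenges selectively, on trials it senses it can win.
#'
#' @param trials Trial `data.frame` or [session_log()].
#' @param followup A [followup_table()].
#' @param coherence_set Coherences entering the contrast (default the
#'   moderate levels 0.06 and 0.12).
#' @return List with `per_coherence` (per-level class accuracies, counts and
#'   differences), `acc_challenge`, `acc_inevitable` (equal-weight means
#'   over levels with both classes), `difference`, `n_challenge`,
#'   `n_inevitable`.
#' @export
challenge_contrast <- function(trials, followup,
                               coherence_set = c(0.06, 0.12)) {
  lab <- classify_challenge(trials, followup, coherence_set)
  d <- lab[lab$chose_internal & near_in(lab$coherence, coherence_set), , drop = FALSE]
  per <- do.call(rbind, lapply(sort(coherence_set), function(cc) {
    x <- d[abs(d$coherence - cc) < 1e-9, , drop = FALSE]
    ch <- x$perceptual_correct[x$challenge_class == "challenge"]
    inev <- x$perceptual_correct[x$challenge_class == "inevitable"]
    data.frame(coherence = cc, n_challenge = length(ch), n_inevitable = length(inev),
               acc_challenge = if (length(ch)) mean(ch) else NA_real_,
               acc_inevitable = if (length(inev)) mean(inev) else NA_real_)
  }))
  per$difference <- per$acc_challenge - per$acc_inevitable
  usable <- stats::complete.cases(per[, c("acc_challenge", "acc_inevitable")])
  if (!any(usable))
    stop("challenge contrast undefined: no coherence level has chosen-internal ",
         "trials of both classes (", sum(per$n_challenge), " challenge, ",
         sum(per$n_inevitable), " inevitable in total)")
  list(per_coherence = per,
       acc_challenge = mean(per$acc_challenge[usable]),
       acc_inevitable = mean(per$acc_inevitable[usable]),
       difference = mean(per$difference[usable]),
       n_challenge = sum(per$n_challenge), n_inevitable = sum(per$n_inevitable))
}

#' Stimulation versus baseline contrast report
#'
#' Compares a stimulation condition against its baseline on the three
#' statistics the causal manipulation is expected to dissociate: the type II
#' ROC area (expected to drop when metacognitive readout is disrupted), the
#' type I ROC area (expected to be preserved), and the challenge-minus-
#' inevitable accuracy benefit (expected to shrink or reverse).
#'
#' @param log_tms,log_baseline [session_log()]s of the two conditions
#'   (matched task configurations).
#' @param followup_tms,followup_baseline Follow-up tables per condition
#'   (`followup_baseline` defaults to `followup_tms`'s value if omitted).
#' @param coherence_set Passed to [challenge_contrast()].
#' @return List with per-condition `sdt` and `challenge` summaries and the
#'   deltas `delta_type_two`, `delta_type_one`, `delta_challenge_benefit`
#'   (each TMS minus baseline).
#' @export
tms_contrast <- function(log_tms, log_baseline, followup_tms,
                         followup_baseline = followup_tms,
                         coherence_set = c(0.06, 0.12)) {
  cfg_a <- log_tms$config; cfg_b <- log_baseline$config
  if (!isTRUE(all.equal(cfg_a$coherence_levels, cfg_b$coherence_levels)) ||
      !isTRUE(all.equal(cfg_a$external_probabilities, cfg_b$external_probabilities)))
    stop("tms_contrast: task configurations of the two conditions differ")
  sdt_t <- sdt_summary(log_tms, followup_tms)
  sdt_b <- sdt_summary(log_baseline, followup_baseline)
  ch_t <- challenge_contrast(log_tms, followup_tms, coherence_set)
  ch_b <- challenge_contrast(log_baseline, followup_baseline, coherence_set)
  list(tms = list(sdt = sdt_t, challenge = ch_t),
       baseline = list(sdt = sdt_b, challenge = ch_b),
       delta_type_two = sdt_t$type_two$area - sdt_b$type_two$area,
       delta_type_one = sdt_t$type_one$area - sdt_b$type_one$area,
       delta_challenge_benefit = ch_t$difference - ch_b$difference)
}
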