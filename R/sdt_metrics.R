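#' Classify metacognitive trials as internal- or external-optimal
#'
#' A metacognitive judgment trial is internal-optimal when the reward
#' expected from attempting the internal option (the participant's own
#' follow-up accuracy at that coherence, times the internal option's certain
#' reward contingency) is at least the external option's reward probability;
#' otherwise it is external-optimal. Only trials at the four intermediate
#' coherences (by default 0.03, 0.06, 0.12, 0.25) are classified: at the
#' extremes the optimal action is unambiguous for every observer and the
#' trials carry no metacognitive signal.
#'
#' Ties (expected internal reward exactly equal to the external probability)
#' are labeled internal-optimal by default: the internal option's reward
#' contingency is certain, so tie trials carry no regret either way.
#'
#' @param trials Trial `data.frame` or [session_log()].
#' @param followup A [followup_table()] with entries for all eligible
#'   coherences present.
#' @param eligible_coherences Coherences entering the classification.
#' @param tie `"internal"` (default) or `"external"`: label assigned when the
#'   two expected reward probabilities are exactly equal.
#' @return `data.frame`: the classified trials plus columns
#'   `expected_internal_reward` and `internal_optimal`.
#' @export
classify_optimality <- function(trials, followup,
                                eligible_coherences = c(0.03, 0.06, 0.12, 0.25),
                                tie = c("internal", "external")) {
  tie <- match.arg(tie)
  if (inherits(trials, "session_log")) trials <- trials$trials
  keep <- near_in(trials$coherence, eligible_coherences)
  out <- trials[keep, , drop = FALSE]
  if (nrow(out) == 0) stop("no trials at the eligible coherences")
  p_int <- followup_p_correct(followup, out$coherence) * 1.0
  out$expected_internal_reward <- p_int
  out$internal_optimal <- if (tie == "internal") p_int >= out$p_external
                          else p_int > out$p_external
  rownames(out) <- NULL
  out
}

#' Area under an ROC curve by trapezoidal integration
#'
#' Connects the supplied (false-alarm rate, hit rate) points, optionally
#' augmented with the (0,0) and (1,1) anchors, after sorting by false-alarm
#' rate (hit rate breaking ties), and integrates by trapezoids.
#'
#' @param fa_rate,hit_rate Coordinates of the ROC points.
#' @param anchors Include the (0,0) and (1,1) corners (default `TRUE`).
#' @return Area in \[0, 1\].
#' @export
roc_area <- function(fa_rate, hit_rate, anchors = TRUE) {
  stopifnot(length(fa_rate) == length(hit_rate))
  if (anchors) {
    fa_rate <- c(0, fa_rate, 1)
    hit_rate <- c(0, hit_rate, 1)
  }
  o <- order(fa_rate, hit_rate)
  x <- fa_rate[o]; y <- hit_rate[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Type II ROC area: metacognitive sensitivity of option selection
#'
#' For each eligible coherence level, the hit rate is the proportion of
#' internal-optimal trials on which the internal option was chosen, and the
#' false-alarm rate is the proportion of external-optimal trials on which it
#' was chosen. The (FA, hit) point per coherence, the (0,0) and (1,1)
#' anchors, and trapezoidal integration give the type II area; 0.5 is
#' chance, 1 is perfect prospective selection.
#'
#' @param trials Trial `data.frame` or [session_log()].
#' @param followup A [followup_table()].
#' @param eligible_coherences,tie Passed to [classify_optimality()].
#' @param anchors Passed to [roc_area()].
#' @return List with `points` (per-coherence rates and opportunity counts)
#'   and `area`. Coherence levels without both opportunity types are dropped
#'   with a warning; if the whole set lacks one class the area is undefined
#'   and an error is raised.
#' @export
type_two_aroc <- function(trials, followup,
                          eligible_coherences = c(0.03, 0.06, 0.12, 0.25),
                          tie = "internal", anchors = TRUE) {
  lab <- classify_optimality(trials, followup, eligible_coherences, tie)
  if (all(lab$internal_optimal) || all(!lab$internal_optimal))
    stop("type II ROC area undefined: all classified trials fall in one ",
         "optimality class (", sum(lab$internal_optimal), " internal-optimal, ",
         sum(!lab$internal_optimal), " external-optimal)")
  pts <- do.call(rbind, lapply(sort(unique(lab$coherence)), function(cc) {
    d <- lab[abs(lab$coherence - cc) < 1e-9, ]
    n_hit_opp <- sum(d$internal_optimal)
    n_fa_opp <- sum(!d$internal_optimal)
    data.frame(coherence = cc,
               hit_rate = if (n_hit_opp > 0) mean(d$chose_internal[d$internal_optimal]) else NA_real_,
               fa_rate = if (n_fa_opp > 0) mean(d$chose_internal[!d$internal_optimal]) else NA_real_,
               n_hit_opportunities = n_hit_opp,
               n_fa_opportunities = n_fa_opp)
  }))
  usable <- stats::complete.cases(pts[, c("hit_rate", "fa_rate")])
  if (any(!usable))
    warning("dropping coherence level(s) without both opportunity types: ",
            paste(pts$coherence[!usable], collapse = ", "))
  area <- roc_area(pts$fa_rate[usable], pts$hit_rate[usable], anchors = anchors)
  list(points = pts, area = area)
}

#' Edge-corrected proportion
#'
#' Log-linear style correction applied before probit transformation so that
#' observed rates of exactly 0 or 1 map to finite z-scores:
#' `(k + 0.5) / (n + 1)`.
#'
#' @param k Number of successes.
#' @param n Number of opportunities.
#' @return Corrected rate strictly inside (0, 1).
#' @export
edge_corrected_rate <- function(k, n) (k + 0.5) / (n + 1)

#' Type I ROC area: perceptual sensitivity on internal-option trials
#'
#' Hit rate is the proportion of leftward-motion trials answered "left";
#' false-alarm rate is the proportion of rightward-motion trials answered
#' "left". Rates are edge-corrected ([edge_corrected_rate()]) and
#' \deqn{A = \Phi\left(\frac{z(hit) - z(FA)}{\sqrt 2}\right), \qquad
#'       d' = z(hit) - z(FA).}
#' Coherence-0 trials are excluded by default: with no coherent motion the
#' "correct" direction is objectively ambiguous.
#'
#' @param trials Trial `data.frame` or [session_log()]; only chosen-internal
#'   trials are scored.
#' @param exclude_zero_coherence Drop coherence-0 trials (default `TRUE`).
#' @param correct_edges Apply the edge correction to all rates (default
#'   `TRUE`).
#' @return List with `hit_rate`, `fa_rate` (corrected), `n_left`, `n_right`,
#'   `d_prime`, and `area`.
#' @export
type_one_aroc <- function(trials, exclude_zero_coherence = TRUE,
                          correct_edges = TRUE) {
  if (inherits(trials, "session_log")) trials <- trials$trials
  d <- trials[trials$chose_internal, , drop = FALSE]
  if (exclude_zero_coherence) d <- d[d$coherence > 1e-9, , drop = FALSE]
  n_left <- sum(d$true_direction == "left")
  n_right <- sum(d$true_direction == "right")
  if (n_left == 0 || n_right == 0)
    stop("type I ROC area undefined: need trials of both motion directions (",
         n_left, " left, ", n_right, " right)")
  k_hit <- sum(d$response_direction == "left" & d$true_direction == "left")
  k_fa <- sum(d$response_direction == "left" & d$true_direction == "right")
  if (correct_edges) {
    hit <- edge_corrected_rate(k_hit, n_left)
    fa <- edge_corrected_rate(k_fa, n_right)
  } else {
    hit <- k_hit / n_left
    fa <- k_fa / n_right
  }
  d_prime <- stats::qnorm(hit) - stats::qnorm(fa)
  list(hit_rate = hit, fa_rate = fa, n_left = n_left, n_right = n_right,
       d_prime = d_prime, area = stats::pnorm(d_prime / sqrt(2)))
}

#' Metacognitive efficiency: M-ratio from the two ROC areas
#'
#' Converts each area to a sensitivity through the Gaussian equal-variance
#' identity \eqn{d' = \sqrt 2\, z(A)}: `meta_d_prime = sqrt(2) * qnorm(a_roc2)`
#' for the type II area and `d_prime = sqrt(2) * qnorm(a_roc1)` for the type
#' I area. Their ratio, meta-d'/d' = z(A_II)/z(A_I), is 1 when option
#' selection is exactly as sensitive as the perceptual decisions themselves.
#'
#' @param a_roc2 Type II ROC area in (0, 1).
#' @param a_roc1 Type I ROC area in (0, 1), not equal to 0.5.
#' @return List with `meta_d_prime`, `d_prime`, `m_ratio`.
#' @export
m_ratio <- function(a_roc2, a_roc1) {
  stopifnot(a_roc2 > 0, a_roc2 < 1, a_roc1 > 0, a_roc1 < 1)
  if (abs(a_roc1 - 0.5) < 1e-12)
    stop("M-ratio undefined: type I ROC area equals chance (d' = 0)")
  meta_d <- sqrt(2) * stats::qnorm(a_roc2)
  d <- sqrt(2) * stats::qnorm(a_roc1)
  list(meta_d_prime = meta_d, d_prime = d, m_ratio = meta_d / d)
}

#' Full signal-detection summary of one participant's data
#'
#' Convenience wrapper computing the type II ROC points and area, the type I
#' rates and area, and the M-ratio in one pass.
#'
#' @param trials Trial `data.frame` or [session_log()] of main-task trials.
#' @param followup A [followup_table()].
#' @param ... Passed to [type_two_aroc()].
#' @return List with components `type_two`, `type_one`, `m_ratio`,
#'   `d_prime`, `meta_d_prime`.
#' @export
sdt_summary <- function(trials, followup, ...) {
  t2 <- type_two_aroc(trials, followup, ...)
  t1 <- type_one_aroc(trials)
  mr <- m_ratio(t2$area, t1$area)
  list(type_two = t2, type_one = t1, m_ratio = mr$m_ratio,
       d_prime = mr$d_prime, meta_d_prime = mr$meta_d_prime)
}
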