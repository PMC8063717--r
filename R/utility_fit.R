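#' Prospect-theory probability weighting function
#'
#' One-parameter inverse-S distortion of probability:
#' \deqn{w(p) = \frac{p^\gamma}{\left(p^\gamma + (1-p)^\gamma\right)^{1/\gamma}}.}
#' `gamma = 1` gives the identity; smaller `gamma` gives stronger distortion
#' (overweighting of small probabilities, underweighting of large ones).
#' Endpoints are exact: `w(0) = 0`, `w(1) = 1`.
#'
#' @param p Probability (vectorized), in \[0, 1\].
#' @param gamma Distortion exponent, > 0.
#' @return Weighted probabilities in \[0, 1\].
#' @export
prospect_weight <- function(p, gamma) {
  if (gamma <= 0) stop("gamma must be > 0")
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  w <- p^gamma / (p^gamma + (1 - p)^gamma)^(1 / gamma)
  # exact endpoints guard against 0^gamma round-off for extreme gamma
  w[p == 0] <- 0
  w[p == 1] <- 1
  w
}

#' Empirical choice curve: observed versus optimal choice proportions
#'
#' For each level of one option (each coherence for the internal side, each
#' reward probability for the external side) the curve pairs the objective
#' probability `p` that the option should have been chosen by an optimal
#' observer (per-participant follow-up baseline, tie to internal) with the
#' subjective probability `w` that it actually was chosen. An undistorted,
#' noise-free chooser lies on the identity; inverse-S departures are
#' summarized by [fit_gamma()].
#'
#' @param trials Trial `data.frame` or [session_log()].
#' @param followup A [followup_table()].
#' @param side `"internal"` or `"external"`.
#' @return `data.frame` with `level`, `n`, `p` (optimal proportion), `w`
#'   (observed proportion). Levels with no trials are absent; a message
#'   reports them.
#' @export
empirical_choice_curve <- function(trials, followup,
                                   side = c("internal", "external")) {
  side <- match.arg(side)
  if (inherits(trials, "session_log")) trials <- trials$trials
  if (nrow(trials) == 0) stop("no trials")
  p_int <- followup_p_correct(followup, trials$coherence)
  internal_optimal <- p_int >= trials$p_external
  level <- if (side == "internal") trials$coherence else trials$p_external
  optimal <- if (side == "internal") internal_optimal else !internal_optimal
  chosen <- if (side == "internal") trials$chose_internal else !trials$chose_internal
  levs <- sort(unique(level))
  out <- do.call(rbind, lapply(levs, function(l) {
    i <- abs(level - l) < 1e-9
    data.frame(level = l, n = sum(i), p = mean(optimal[i]), w = mean(chosen[i]))
  }))
  rownames(out) <- NULL
  out
}

#' Fit the probability-weighting exponent
#'
#' Least-squares fit of [prospect_weight()] to (p, w) pairs: minimizes
#' `sum(weights * (w - w(p; gamma))^2)` over `gamma` in \[0.05, 20\] by
#' bounded golden-section search (tolerance 1e-6).
#'
#' @param pairs `data.frame` with columns `p` and `w` (e.g. from
#'   [empirical_choice_curve()]).
#' @param weights Optional per-pair weights (e.g. bin counts); default
#'   unweighted.
#' @param lower,upper Search bounds for `gamma`.
#' @return List of class `utility_fit` with `gamma`, `log_gamma`, `sse`, and
#'   the input `pairs`.
#' @export
fit_gamma <- function(pairs, weights = NULL, lower = 0.05, upper = 20) {
  stopifnot(is.data.frame(pairs), all(c("p", "w") %in% names(pairs)))
  if (length(unique(round(pairs$p, 12))) < 3)
    stop("gamma is not identifiable: need at least 3 pairs with distinct p")
  if (is.null(weights)) weights <- rep(1, nrow(pairs))
  sse <- function(g) sum(weights * (pairs$w - prospect_weight(pairs$p, g))^2)
  # the SSE profile in gamma need not be unimodal; bracket the global
  # minimum on a log-spaced grid before the local golden-section refinement
  grid <- exp(seq(log(lower), log(upper), length.out = 80))
  vals <- vapply(grid, sse, numeric(1))
  i <- which.min(vals)
  opt <- stats::optimize(sse, lower = grid[max(i - 1, 1)],
                         upper = grid[min(i + 1, length(grid))], tol = 1e-6)
  structure(list(gamma = opt$minimum, log_gamma = log(opt$minimum),
                 sse = opt$objective, pairs = pairs),
            class = "utility_fit")
}

#' @export
print.utility_fit <- function(x, ...) {
  cat(sprintf("prospect-theory weighting fit: gamma = %.4f (log gamma = %.4f), SSE = %.4g over %d pairs\n",
              x$gamma, x$log_gamma, x$sse, nrow(x$pairs)))
  invisible(x)
}

#' Reward rate and outcome variance per option
#'
#' Reward outcomes are Bernoulli, so the per-option risk profile is the mean
#' reward rate and the implied Bernoulli outcome variance `r * (1 - r)`.
#'
#' @param trials Trial `data.frame` or [session_log()].
#' @param side `"internal"` or `"external"`: which chosen option to score.
#' @return List with `reward_rate`, `outcome_variance`, `n`.
#' @export
risk_metrics <- function(trials, side = c("internal", "external")) {
  side <- match.arg(side)
  if (inherits(trials, "session_log")) trials <- trials$trials
  d <- trials[trials$chose_internal == (side == "internal"), , drop = FALSE]
  if (nrow(d) == 0) stop("no trials with the ", side, " option chosen")
  r <- mean(d$rewarded)
  list(reward_rate = r, outcome_variance = r * (1 - r), n = nrow(d))
}
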