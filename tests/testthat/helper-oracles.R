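# Independent brute-force oracles and fixture builders shared across tests.

# Trapezoid ROC area, written independently of roc_area(): explicit
# insertion sort over (fa, hit) pairs and running trapezoid sum.
oracle_roc_area <- function(fa, hit, anchors = TRUE) {
  if (anchors) { fa <- c(fa, 0, 1); hit <- c(hit, 0, 1) }
  pts <- cbind(fa, hit)
  n <- nrow(pts)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (pts[j, 1] < pts[i, 1] ||
        (pts[j, 1] == pts[i, 1] && pts[j, 2] < pts[i, 2])) {
      tmp <- pts[i, ]; pts[i, ] <- pts[j, ]; pts[j, ] <- tmp
    }
  }
  area <- 0
  for (i in seq_len(n - 1))
    area <- area + (pts[i + 1, 1] - pts[i, 1]) * (pts[i, 2] + pts[i + 1, 2]) / 2
  unname(area)
}

# Exhaustive min/max search for the beta-slope statistic: scan every grid
# point with explicit loops and strict window bounds, earliest-tie rule.
oracle_slope <- function(time, beta, t_min_max = 4, t_max_max = 11) {
  i_min <- NA
  for (i in seq_along(time)) {
    if (time[i] > 0 && time[i] < t_min_max &&
        (is.na(i_min) || beta[i] < beta[i_min])) i_min <- i
  }
  j_max <- NA
  for (j in seq_along(time)) {
    if (time[j] > time[i_min] && time[j] < t_max_max &&
        (is.na(j_max) || beta[j] > beta[j_max])) j_max <- j
  }
  list(t_min = time[i_min], beta_min = beta[i_min],
       t_max = time[j_max], beta_max = beta[j_max],
       slope = (beta[j_max] - beta[i_min]) / (time[j_max] - time[i_min]),
       magnitude = beta[j_max] - beta[i_min])
}

# Minimal trial-log builder with sensible defaults.
make_trials <- function(n = 4, coherence = 0.12, p_external = 0.5,
                        chose_internal = TRUE, true_direction = "left",
                        response_direction = true_direction,
                        perceptual_correct = TRUE,
                        rewarded = perceptual_correct,
                        session_id = "s1") {
  data.frame(session_id = rep_len(session_id, n), trial_index = seq_len(n),
             coherence = rep_len(coherence, n),
             p_external = rep_len(p_external, n),
             chose_internal = rep_len(chose_internal, n),
             true_direction = rep_len(true_direction, n),
             response_direction = rep_len(response_direction, n),
             perceptual_correct = rep_len(perceptual_correct, n),
             rewarded = rep_len(rewarded, n),
             stringsAsFactors = FALSE)
}

# Follow-up table with stated accuracies (counts out of n each).
make_followup <- function(p_correct,
                          coherence = c(0.03, 0.06, 0.12, 0.25),
                          n = 100) {
  out <- data.frame(coherence = coherence, n_trials = n,
                    n_correct = round(p_correct * n),
                    p_correct = round(p_correct * n) / n)
  class(out) <- c("followup_table", "data.frame")
  out
}

sim_with_followup <- function(..., n_sessions = 2, seed = 1,
                              agent = agent_params()) {
  sim <- simulate_experiment(simulation_spec(agent = agent,
                                             n_sessions = n_sessions,
                                             seed = seed, ...))
  sim$fu <- suppressWarnings(followup_table(sim$followup))
  sim
}
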