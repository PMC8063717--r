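#' Task configuration for the two-stage probability-matching task
#'
#' Describes the stimulus grids and session structure of the task: on every
#' trial an "internal" option (full dot field, motion coherence drawn from
#' `coherence_levels`, reward certain given a correct perceptual decision) is
#' offered against an "external" option (100% coherent motion, reward
#' delivered with one of `external_probabilities` given a correct decision).
#' The default grids are the 8 x 8 design of the task: every combination of
#' the eight coherences and eight external probabilities appears in a session.
#'
#' @param coherence_levels Ordered vector of motion coherences (proportions).
#' @param external_probabilities Ordered vector of reward probabilities for
#'   the external option.
#' @param n_trials_per_session Number of main-task trials in one session.
#' @param internal_dot_count Dot count of the internal option (always the
#'   maximum; the internal option's own external reward probability is 1).
#' @param dots_per_probability Named map from external probability to the dot
#'   count that cues it. Defaults to `100 * p`.
#' @return An object of class `task_config`.
#' @export
task_config <- function(coherence_levels = c(0, 0.03, 0.06, 0.12, 0.25, 0.37, 0.50, 0.75),
                        external_probabilities = c(0.1, 0.3, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0),
                        n_trials_per_session = 195L,
                        internal_dot_count = 100L,
                        dots_per_probability = NULL) {
  stopifnot(is.numeric(coherence_levels), all(coherence_levels >= 0 & coherence_levels <= 1),
            !anyDuplicated(coherence_levels),
            is.numeric(external_probabilities),
            all(external_probabilities >= 0 & external_probabilities <= 1),
            !anyDuplicated(external_probabilities),
            length(n_trials_per_session) == 1L, n_trials_per_session >= 1)
  if (is.null(dots_per_probability)) {
    dots_per_probability <- stats::setNames(round(100 * external_probabilities),
                                            format_prob(external_probabilities))
  }
  structure(
    list(coherence_levels = sort(coherence_levels),
         external_probabilities = sort(external_probabilities),
         n_trials_per_session = as.integer(n_trials_per_session),
         internal_dot_count = as.integer(internal_dot_count),
         internal_external_prob = 1.0,
         dots_per_probability = dots_per_probability),
    class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat("Two-stage task configuration\n")
  cat("  coherence levels:      ", paste(x$coherence_levels, collapse = ", "), "\n")
  cat("  external probabilities:", paste(x$external_probabilities, collapse = ", "), "\n")
  cat("  trials per session:    ", x$n_trials_per_session, "\n")
  invisible(x)
}

# Canonical trial-log column order; booleans are stored as 0/1 on disk.
TRIAL_LOG_COLUMNS <- c("session_id", "trial_index", "coherence", "p_external",
                       "chose_internal", "true_direction", "response_direction",
                       "perceptual_correct", "rewarded")

format_prob <- function(p) formatC(p, format = "g", digits = 6)

#' Construct a session log
#'
#' A session log bundles the trials of one session (presentation order, one
#' row per trial) with the task configuration and free-form metadata (e.g.
#' generating agent parameters and seed for simulated sessions).
#'
#' @param trials `data.frame` with the trial-log columns (see
#'   [read_session_log()] for the column set).
#' @param config A [task_config()].
#' @param metadata Optional named list.
#' @param validate Check invariants (default `TRUE`).
#' @return An object of class `session_log`.
#' @export
session_log <- function(trials, config = task_config(), metadata = list(),
                        validate = TRUE) {
  stopifnot(is.data.frame(trials))
  missing <- setdiff(TRIAL_LOG_COLUMNS, names(trials))
  if (length(missing) > 0)
    stop("trial log is missing column(s): ", paste(missing, collapse = ", "))
  trials <- trials[, TRIAL_LOG_COLUMNS]
  for (col in c("chose_internal", "perceptual_correct", "rewarded"))
    trials[[col]] <- as.logical(trials[[col]])
  trials$trial_index <- as.integer(trials$trial_index)
  rownames(trials) <- NULL
  log <- structure(list(config = config, trials = trials, metadata = metadata),
                   class = "session_log")
  if (validate) validate_session_log(log)
  log
}

#' Validate a session log against the task invariants
#'
#' Checks, per trial: a reward is only possible after a correct perceptual
#' decision; coherence and external probability come from the configured
#' grids; trial indices are strictly increasing. Violations are reported with
#' their row numbers.
#'
#' @param log A [session_log()].
#' @return The log, invisibly; errors on any violation.
#' @export
validate_session_log <- function(log) {
  tr <- log$trials
  if (nrow(tr) == 0) return(invisible(log))
  bad <- which(tr$rewarded & !tr$perceptual_correct)
  if (length(bad) > 0)
    stop("invalid trial log: rewarded=1 with perceptual_correct=0 at row(s) ",
         paste(bad, collapse = ", "))
  bad <- which(!near_in(tr$coherence, log$config$coherence_levels))
  if (length(bad) > 0)
    stop("invalid trial log: coherence outside the configured levels at row(s) ",
         paste(utils::head(bad, 10), collapse = ", "))
  bad <- which(!near_in(tr$p_external, log$config$external_probabilities))
  if (length(bad) > 0)
    stop("invalid trial log: p_external outside the configured levels at row(s) ",
         paste(utils::head(bad, 10), collapse = ", "))
  for (sid in unique(tr$session_id)) {
    idx <- tr$trial_index[tr$session_id == sid]
    if (any(diff(idx) <= 0))
      stop("invalid trial log: trial_index not strictly increasing in session ", sid)
  }
  bad <- which(!tr$true_direction %in% c("left", "right") |
                 !tr$response_direction %in% c("left", "right"))
  if (length(bad) > 0)
    stop("invalid trial log: direction must be left/right at row(s) ",
         paste(utils::head(bad, 10), collapse = ", "))
  invisible(log)
}

near_in <- function(x, set, tol = 1e-9) {
  vapply(x, function(v) any(abs(v - set) < tol), logical(1))
}

#' @export
print.session_log <- function(x, ...) {
  cat("session_log:", nrow(x$trials), "trials,",
      length(unique(x$trials$session_id)), "session(s)\n")
  invisible(x)
}

#' Write a trial log as tab-separated text
#'
#' Output is byte-stable for identical input: fixed column order, booleans as
#' 0/1, probabilities as plain decimals with at most six significant digits,
#' `\n` line endings.
#'
#' @param log A [session_log()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(log, path) {
  validate_session_log(log)
  tr <- log$trials
  fields <- list(
    as.character(tr$session_id),
    as.character(tr$trial_index),
    format_prob(tr$coherence),
    format_prob(tr$p_external),
    as.character(as.integer(tr$chose_internal)),
    tr$true_direction,
    tr$response_direction,
    as.character(as.integer(tr$perceptual_correct)),
    as.character(as.integer(tr$rewarded)))
  lines <- c(paste(TRIAL_LOG_COLUMNS, collapse = "\t"),
             if (nrow(tr) > 0) do.call(paste, c(fields, sep = "\t")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a trial log from tab-separated text
#'
#' @param path File written by [write_session_log()] (or any TSV with the
#'   same header).
#' @param config Task configuration used for validation.
#' @return A validated [session_log()].
#' @export
read_session_log <- function(path, config = task_config()) {
  if (!file.exists(path)) stop("no such file: ", path)
  tr <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = list(session_id = "character"),
                          stringsAsFactors = FALSE)
  missing <- setdiff(TRIAL_LOG_COLUMNS, names(tr))
  if (length(missing) > 0)
    stop("trial-log format error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  session_log(tr, config = config)
}

#' Empirical accuracy per coherence from follow-up trials
#'
#' The follow-up task presents the internal option alone (no metacognitive
#' choice stage); per coherence level it yields an empirical estimate of the
#' probability of a correct perceptual decision. This table is the baseline
#' "internal probability" used by optimality classification, the decision
#' variable model, and the challenge/inevitable analysis.
#'
#' @param trials Trial `data.frame` (or a [session_log()]) of internal-only
#'   perceptual trials.
#' @param config Optional [task_config()]; if given, coherences absent from
#'   the configured levels raise an error.
#' @return `data.frame` of class `followup_table` with columns `coherence`,
#'   `n_trials`, `n_correct`, `p_correct`. Warns (does not fail) if accuracy
#'   is not non-decreasing in coherence.
#' @export
followup_table <- function(trials, config = NULL) {
  if (inherits(trials, "session_log")) trials <- trials$trials
  if (!is.data.frame(trials) || nrow(trials) == 0)
    stop("followup_table: no trials supplied")
  if (!all(trials$chose_internal))
    stop("followup_table: follow-up trials must all be internal-only perceptual trials")
  if (!is.null(config)) {
    bad <- unique(trials$coherence[!near_in(trials$coherence, config$coherence_levels)])
    if (length(bad) > 0)
      stop("followup_table: coherence(s) absent from config: ",
           paste(bad, collapse = ", "))
  }
  coh <- sort(unique(trials$coherence))
  n <- vapply(coh, function(cc) sum(abs(trials$coherence - cc) < 1e-9), numeric(1))
  k <- vapply(coh, function(cc)
    sum(trials$perceptual_correct[abs(trials$coherence - cc) < 1e-9]), numeric(1))
  out <- data.frame(coherence = coh, n_trials = as.integer(n),
                    n_correct = as.integer(k), p_correct = k / n)
  if (any(diff(out$p_correct) < 0))
    warning("followup_table: p_correct is not non-decreasing in coherence")
  class(out) <- c("followup_table", "data.frame")
  out
}

#' Look up follow-up accuracy for given coherences
#'
#' @param followup A [followup_table()].
#' @param coherence Vector of coherence levels.
#' @return Vector of `p_correct` values; errors if any level has no entry.
#' @export
followup_p_correct <- function(followup, coherence) {
  idx <- match_near(coherence, followup$coherence)
  if (anyNA(idx))
    stop("no follow-up entry for coherence(s): ",
         paste(unique(coherence[is.na(idx)]), collapse = ", "))
  followup$p_correct[idx]
}

match_near <- function(x, table, tol = 1e-9) {
  vapply(x, function(v) {
    j <- which(abs(v - table) < tol)
    if (length(j) == 0) NA_integer_ else j[1]
  }, integer(1))
}

#' Write / read a follow-up table as tab-separated text
#'
#' @param followup A [followup_table()].
#' @param path File path.
#' @return `path` (write) or a `followup_table` (read).
#' @export
write_followup_table <- function(followup, path) {
  lines <- c("coherence\tn_trials\tn_correct",
             paste(format_prob(followup$coherence), followup$n_trials,
                   followup$n_correct, sep = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_followup_table
#' @export
read_followup_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.delim(path, sep = "\t", header = TRUE)
  missing <- setdiff(c("coherence", "n_trials", "n_correct"), names(x))
  if (length(missing) > 0)
    stop("follow-up format error: missing column(s) ", paste(missing, collapse = ", "))
  x$p_correct <- x$n_correct / x$n_trials
  class(x) <- c("followup_table", "data.frame")
  x
}
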