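#' Linearize the coherence ladder
#'
#' The task's coherence levels are approximately geometrically spaced. For
#' regression modeling the "internal probability" predictor is the coherence
#' mapped off that exponential-like ladder onto a linear scale. Two
#' candidate transforms are provided: `"rank"` (default) maps each level to
#' its rank index rescaled to \[0, 1\]; `"log"` maps `log(c)` (with the
#' zero level pinned half a log-step below the smallest positive level)
#' rescaled to \[0, 1\]. Predictors are z-scored downstream, so only the
#' spacing, not the scale, matters.
#'
#' @param coherence Vector of coherence values.
#' @param levels The configured coherence ladder.
#' @param method `"rank"` or `"log"`.
#' @return Numeric vector in \[0, 1\].
#' @export
coherence_transform <- function(coherence,
                                levels = task_config()$coherence_levels,
                                method = c("rank", "log")) {
  method <- match.arg(method)
  levels <- sort(levels)
  idx <- match_near(coherence, levels)
  if (anyNA(idx))
    stop("coherence value(s) not on the configured ladder: ",
         paste(unique(coherence[is.na(idx)]), collapse = ", "))
  if (method == "rank") {
    (idx - 1) / (length(levels) - 1)
  } else {
    pos <- levels[levels > 0]
    floor_val <- if (any(levels == 0)) {
      # half a log-step below the smallest positive level
      exp(log(pos[1]) - diff(log(pos[1:2])) / 2)
    } else pos[1]
    lv <- log(pmax(levels, floor_val))
    x <- lv[idx]
    (x - min(lv)) / (max(lv) - min(lv))
  }
}

lag_encounter_index <- function(is_type, n_lags) {
  # for each trial, the row indices of the k-th most recent trial (strictly
  # before it, same session) on which the given task type was performed
  n <- length(is_type)
  out <- matrix(NA_integer_, n, n_lags)
  hist <- integer(0)
  for (i in seq_len(n)) {
    nh <- length(hist)
    k <- seq_len(min(n_lags, nh))
    if (length(k) > 0) out[i, k] <- hist[nh - k + 1L]
    if (is_type[i]) hist <- c(hist, i)
  }
  out
}

#' Build the lagged logistic design matrix
#'
#' One row per trial. Current-trial predictors are the linearized internal
#' probability `x_int` and the external probability `x_ext`. For each lag
#' k = 1..`n_lags`, the design contains the outcome of the k-th previous
#' *encounter* of each task type (`o_int_k`, `o_ext_k`: the k-th most recent
#' trial on which that option was actually performed, within the same
#' session), the probabilities offered on those encounter trials (`x_int_k`,
#' `x_ext_k`), and the outcome-by-probability products (`ox_int_k`,
#' `ox_ext_k`). An internal encounter's outcome is its perceptual
#' correctness; an external encounter's outcome is its reward. Trials whose
#' history contains fewer than `n_lags` encounters of either type are
#' dropped (and counted) rather than zero-imputed. All predictors are
#' z-scored within session after row selection; columns that are constant
#' after masking are reported in the `degenerate` field.
#'
#' @param log A [session_log()] (may contain several sessions; histories
#'   never cross a session boundary).
#' @param dependent `"choice"` (y = chose internal) or `"performance"`
#'   (y = outcome of the performed task, rows restricted to trials where
#'   `side` was chosen).
#' @param side For `dependent = "performance"`: score the `"internal"` task
#'   (y = perceptual correctness) or the `"external"` task (y = reward).
#' @param n_lags Number of past encounters per task type (default 3).
#' @param transform Coherence linearization, see [coherence_transform()].
#' @return List of class `lagged_design` with `X` (numeric matrix, z-scored,
#'   no intercept column), `y`, `session`, `n_dropped`, `degenerate`.
#' @export
build_lagged_design <- function(log, dependent = c("choice", "performance"),
                                side = c("internal", "external"), n_lags = 3L,
                                transform = c("rank", "log")) {
  dependent <- match.arg(dependent)
  side <- match.arg(side)
  transform <- match.arg(transform)
  trials <- if (inherits(log, "session_log")) log$trials else log
  config <- if (inherits(log, "session_log")) log$config else task_config()

  per_session <- lapply(split(trials, trials$session_id), function(tr) {
    n <- nrow(tr)
    x_int <- coherence_transform(tr$coherence, config$coherence_levels, transform)
    x_ext <- tr$p_external
    outcome <- ifelse(tr$chose_internal, tr$perceptual_correct, tr$rewarded)
    li <- lag_encounter_index(tr$chose_internal, n_lags)
    le <- lag_encounter_index(!tr$chose_internal, n_lags)
    cols <- list(x_int = x_int, x_ext = x_ext)
    for (k in seq_len(n_lags)) {
      oi <- as.numeric(outcome[li[, k]]); oe <- as.numeric(outcome[le[, k]])
      xi <- x_int[li[, k]];               xe <- x_ext[le[, k]]
      cols[[paste0("o_int_", k)]] <- oi
      cols[[paste0("o_ext_", k)]] <- oe
      cols[[paste0("x_int_", k)]] <- xi
      cols[[paste0("x_ext_", k)]] <- xe
      cols[[paste0("ox_int_", k)]] <- oi * xi
      cols[[paste0("ox_ext_", k)]] <- oe * xe
    }
    X <- do.call(cbind, cols)
    y <- if (dependent == "choice") as.numeric(tr$chose_internal)
         else as.numeric(if (side == "internal") tr$perceptual_correct else tr$rewarded)
    keep <- stats::complete.cases(X)
    if (dependent == "performance")
      keep <- keep & (tr$chose_internal == (side == "internal"))
    list(X = X[keep, , drop = FALSE], y = y[keep],
         session = rep(tr$session_id[1], sum(keep)),
         n_dropped = sum(stats::complete.cases(X) == FALSE))
  })

  X <- do.call(rbind, lapply(per_session, `[[`, "X"))
  y <- unlist(lapply(per_session, `[[`, "y"), use.names = FALSE)
  session <- unlist(lapply(per_session, `[[`, "session"), use.names = FALSE)
  if (length(y) == 0) stop("no usable rows after lag masking")
  if (dependent == "performance" && side == "internal" && all(y == y[1]) && length(y) > 0 &&
      !any(trials$chose_internal))
    stop("performance model undefined: no chosen-internal trials")
  # z-score within session after row selection
  degenerate <- character(0)
  for (s in unique(session)) {
    i <- session == s
    for (j in seq_len(ncol(X))) {
      v <- X[i, j]
      if (stats::sd(v) < 1e-12) {
        degenerate <- union(degenerate, colnames(X)[j])
        X[i, j] <- 0
      } else {
        X[i, j] <- (v - mean(v)) / stats::sd(v)
      }
    }
  }
  structure(list(X = X, y = y, session = session,
                 n_dropped = sum(vapply(per_session, `[[`, numeric(1), "n_dropped")),
                 degenerate = degenerate),
            class = "lagged_design")
}

#' Maximum-likelihood logistic regression by IRLS
#'
#' Iteratively reweighted least squares with an intercept, monotone
#' non-decreasing log-likelihood (step-halving if a step would decrease it),
#' convergence when the largest coefficient change is below `tol`. Perfect
#' separation is detected (diverging coefficients together with perfect
#' classification) and raised as an error naming the culprit columns.
#'
#' @param X Numeric predictor matrix (no intercept column).
#' @param y 0/1 response vector.
#' @param tol Convergence tolerance on coefficient change.
#' @param max_iter Iteration cap.
#' @return List of class `fit_result`: `coefficients` (named, starting with
#'   `(Intercept)`), `se`, `converged`, `n_rows_used`, `log_lik`,
#'   `n_iterations`.
#' @export
fit_logistic <- function(X, y, tol = 1e-8, max_iter = 100L) {
  if (inherits(X, "lagged_design")) { y <- X$y; X <- X$X }
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  sds <- apply(X, 2, stats::sd)
  if (any(sds < 1e-12))
    stop("degenerate (constant) column(s) in design: ",
         paste(colnames(X)[sds < 1e-12], collapse = ", "))
  Xi <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xi)
  beta <- rep(0, p)
  loglik <- function(b) {
    eta <- drop(Xi %*% b)
    sum(y * eta - log1p(exp(eta)))
  }
  ll <- loglik(beta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(Xi %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    fit <- tryCatch(solve(crossprod(Xi, Xi * w), crossprod(Xi, w * z)),
                    error = function(e) NULL)
    if (is.null(fit)) stop("rank-deficient design in logistic fit")
    beta_new <- drop(fit)
    # step-halving keeps the log-likelihood monotone non-decreasing
    step <- 1
    ll_new <- loglik(beta_new)
    while (ll_new < ll - 1e-12 && step > 1e-4) {
      step <- step / 2
      beta_new <- beta + step * (drop(fit) - beta)
      ll_new <- loglik(beta_new)
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    ll <- ll_new
    eta <- drop(Xi %*% beta)
    mu <- stats::plogis(eta)
    if (max(abs(eta)) > 25 && all((mu > 0.5) == (y == 1))) {
      culprit <- colnames(Xi)[order(-abs(beta))]
      culprit <- setdiff(culprit, "(Intercept)")[1:min(2, p - 1)]
      stop("perfect separation in logistic fit; culprit column(s): ",
           paste(culprit, collapse = ", "))
    }
    if (delta < tol) { converged <- TRUE; break }
  }
  mu <- stats::plogis(drop(Xi %*% beta))
  w <- pmax(mu * (1 - mu), 1e-10)
  info <- crossprod(Xi, Xi * w)
  se <- sqrt(diag(solve(info)))
  structure(list(coefficients = stats::setNames(beta, colnames(Xi)),
                 se = stats::setNames(se, colnames(Xi)),
                 converged = converged, n_rows_used = nrow(Xi),
                 log_lik = ll, n_iterations = iter),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("logistic fit (", x$n_rows_used, " rows, ",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  print(round(cbind(estimate = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' Fit the lagged choice/performance model
#'
#' Builds the lagged design ([build_lagged_design()]) and fits the logistic
#' model. By default the model is fitted separately per session and the
#' coefficients averaged (matching a per-participant, per-session analysis
#' followed by aggregation); `per_session = FALSE` pools all rows into one
#' fit.
#'
#' @param log A [session_log()].
#' @param dependent,side,n_lags,transform Passed to [build_lagged_design()].
#' @param per_session Average per-session fits (default) or pool.
#' @return For `per_session = TRUE`: list with `coefficients` (across-session
#'   mean), `se` (sd of per-session estimates / sqrt(sessions)), `fits`
#'   (per-session [fit_logistic()] results), `n_sessions`. Otherwise a
#'   single `fit_result`.
#' @export
fit_lagged_model <- function(log, dependent = "choice", side = "internal",
                             n_lags = 3L, transform = "rank",
                             per_session = TRUE) {
  if (!per_session) {
    design <- build_lagged_design(log, dependent, side, n_lags, transform)
    return(fit_logistic(design))
  }
  trials <- if (inherits(log, "session_log")) log$trials else log
  config <- if (inherits(log, "session_log")) log$config else task_config()
  fits <- lapply(split(trials, trials$session_id), function(tr) {
    d <- build_lagged_design(session_log(tr, config, validate = FALSE),
                             dependent, side, n_lags, transform)
    tryCatch(fit_logistic(d), error = function(e) {
      if (!grepl("separation", conditionMessage(e))) stop(e)
      warning("session ", tr$session_id[1],
              " dropped from the per-session average (", conditionMessage(e), ")",
              call. = FALSE)
      NULL
    })
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0)
    stop("no session could be fitted (perfect separation in every session)")
  coefs <- do.call(rbind, lapply(fits, `[[`, "coefficients"))
  list(coefficients = colMeans(coefs),
       se = apply(coefs, 2, stats::sd) / sqrt(nrow(coefs)),
       fits = fits, n_sessions = nrow(coefs))
}

#' Decision-variable logistic model of option choice
#'
#' The decision variable on trial n is the internal reward probability (the
#' participant's follow-up accuracy at the trial's coherence, times the
#' internal option's certain reward contingency) minus the external reward
#' probability. The model is a single-predictor logistic regression of the
#' internal-option choice on DV.
#'
#' @param log A [session_log()].
#' @param followup A [followup_table()] covering every coherence in the log.
#' @return A `fit_result` (see [fit_logistic()]) with predictor `dv`, plus a
#'   `dv` vector attribute.
#' @export
fit_dv_model <- function(log, followup) {
  trials <- if (inherits(log, "session_log")) log$trials else log
  dv <- followup_p_correct(followup, trials$coherence) * 1.0 - trials$p_external
  fit <- fit_logistic(matrix(dv, dimnames = list(NULL, "dv")),
                      as.numeric(trials$chose_internal))
  attr(fit, "dv") <- dv
  fit
}
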