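#' Performance metrics and statistics
#'
#' Run-level task metrics (percent trials correct, average decision time,
#' average integrated distance to target), trajectory metrics quantifying
#' decoding bias (position covariance, true-vs-decoded velocity angle,
#' trajectory length), ordinary-least-squares parameter trends and paired
#' t-tests. All trials, including timeouts (counted as 6 s), enter the
#' run-level metrics.
#'
#' @name analysis
NULL

#' Run-level metrics
#'
#' @param results list of `smr_trial_result`s from one run.
#' @return an `smr_run_metrics` list: `ptc` (percent of all trials hit),
#'   `avg_decision_time` (s; timeouts count as the feedback limit),
#'   `avg_integrated_distance` (workspace units; per-trial mean distance to
#'   target, averaged over trials), and the outcome counts.
#' @export
run_metrics <- function(results) {
  if (!length(results)) stop("empty result list")
  outc <- vapply(results, function(r) r$outcome, character(1))
  n <- length(results)
  n_hits <- sum(outc == "hit")
  dt <- vapply(results, function(r) r$duration_s, numeric(1))
  idist <- vapply(results, function(r) mean(r$distance), numeric(1))
  structure(list(
    ptc = 100 * n_hits / n,
    avg_decision_time = mean(dt),
    avg_integrated_distance = mean(idist),
    n_trials = n, n_hits = n_hits,
    n_misses = sum(outc == "miss"), n_timeouts = sum(outc == "timeout")),
    class = "smr_run_metrics")
}

#' @export
print.smr_run_metrics <- function(x, ...) {
  cat(sprintf("<smr_run_metrics> %d trials: PTC %.1f%%, decision time %.2f s, integrated distance %.3f\n",
              x$n_trials, x$ptc, x$avg_decision_time, x$avg_integrated_distance))
  invisible(x)
}

#' Trajectory metrics for one trial
#'
#' The per-sample angle of deviation between the true (intended) and
#' decoded velocity vectors (degrees, in `[0, 180]`; samples where either
#' vector has zero norm are excluded) and the trajectory length (the norm of
#' the decoded velocity summed over the feedback samples, i.e. path length
#' in workspace units).
#'
#' @param result an `smr_trial_result`.
#' @param screen_px workspace extent used to express lengths in normalized
#'   units.
#' @return list with `mean_angle_deviation` (degrees, `NA` if no valid
#'   samples) and `trajectory_length` (workspace units).
#' @export
trajectory_metrics <- function(result, screen_px = 1000) {
  v <- result$velocities
  u <- result$intention
  nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
  ok <- nu > 0 & nv > 0
  ang <- if (any(ok)) {
    cosang <- rowSums(u[ok, , drop = FALSE] * v[ok, , drop = FALSE]) /
      (nu[ok] * nv[ok])
    mean(acos(pmin(1, pmax(-1, cosang)))) * 180 / pi
  } else NA_real_
  dt <- result$duration_s / nrow(v)
  # decoded velocity is in pixels/s; normalize to workspace units
  len <- sum(nv) * dt / (screen_px / 2)
  list(mean_angle_deviation = ang, trajectory_length = len)
}

#' Pooled cursor position covariance for a run
#'
#' Sample covariance between horizontal and vertical cursor positions,
#' pooled over the feedback-phase samples of all trials in the run
#' (normalized workspace units).
#'
#' @param results list of `smr_trial_result`s (2D paradigm).
#' @param screen_px workspace extent in pixels.
#' @return scalar covariance.
#' @export
position_covariance <- function(results, screen_px = 1000) {
  xy <- do.call(rbind, lapply(results, function(r) r$trajectory))
  if (is.null(xy) || nrow(xy) < 2) stop("need at least 2 pooled position samples")
  half <- screen_px / 2
  xn <- (xy[, 1] - half) / half; yn <- (xy[, 2] - half) / half
  stats::cov(xn, yn)
}

#' Ordinary least squares trend of a metric against a parameter
#'
#' @param parameter numeric parameter values (one per subject-run point).
#' @param metric numeric metric values.
#' @return an `smr_trend`: slope, intercept, two-sided slope p-value and
#'   95 percent confidence interval, plus the underlying `lm` fit.
#' @export
ols_trend <- function(parameter, metric) {
  stopifnot(length(parameter) == length(metric))
  if (length(parameter) < 3) stop("need at least 3 points")
  if (length(unique(parameter)) < 2) stop("need at least 2 distinct parameter values")
  fit <- stats::lm(metric ~ parameter)
  sm <- summary(fit)
  ci <- stats::confint(fit, "parameter", level = 0.95)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    slope_p = unname(sm$coefficients["parameter", "Pr(>|t|)"]),
    slope_ci = unname(ci[1, ]),
    fit = fit,
    data = data.frame(parameter = parameter, metric = metric)),
    class = "smr_trend")
}

#' @export
print.smr_trend <- function(x, ...) {
  cat(sprintf("<smr_trend> slope %.4g [%.4g, %.4g], p = %.3g\n",
              x$slope, x$slope_ci[1], x$slope_ci[2], x$slope_p))
  invisible(x)
}

#' Paired t-test with degenerate-case handling
#'
#' Standard two-sided paired t statistic on the within-pair differences.
#' All-zero differences return t = 0, p = 1 with `degenerate = TRUE`;
#' nonzero constant differences (zero variance) are flagged degenerate with
#' p = 0.
#'
#' @param a,b paired condition samples (equal length >= 2).
#' @return list with `t`, `p`, `df`, `mean_difference`, `degenerate`.
#' @export
paired_ttest <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(list(t = 0, p = 1, df = length(d) - 1, mean_difference = 0,
                  degenerate = TRUE))
    }
    return(list(t = sign(mean(d)) * Inf, p = 0, df = length(d) - 1,
                mean_difference = mean(d), degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_difference = unname(ht$estimate),
       degenerate = FALSE)
}

#' Per-run metrics table for a session
#'
#' @param session an `smr_session`.
#' @return data frame with one row per run: the swept parameter columns and
#'   the run metrics.
#' @export
session_metrics <- function(session) {
  stopifnot(inherits(session, "smr_session"))
  out <- session$runs
  ms <- lapply(seq_len(nrow(out)), function(ri) {
    res <- Filter(function(t) t$run == ri, session$trials)
    m <- run_metrics(res)
    data.frame(ptc = m$ptc, avg_decision_time = m$avg_decision_time,
               avg_integrated_distance = m$avg_integrated_distance,
               n_hits = m$n_hits, n_misses = m$n_misses,
               n_timeouts = m$n_timeouts)
  })
  cbind(out, do.call(rbind, ms))
}
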