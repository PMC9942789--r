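#' Simulate a rating agent at question trials
#'
#' A ground-truth generator for model and parameter recovery: the simulated
#' participant's probability report at a question trial is the learner's
#' posterior-mean prediction for the next stimulus plus Gaussian noise,
#' clipped to [0, 1]; the confidence report is the learner's confidence
#' min-max-normalized over the participant's own trace (a bounded-scale
#' mapping; only correlations in it are consumed downstream), plus noise,
#' clipped.
#'
#' @param sequence a `ps_sequence` (or 1/2 intensity vector).
#' @param schedule integer question positions from [schedule_questions()].
#' @param spec learner [model_spec()] generating the reports.
#' @param noise_sd report noise SD on the unit scale (>= 0).
#' @param seed integer seed.
#' @param trace optional precomputed [run_learner()] trace for `sequence`
#'   and `spec` (avoids recomputation).
#' @return tibble: `trial`, `p_report`, `conf_report` (one row per question).
#' @export
simulate_rater <- function(sequence, schedule, spec, noise_sd = 0.05, seed,
                           trace = NULL) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (is.null(trace)) trace <- run_learner(sequence, spec)
  schedule <- as.integer(schedule)
  stopifnot(all(schedule >= 1), all(schedule <= nrow(trace)))
  set.seed(as.integer(seed))
  p <- trace$p_next[schedule]
  cf <- trace$confidence
  if (all(is.na(cf))) {
    conf_norm <- rep(NA_real_, length(schedule))
  } else {
    rng <- range(cf, na.rm = TRUE)
    span <- if (diff(rng) > 0) diff(rng) else 1
    conf_norm <- (cf[schedule] - rng[1]) / span
  }
  n_q <- length(schedule)
  p_report <- pmin(pmax(p + stats::rnorm(n_q, 0, noise_sd), 0), 1)
  conf_report <- pmin(pmax(conf_norm + stats::rnorm(n_q, 0, noise_sd), 0), 1)
  tibble::tibble(trial = schedule, p_report = p_report,
                 conf_report = conf_report)
}
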