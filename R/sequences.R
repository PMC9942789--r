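#' Generate a Markov stimulus sequence
#'
#' Draws a binary intensity stream (1 = cool I1, 2 = hot I2) from a two-state
#' Markov chain parameterized by the transition-probability pair
#' `(p(I1|I2), p(I2|I1))`. The first stimulus is drawn from the chain's
#' stationary distribution, `p(y1 = I1) = p(I1|I2) / (p(I1|I2) + p(I2|I1))`,
#' and every later stimulus from the transition row indexed by its
#' predecessor.
#'
#' @param tp_pair numeric length-2, `(p(I1|I2), p(I2|I1))`, each strictly
#'   inside (0, 1).
#' @param n_stimuli sequence length (>= 1); the testing-block design uses 100.
#' @param seed integer seed; equal seeds reproduce the identical sequence.
#' @param block_id integer condition label carried through to trial metadata.
#' @param isi_seconds interstimulus interval in seconds (default 3).
#' @return a `ps_sequence`: list with `intensities` (integer vector of 1/2),
#'   `tp_pair`, `block_id`, `isi_seconds`, `seed`.
#' @examples
#' s <- generate_sequence(c(0.3, 0.7), 100, seed = 1)
#' table(s$intensities)
#' @export
generate_sequence <- function(tp_pair, n_stimuli = 100, seed,
                              block_id = 1L, isi_seconds = 3) {
  stopifnot(length(tp_pair) == 2, n_stimuli >= 1, isi_seconds > 0)
  if (any(tp_pair <= 0) || any(tp_pair >= 1)) {
    stop("tp_pair components must lie strictly inside (0, 1); ",
         "degenerate chains are rejected")
  }
  p_1_given_2 <- tp_pair[1]
  p_2_given_1 <- tp_pair[2]
  set.seed(as.integer(seed))
  p1_stationary <- p_1_given_2 / (p_1_given_2 + p_2_given_1)
  u <- stats::runif(n_stimuli)
  y <- integer(n_stimuli)
  y[1] <- if (u[1] < p1_stationary) 1L else 2L
  if (n_stimuli > 1) {
    for (n in 2:n_stimuli) {
      ## probability of switching away from the current state
      p_switch <- if (y[n - 1] == 1L) p_2_given_1 else p_1_given_2
      y[n] <- if (u[n] < p_switch) 3L - y[n - 1] else y[n - 1]
    }
  }
  structure(
    list(intensities = y, tp_pair = as.numeric(tp_pair),
         block_id = as.integer(block_id), isi_seconds = isi_seconds,
         seed = as.integer(seed)),
    class = "ps_sequence"
  )
}

#' @export
print.ps_sequence <- function(x, ...) {
  cat(sprintf(
    "<ps_sequence> block %d: %d stimuli, TPs (p(I1|I2), p(I2|I1)) = (%.2f, %.2f), ISI %.1f s, seed %d\n",
    x$block_id, length(x$intensities), x$tp_pair[1], x$tp_pair[2],
    x$isi_seconds, x$seed))
  cat("  first 20:", paste(x$intensities[seq_len(min(20, length(x$intensities)))],
                           collapse = ""), "...\n")
  invisible(x)
}

#' Schedule question trials along a sequence
#'
#' Question trials pause the sequence every `interval` +/- `jitter` stimuli;
#' gaps between consecutive question positions are drawn uniformly from the
#' integers `[interval - jitter, interval + jitter]`.
#'
#' @param n_stimuli sequence length.
#' @param interval mean gap in stimuli (design default 15).
#' @param jitter maximal absolute deviation of a gap (design default 3);
#'   must satisfy `interval > jitter >= 0`.
#' @param seed integer seed.
#' @return strictly increasing integer vector of question positions, all
#'   `<= n_stimuli` (possibly empty for short sequences).
#' @examples
#' schedule_questions(100, 15, 0, seed = 1)  # 15, 30, ..., 90
#' @export
schedule_questions <- function(n_stimuli, interval = 15, jitter = 3, seed) {
  stopifnot(n_stimuli >= 1, interval > jitter, jitter >= 0)
  set.seed(as.integer(seed))
  max_q <- ceiling(n_stimuli / (interval - jitter)) + 1L
  choices <- seq.int(interval - jitter, interval + jitter)
  gaps <- choices[sample.int(length(choices), max_q, replace = TRUE)]
  idx <- cumsum(gaps)
  as.integer(idx[idx <= n_stimuli])
}
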