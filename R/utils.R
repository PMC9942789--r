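#' @keywords internal
"_PACKAGE"

## Probabilities are clamped before any log so that surprise and the
## log-probability regressors stay finite on degenerate inputs.
.P_EPS <- 1e-12

clamp01 <- function(p, eps = .P_EPS) {
  pmin(pmax(p, eps), 1 - eps)
}

log_sum_exp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Derive a child random seed from a parent seed and integer keys
#'
#' Expands one global seed into independent, reproducible sub-streams
#' (per participant, per block, per stage) via a Lehmer-style mix kept
#' strictly below 2^31 so it is always a valid R integer seed.
#'
#' @param seed parent integer seed.
#' @param ... integer keys (participant index, block index, stage tag, ...).
#' @return a single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  keys <- c(seed, ...)
  m <- 2147483647
  s <- 1
  for (k in keys) {
    s <- (s * 48271 + (as.numeric(k) %% m) + 1) %% m
  }
  as.integer(s + 1)
}

#' Integration half-life of a leaky integrator
#'
#' Number of stimuli after which the exponential count weight
#' `exp(-k / omega)` has fallen to one half, rounded to the nearest
#' whole stimulus.
#'
#' @param omega integration time constant in stimuli.
#' @return half-life in stimuli (integer-valued numeric).
#' @export
integration_half_life <- function(omega) {
  stopifnot(all(omega >= 1))
  round(omega * log(2))
}

#' Integration time constant expressed in seconds
#'
#' @param omega integration time constant in stimuli.
#' @param isi_seconds interstimulus interval in seconds (design default 3 s).
#' @return time constant in seconds.
#' @export
integration_time_seconds <- function(omega, isi_seconds = 3) {
  stopifnot(all(omega >= 1), isi_seconds > 0)
  omega * isi_seconds
}
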