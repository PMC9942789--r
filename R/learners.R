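#' Specify a sequence-learning model
#'
#' Six models are considered: Bayesian ideal observers with leaky
#' integration (family `"bayes"`, parameter the integration time constant
#' `omega` in `[1, Inf]`) and Rescorla-Wagner delta rules (family `"rw"`,
#' parameter the learning rate `alpha` in (0, 1)), each tracking one of
#' three sequence statistics: item frequency (`"IF"`), alternation
#' frequency (`"AF"`), or the two transition probabilities (`"TP"`).
#'
#' @param family `"bayes"` or `"rw"`.
#' @param statistic `"IF"`, `"AF"` or `"TP"`.
#' @param param `omega` (bayes; `Inf` = perfect integrator) or `alpha` (rw).
#' @param most_recent_weight_one logical; if `TRUE` (default) the most recent
#'   counted observation carries leak weight 1 (`exp(0)`), if `FALSE` it
#'   carries `exp(-1/omega)`. Only the relative weighting differs; see
#'   [leaky_counts()].
#' @param tp_confidence `"row"` (default): confidence of the TP model is the
#'   log precision of the Beta marginal for the transition row conditioned on
#'   the previous stimulus — the row that governs the next prediction.
#'   `"joint"`: sum of both rows' log precisions.
#' @return a `ps_model_spec` list.
#' @export
model_spec <- function(family = c("bayes", "rw"),
                       statistic = c("TP", "IF", "AF"),
                       param,
                       most_recent_weight_one = TRUE,
                       tp_confidence = c("row", "joint")) {
  family <- match.arg(family)
  statistic <- match.arg(statistic)
  tp_confidence <- match.arg(tp_confidence)
  stopifnot(length(param) == 1, is.numeric(param))
  if (family == "bayes") {
    if (param < 1) stop("omega must lie in [1, Inf]")
  } else {
    if (param <= 0 || param >= 1) stop("alpha must lie strictly in (0, 1)")
  }
  structure(
    list(family = family, statistic = statistic, param = param,
         most_recent_weight_one = most_recent_weight_one,
         tp_confidence = tp_confidence,
         label = sprintf("%s-%s", statistic, family)),
    class = "ps_model_spec"
  )
}

#' @export
print.ps_model_spec <- function(x, ...) {
  pname <- if (x$family == "bayes") "omega" else "alpha"
  cat(sprintf("<ps_model_spec> %s (%s = %g)\n", x$label, pname, x$param))
  invisible(x)
}

#' Leaky (exponentially weighted) event counts
#'
#' The ideal observer forgets: the k-th last counted observation (item,
#' alternation, or transition, depending on the tracked statistic) is
#' weighted by `exp(-k / omega)` with `k = 0` for the most recent one, so a
#' perfect integrator (`omega = Inf`) reduces to plain counting.
#'
#' @param flags 0/1 (or logical) vector of counted observations, ordered
#'   oldest to newest; `flags[k] = 1` means the event was of the counted type.
#' @param omega integration time constant in stimuli, `[1, Inf]`.
#' @param most_recent_weight_one if `FALSE`, weights are `exp(-k/omega)` with
#'   `k = 1` for the most recent observation instead (a uniform rescaling of
#'   all weights by `exp(-1/omega)`).
#' @return named numeric of length 2: `count1` (weighted count of flagged
#'   events) and `count0` (weighted count of unflagged events).
#' @examples
#' leaky_counts(c(1, 1, 1), Inf)  # count1 = 3
#' leaky_counts(c(1, 1, 1), 8)    # 1 + exp(-1/8) + exp(-2/8)
#' @export
leaky_counts <- function(flags, omega, most_recent_weight_one = TRUE) {
  if (omega < 1) stop("omega must lie in [1, Inf]")
  flags <- as.numeric(flags)
  m <- length(flags)
  if (m == 0L) return(c(count1 = 0, count0 = 0))
  k <- (m - 1):0                         # k = 0 for the most recent
  if (!most_recent_weight_one) k <- k + 1
  w <- exp(-k / omega)
  c(count1 = sum(w * flags), count0 = sum(w * (1 - flags)))
}

## ---------------------------------------------------------------------------
## Vectorized learner engine
##
## All six models admit the same O(n) forward recursion; the recursion is run
## once per sequence but vectorized over an arbitrary vector of model
## parameters (the whole omega/alpha grid at once), which is what makes
## grid fitting cheap. Counts are updated as C <- d * C + event with
## d = exp(-1/omega), which reproduces weights exp(-k/omega), k = 0 for the
## most recent event.
## ---------------------------------------------------------------------------

.beta_conf <- function(a, b) {
  ## -log posterior SD of Beta(a, b) = 0.5 * log precision
  -0.5 * log(a * b / ((a + b)^2 * (a + b + 1)))
}

.learner_curves <- function(y, family, statistic, params,
                            most_recent_weight_one = TRUE,
                            tp_confidence = "row") {
  n <- length(y)
  P <- length(params)
  stopifnot(n >= 1, P >= 1, all(y %in% c(1L, 2L)))
  p_obs <- p_next <- conf <- matrix(NA_real_, n, P)

  if (family == "bayes") {
    omega <- params
    d <- exp(-1 / omega)                 # omega = Inf -> d = 1
    w_new <- if (most_recent_weight_one) 1 else d
    if (statistic == "IF") {
      c1 <- c2 <- numeric(P)
      for (nn in seq_len(n)) {
        m1 <- (c1 + 1) / (c1 + c2 + 2)
        p_obs[nn, ] <- if (y[nn] == 1L) m1 else 1 - m1
        c1 <- d * c1 + w_new * (y[nn] == 1L)
        c2 <- d * c2 + w_new * (y[nn] == 2L)
        a <- c1 + 1; b <- c2 + 1
        p_next[nn, ] <- a / (a + b)
        conf[nn, ] <- .beta_conf(a, b)
      }
    } else if (statistic == "AF") {
      ca <- cr <- numeric(P)             # alternations / repetitions
      for (nn in seq_len(n)) {
        if (nn == 1L) {
          p_obs[nn, ] <- 0.5
        } else {
          alt <- y[nn] != y[nn - 1]
          m_alt <- (ca + 1) / (ca + cr + 2)
          p_obs[nn, ] <- if (alt) m_alt else 1 - m_alt
          ca <- d * ca + w_new * alt
          cr <- d * cr + w_new * (!alt)
        }
        a <- ca + 1; b <- cr + 1
        m_alt <- a / (a + b)             # posterior mean P(alternation)
        p_next[nn, ] <- if (y[nn] == 2L) m_alt else 1 - m_alt
        conf[nn, ] <- .beta_conf(a, b)
      }
    } else {                             # TP
      a1 <- b1 <- a2 <- b2 <- numeric(P) # from I1: ->I1, ->I2; from I2: ->I1, ->I2
      for (nn in seq_len(n)) {
        if (nn == 1L) {
          p_obs[nn, ] <- 0.5
        } else {
          if (y[nn - 1] == 1L) m1 <- (a1 + 1) / (a1 + b1 + 2)
          else                 m1 <- (a2 + 1) / (a2 + b2 + 2)
          p_obs[nn, ] <- if (y[nn] == 1L) m1 else 1 - m1
          ## one global transition clock: all four counts decay per transition
          a1 <- d * a1; b1 <- d * b1; a2 <- d * a2; b2 <- d * b2
          if (y[nn - 1] == 1L) {
            if (y[nn] == 1L) a1 <- a1 + w_new else b1 <- b1 + w_new
          } else {
            if (y[nn] == 1L) a2 <- a2 + w_new else b2 <- b2 + w_new
          }
        }
        if (y[nn] == 1L) { ar <- a1 + 1; br <- b1 + 1 }
        else             { ar <- a2 + 1; br <- b2 + 1 }
        p_next[nn, ] <- ar / (ar + br)
        if (tp_confidence == "row") {
          conf[nn, ] <- .beta_conf(ar, br)
        } else {
          conf[nn, ] <- .beta_conf(a1 + 1, b1 + 1) + .beta_conf(a2 + 1, b2 + 1)
        }
      }
    }
  } else {                               # Rescorla-Wagner
    alpha <- params
    if (statistic == "IF") {
      V <- rep(0.5, P)                   # estimated p(I1)
      for (nn in seq_len(n)) {
        p_obs[nn, ] <- if (y[nn] == 1L) V else 1 - V
        R <- as.numeric(y[nn] == 1L)
        V <- V + alpha * (R - V)
        p_next[nn, ] <- V
      }
    } else if (statistic == "AF") {
      V <- rep(0.5, P)                   # estimated p(alternation)
      for (nn in seq_len(n)) {
        if (nn == 1L) {
          p_obs[nn, ] <- 0.5
        } else {
          alt <- y[nn] != y[nn - 1]
          p_obs[nn, ] <- if (alt) V else 1 - V
          V <- V + alpha * (as.numeric(alt) - V)
        }
        p_next[nn, ] <- if (y[nn] == 2L) V else 1 - V
      }
    } else {                             # TP: V1 = est p(I1|I1), V2 = est p(I1|I2)
      V1 <- V2 <- rep(0.5, P)
      for (nn in seq_len(n)) {
        if (nn == 1L) {
          p_obs[nn, ] <- 0.5
        } else {
          m1 <- if (y[nn - 1] == 1L) V1 else V2
          p_obs[nn, ] <- if (y[nn] == 1L) m1 else 1 - m1
          R <- as.numeric(y[nn] == 1L)
          if (y[nn - 1] == 1L) V1 <- V1 + alpha * (R - V1)
          else                 V2 <- V2 + alpha * (R - V2)
        }
        p_next[nn, ] <- if (y[nn] == 1L) V1 else V2
      }
    }
  }
  list(p_obs = p_obs, p_next = p_next, conf = conf)
}

#' Run a sequence-learning model over a stimulus sequence
#'
#' Sequential forward pass: at every position n the model first assigns a
#' probability `p_obs` to the stimulus actually delivered (computed from its
#' state after `y_{1:n-1}`; 0.5 at n = 1 by the uniform-prior / V0 = 0.5
#' convention), yielding the prediction error `pe = 1 - p_obs` and Shannon
#' surprise `-log(p_obs)`; it then updates its state with `y_n` and reports
#' `p_next` (posterior-mean probability that the next stimulus is I1) and,
#' for Bayesian models, the confidence `-log(posterior SD)` of the statistic
#' governing that prediction.
#'
#' @param sequence a `ps_sequence` or an integer vector of 1/2 intensities.
#' @param spec a [model_spec()].
#' @return tibble with one row per trial: `trial`, `intensity`, `p_next`,
#'   `p_obs`, `confidence` (NA for RW models), `pe`, `surprise`.
#' @examples
#' s <- generate_sequence(c(0.3, 0.7), 50, seed = 2)
#' tr <- run_learner(s, model_spec("bayes", "TP", 8))
#' head(tr)
#' @export
run_learner <- function(sequence, spec) {
  y <- if (inherits(sequence, "ps_sequence")) sequence$intensities
       else as.integer(sequence)
  if (length(y) == 0L) stop("empty sequence")
  stopifnot(inherits(spec, "ps_model_spec"))
  cur <- .learner_curves(y, spec$family, spec$statistic, spec$param,
                         spec$most_recent_weight_one, spec$tp_confidence)
  p_obs <- clamp01(drop(cur$p_obs))
  tibble::tibble(
    trial = seq_along(y),
    intensity = y,
    p_next = drop(cur$p_next),
    p_obs = p_obs,
    confidence = drop(cur$conf),
    pe = 1 - p_obs,
    surprise = -log(p_obs)
  )
}
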