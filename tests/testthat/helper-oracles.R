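## Brute-force oracles, independent of the incremental learner engine:
## every quantity is recomputed from scratch from the full history using
## explicit weight sums.

clamp_ref <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)

beta_mean_or <- function(a, b) a / (a + b)
beta_sd_or <- function(a, b) sqrt(a * b / ((a + b)^2 * (a + b + 1)))

## Weighted counts of a 0/1 event vector with weights exp(-k/omega),
## k = 0 for the most recent event. Plain loop, no recursion.
brute_counts <- function(flags, omega) {
  m <- length(flags)
  c1 <- c0 <- 0
  for (j in seq_len(m)) {
    w <- exp(-(m - j) / omega)
    if (flags[j] == 1) c1 <- c1 + w else c0 <- c0 + w
  }
  c(c1, c0)
}

## Full brute-force Bayesian trace: at each n, recount the entire history.
brute_bayes_trace <- function(y, statistic, omega) {
  n <- length(y)
  p_obs <- p_next <- conf <- numeric(n)
  for (nn in seq_len(n)) {
    ## --- p_obs from state after y_{1:nn-1}
    if (nn == 1) {
      p_obs[nn] <- 0.5
    } else if (statistic == "IF") {
      cc <- brute_counts(as.numeric(y[1:(nn - 1)] == 1), omega)
      m1 <- beta_mean_or(cc[1] + 1, cc[2] + 1)
      p_obs[nn] <- if (y[nn] == 1) m1 else 1 - m1
    } else if (statistic == "AF") {
      if (nn == 2) {
        p_obs[nn] <- 0.5
      } else {
        alt_hist <- as.numeric(y[2:(nn - 1)] != y[1:(nn - 2)])
        cc <- brute_counts(alt_hist, omega)
        m_alt <- beta_mean_or(cc[1] + 1, cc[2] + 1)
        p_obs[nn] <- if (y[nn] != y[nn - 1]) m_alt else 1 - m_alt
      }
    } else {                                   # TP
      if (nn == 2) {
        p_obs[nn] <- 0.5
      } else {
        from <- y[1:(nn - 2)]; to <- y[2:(nn - 1)]
        m <- length(from)
        a <- b <- 0                            # row = y[nn-1]: to I1 / to I2
        for (j in seq_len(m)) {
          w <- exp(-(m - j) / omega)           # one global transition clock
          if (from[j] == y[nn - 1]) {
            if (to[j] == 1) a <- a + w else b <- b + w
          }
        }
        m1 <- beta_mean_or(a + 1, b + 1)
        p_obs[nn] <- if (y[nn] == 1) m1 else 1 - m1
      }
    }
    ## --- p_next and confidence from state after y_{1:nn}
    if (statistic == "IF") {
      cc <- brute_counts(as.numeric(y[1:nn] == 1), omega)
      p_next[nn] <- beta_mean_or(cc[1] + 1, cc[2] + 1)
      conf[nn] <- -log(beta_sd_or(cc[1] + 1, cc[2] + 1))
    } else if (statistic == "AF") {
      if (nn == 1) {
        cc <- c(0, 0)
      } else {
        cc <- brute_counts(as.numeric(y[2:nn] != y[1:(nn - 1)]), omega)
      }
      m_alt <- beta_mean_or(cc[1] + 1, cc[2] + 1)
      p_next[nn] <- if (y[nn] == 2) m_alt else 1 - m_alt
      conf[nn] <- -log(beta_sd_or(cc[1] + 1, cc[2] + 1))
    } else {
      a <- b <- 0
      if (nn >= 2) {
        from <- y[1:(nn - 1)]; to <- y[2:nn]
        m <- length(from)
        for (j in seq_len(m)) {
          w <- exp(-(m - j) / omega)
          if (from[j] == y[nn]) {
            if (to[j] == 1) a <- a + w else b <- b + w
          }
        }
      }
      p_next[nn] <- beta_mean_or(a + 1, b + 1)
      conf[nn] <- -log(beta_sd_or(a + 1, b + 1))
    }
  }
  list(p_obs = p_obs, p_next = p_next, conf = conf)
}

## Posterior mean/SD of a weighted Beta-Bernoulli likelihood by numerical
## integration of the unnormalized posterior on a fine grid.
grid_posterior_moments <- function(w1, w0, n_grid = 1e4) {
  theta <- (seq_len(n_grid) - 0.5) / n_grid
  logpost <- w1 * log(theta) + w0 * log(1 - theta)   # uniform prior
  post <- exp(logpost - max(logpost))
  post <- post / sum(post)
  m <- sum(theta * post)
  v <- sum((theta - m)^2 * post)
  c(mean = m, sd = sqrt(v))
}
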