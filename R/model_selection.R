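#' Integration time-constant grid for the Bayesian models
#'
#' 102 log-spaced values on `[1, 400]` plus `Inf` (the perfect integrator),
#' 103 values in total.
#'
#' @param n_finite number of finite grid points.
#' @param lo,hi grid range in stimuli.
#' @export
omega_grid <- function(n_finite = 102, lo = 1, hi = 400) {
  c(exp(seq(log(lo), log(hi), length.out = n_finite)), Inf)
}

#' Learning-rate grid for the Rescorla-Wagner models
#'
#' 99 linearly spaced values on `[0.005, 0.95]`.
#'
#' @param n number of grid points.
#' @param lo,hi grid range.
#' @export
alpha_grid <- function(n = 99, lo = 0.005, hi = 0.95) {
  seq(lo, hi, length.out = n)
}

#' Regress probability reports on model predictions
#'
#' Ordinary least squares of the subjective probability report `x_n` on the
#' model's predicted probability `p_n` (one intercept, one slope).
#'
#' @param x probability reports.
#' @param p model predictions, same length.
#' @return list `beta0`, `beta1`, `mse` (mean squared residual), `n`,
#'   `degenerate` (TRUE when the regressor is constant; such fits carry
#'   infinite BIC).
#' @export
fit_ratings <- function(x, p) {
  stopifnot(length(x) == length(p))
  if (length(x) < 3) stop("need at least 3 rating trials")
  vp <- stats::var(p)
  if (!is.finite(vp) || vp == 0) {
    return(list(beta0 = mean(x), beta1 = NA_real_, mse = Inf,
                n = length(x), degenerate = TRUE))
  }
  beta1 <- stats::cov(x, p) / vp
  beta0 <- mean(x) - beta1 * mean(p)
  res <- x - beta0 - beta1 * p
  list(beta0 = beta0, beta1 = beta1, mse = mean(res^2), n = length(x),
       degenerate = FALSE)
}

#' Bayesian information criterion for a rating regression
#'
#' `BIC = N * log(sigma_e^2) + q * log(N)` with `q = 3` (two regression
#' coefficients plus one model-free parameter). Model evidence is
#' approximated as `exp(-BIC / 2)`. A small floor on the MSE keeps
#' noiseless simulations finite.
#'
#' @param mse mean squared residual of the fit.
#' @param n_obs number of rating observations N.
#' @param q number of parameters (default 3).
#' @param mse_floor lower bound applied to `mse` before the log.
#' @export
bic_score <- function(mse, n_obs, q = 3, mse_floor = 1e-10) {
  stopifnot(n_obs >= 1)
  n_obs * log(pmax(mse, mse_floor)) + q * log(n_obs)
}

.MODEL_SET <- data.frame(
  family = rep(c("bayes", "rw"), each = 3),
  statistic = rep(c("IF", "AF", "TP"), 2),
  stringsAsFactors = FALSE
)
.MODEL_SET$label <- sprintf("%s-%s", .MODEL_SET$statistic, .MODEL_SET$family)

#' Fit all six learning models to one participant's ratings over grids
#'
#' For every model the learner is run on each block's sequence across the
#' whole parameter grid at once; predictions at the question trials are
#' pooled across blocks and regressed against the probability reports
#' (confidence reports are never used in fitting). The per-model evidence
#' profile is `-BIC/2` over the grid; the best parameter attains the
#' grid-minimum BIC, and individual model probabilities normalize the six
#' best evidences within the participant.
#'
#' @param ratings tibble with columns `block`, `trial`, `p_report` (pooled
#'   over the participant's blocks).
#' @param sequences named/indexed list of `ps_sequence` (or 1/2 vectors),
#'   one per block id appearing in `ratings$block`.
#' @param omega,alpha parameter grids (defaults [omega_grid()],
#'   [alpha_grid()]).
#' @param models subset of model labels to fit (default all six).
#' @param ... passed to the learner (e.g. `tp_confidence`).
#' @return a `ps_fit`: list with `grid` (tibble per model x grid value:
#'   `beta0`, `beta1`, `mse`, `bic`, `log_evidence`) and `best` (one row per
#'   model: `best_param`, `bic`, `log_evidence`, `model_prob`).
#' @export
grid_fit <- function(ratings, sequences,
                     omega = omega_grid(), alpha = alpha_grid(),
                     models = .MODEL_SET$label, ...) {
  stopifnot(all(c("block", "trial", "p_report") %in% names(ratings)))
  if (length(omega) == 0 && length(alpha) == 0) stop("empty parameter grid")
  blocks <- sort(unique(ratings$block))
  seq_of <- function(b) {
    s <- sequences[[b]]
    if (inherits(s, "ps_sequence")) s$intensities else as.integer(s)
  }
  x <- ratings$p_report
  out <- list()
  for (mi in seq_len(nrow(.MODEL_SET))) {
    fam <- .MODEL_SET$family[mi]; sta <- .MODEL_SET$statistic[mi]
    lab <- .MODEL_SET$label[mi]
    if (!lab %in% models) next
    grid <- if (fam == "bayes") omega else alpha
    if (length(grid) == 0) next
    ## predictions at question trials, pooled over blocks: [n_ratings x P]
    pm <- matrix(NA_real_, nrow(ratings), length(grid))
    for (b in blocks) {
      rows <- which(ratings$block == b)
      cur <- .learner_curves(seq_of(b), fam, sta, grid, ...)
      pm[rows, ] <- cur$p_next[ratings$trial[rows], , drop = FALSE]
    }
    ## vectorized OLS over grid columns
    n <- length(x)
    mx <- mean(x)
    mp <- colMeans(pm)
    cxp <- colMeans(pm * x) - mp * mx
    vp <- colMeans(pm^2) - mp^2
    beta1 <- ifelse(vp > 0, cxp / vp, NA_real_)
    beta0 <- mx - beta1 * mp
    mse <- colMeans((x - matrix(beta0, n, length(grid), byrow = TRUE) -
                       pm * matrix(beta1, n, length(grid), byrow = TRUE))^2)
    mse[!is.finite(beta1)] <- Inf
    bic <- bic_score(mse, n)
    out[[lab]] <- tibble::tibble(
      model = lab, family = fam, statistic = sta, param = grid,
      beta0 = beta0, beta1 = beta1, mse = mse, bic = bic,
      log_evidence = -bic / 2
    )
  }
  grid_tbl <- do.call(rbind, out)
  best <- do.call(rbind, lapply(out, function(g) {
    i <- which.min(g$bic)
    g[i, c("model", "family", "statistic", "param", "bic", "log_evidence")]
  }))
  names(best)[names(best) == "param"] <- "best_param"
  lev <- best$log_evidence
  best$model_prob <- exp(lev - log_sum_exp(lev))
  res <- list(grid = grid_tbl, best = tibble::as_tibble(best),
              n_ratings = length(x))
  class(res) <- "ps_fit"
  res
}

#' @export
print.ps_fit <- function(x, ...) {
  cat(sprintf("<ps_fit> %d models over %d ratings\n",
              nrow(x$best), x$n_ratings))
  print(x$best[order(-x$best$model_prob), ])
  invisible(x)
}

#' Random-effects Bayesian model selection
#'
#' Variational Dirichlet scheme over population model frequencies
#' (Stephan-style random effects): model identity is treated as a random
#' effect across participants, and the posterior Dirichlet over frequencies
#' is estimated by iterating participant-wise model attributions against
#' Dirichlet counts. The exceedance probability of each model — the
#' probability that it is the most frequent in the population — is
#' estimated by Monte-Carlo sampling from the fitted Dirichlet.
#'
#' @param log_evidence numeric matrix `[participants x models]` of log model
#'   evidences (e.g. `-BIC/2`); column names label the models.
#' @param alpha0 prior Dirichlet count per model (default 1, uniform).
#' @param n_samples Monte-Carlo draws for the exceedance probability.
#' @param seed seed for the Monte-Carlo step.
#' @param tol,max_iter convergence controls for the variational loop.
#' @return a `ps_bms`: `alpha` (posterior Dirichlet), `expected_probs`
#'   (posterior mean frequencies, sum to 1), `exceedance` (phi, sums to 1
#'   within Monte-Carlo error), `attribution` (`[participants x models]`
#'   posterior model assignment probabilities).
#' @export
rfx_bms <- function(log_evidence, alpha0 = 1, n_samples = 1e5, seed = 1,
                    tol = 1e-8, max_iter = 500) {
  le <- as.matrix(log_evidence)
  if (any(!is.finite(le))) stop("log evidences must be finite")
  S <- nrow(le); K <- ncol(le)
  if (K == 1L) {
    return(structure(list(alpha = alpha0 + S,
                          expected_probs = stats::setNames(1, colnames(le)),
                          exceedance = stats::setNames(1, colnames(le)),
                          attribution = matrix(1, S, 1,
                                               dimnames = dimnames(le))),
                     class = "ps_bms"))
  }
  alpha <- rep(alpha0, K)
  for (it in seq_len(max_iter)) {
    lw <- sweep(le, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    lw <- lw - apply(lw, 1, max)
    g <- exp(lw)
    g <- g / rowSums(g)
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  expected <- alpha / sum(alpha)
  set.seed(as.integer(seed))
  draws <- matrix(stats::rgamma(n_samples * K, shape = rep(alpha, each = n_samples)),
                  n_samples, K)
  win <- max.col(draws, ties.method = "random")
  phi <- tabulate(win, nbins = K) / n_samples
  nm <- colnames(le)
  structure(
    list(alpha = stats::setNames(alpha, nm),
         expected_probs = stats::setNames(expected, nm),
         exceedance = stats::setNames(phi, nm),
         attribution = g),
    class = "ps_bms"
  )
}

#' @export
print.ps_bms <- function(x, ...) {
  cat("<ps_bms> random-effects model comparison\n")
  print(round(rbind(expected_prob = x$expected_probs,
                    exceedance = x$exceedance), 4))
  invisible(x)
}

#' Bayesian model averaging over the shared model-free parameter
#'
#' Per participant, the posterior over the parameter grid is
#' `p(omega | x) proportional to sum_i exp(-BIC(M_i, omega) / 2)` over the
#' models sharing the grid; the group curve is the mean of the normalized
#' per-participant posteriors, and the reported `omega_star` is its grid
#' argmax.
#'
#' @param bic_array numeric array `[participants x models x grid]` of BIC
#'   values on a shared parameter grid.
#' @param grid the parameter grid (length = `dim(bic_array)[3]`).
#' @return a `ps_bma`: `grid`, `per_participant` (`[participants x grid]`
#'   posteriors), `group` (mean curve), `omega_star`.
#' @export
bma_omega <- function(bic_array, grid) {
  stopifnot(length(dim(bic_array)) == 3, dim(bic_array)[3] == length(grid))
  S <- dim(bic_array)[1]
  post <- matrix(NA_real_, S, length(grid))
  for (s in seq_len(S)) {
    lev <- -bic_array[s, , , drop = TRUE] / 2   # [models x grid]
    if (is.null(dim(lev))) lev <- matrix(lev, nrow = 1)
    bad <- !is.finite(lev)
    if (any(bad)) {
      warning("non-finite evidences excluded from BMA")
      lev[bad] <- -Inf
    }
    lg <- apply(lev, 2, log_sum_exp)            # log sum_i evidence per grid pt
    post[s, ] <- exp(lg - log_sum_exp(lg))
  }
  group <- colMeans(post)
  structure(
    list(grid = grid, per_participant = post, group = group,
         omega_star = grid[which.max(group)]),
    class = "ps_bma"
  )
}

#' @export
print.ps_bma <- function(x, ...) {
  cat(sprintf("<ps_bma> %d participants, %d grid points; omega* = %.3g\n",
              nrow(x$per_participant), length(x$grid), x$omega_star))
  invisible(x)
}

#' Quadratic fit of confidence on probability estimates
#'
#' Least-squares fit `c = a + b * p + d * p^2`; confidence estimates rise
#' for more extreme probability estimates, so the fit is summarized by its
#' coefficient of determination.
#'
#' @param p probability estimates.
#' @param c_values confidence estimates, same length (>= 4 points).
#' @return list `coefficients` (a, b, d) and `r_squared` in `[0, 1]`.
#' @export
quadratic_fit <- function(p, c_values) {
  stopifnot(length(p) == length(c_values))
  if (length(p) < 4) stop("need at least 4 points for a quadratic fit")
  X <- cbind(1, p, p^2)
  if (qr(X)$rank < 3) stop("rank-deficient design (constant or two-valued p)")
  fit <- stats::lm.fit(X, c_values)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((c_values - mean(c_values))^2)
  r2 <- if (ss_tot > 0) max(0, min(1, 1 - ss_res / ss_tot)) else NA_real_
  list(coefficients = stats::setNames(fit$coefficients, c("a", "b", "d")),
       r_squared = r2)
}

#' Rating accuracy: per-participant correlations and group test
#'
#' Accuracy of probability or confidence ratings is the per-participant
#' Pearson correlation between reports and the corresponding model
#' outcomes; the group-level test is a one-sample t-test of the
#' correlations against 0, with Cohen's d = mean(r) / sd(r).
#'
#' @param reports list (one element per participant) of report vectors.
#' @param model_values list of matching model-outcome vectors.
#' @return list `r` (per participant), `t`, `df`, `p_value`, `cohens_d`
#'   (NA with `zero_variance = TRUE` when r is constant across
#'   participants).
#' @export
accuracy_correlations <- function(reports, model_values) {
  stopifnot(length(reports) == length(model_values))
  r <- mapply(function(x, m) stats::cor(x, m), reports, model_values)
  if (length(r) < 2) stop("need at least 2 participants for the group test")
  sr <- stats::sd(r)
  if (sr < 1e-10 * max(1, abs(mean(r)))) {
    return(list(r = r, t = NA_real_, df = length(r) - 1, p_value = NA_real_,
                cohens_d = NA_real_, zero_variance = TRUE))
  }
  tt <- stats::t.test(r, mu = 0)
  list(r = r, t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, cohens_d = mean(r) / sr, zero_variance = FALSE)
}
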