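#' Reject trials by absolute amplitude
#'
#' Drops every trial whose absolute amplitude reaches `threshold_uV` on any
#' channel; trial metadata stays aligned with the retained trials.
#'
#' @param epochs a `ps_epochs`.
#' @param threshold_uV rejection threshold in microvolts (default 80).
#' @return a `ps_epochs` with the offending trials removed.
#' @export
reject_trials <- function(epochs, threshold_uV = 80) {
  stopifnot(inherits(epochs, "ps_epochs"), threshold_uV > 0)
  peak <- apply(abs(epochs$data), 3, max)
  keep <- peak < threshold_uV
  if (!any(keep)) stop("all trials rejected at threshold ", threshold_uV, " uV")
  epochs$data <- epochs$data[, , keep, drop = FALSE]
  epochs$trial_meta <- epochs$trial_meta[keep, , drop = FALSE]
  epochs
}

#' Residual confidence
#'
#' Removes from confidence everything explainable by the predicted
#' probability: OLS of `c` on block-grouped fixed intercepts plus `p`,
#' `p^2`, `log(p)` and `log(1 - p)`; the residuals are the part of
#' confidence not driven by the prediction itself.
#'
#' @param c_values confidence per trial.
#' @param p predicted probability of I1 per trial, strictly in (0, 1).
#' @param block_ids block (testing-condition) label per trial.
#' @return numeric residuals, mean zero within each block.
#' @export
residual_confidence <- function(c_values, p, block_ids) {
  stopifnot(length(c_values) == length(p), length(p) == length(block_ids))
  p <- clamp01(p)
  if (any(p <= .P_EPS) || any(p >= 1 - .P_EPS)) {
    stop("predicted probabilities at 0/1 after clamping")
  }
  X <- stats::model.matrix(~ 0 + factor(block_ids))
  X <- cbind(X, p = p, p2 = p^2, logp = log(p), log1mp = log(1 - p))
  stats::lm.fit(X, c_values)$residuals
}

#' Variance inflation factor between two regressors
#'
#' `VIF = 1 / (1 - R^2)` where `R^2` comes from regressing `x` on `y` with
#' an intercept. Values above 5 flag problematic collinearity.
#'
#' @param x,y numeric vectors, same length; `var(y) > 0` required.
#' @return VIF >= 1 (`Inf` with a warning for perfectly collinear input).
#' @export
vif <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (stats::var(y) == 0) stop("var(y) must be positive")
  r2 <- stats::cor(x, y)^2
  if (isTRUE(all.equal(r2, 1))) {
    warning("perfectly collinear regressors; VIF is infinite")
    return(Inf)
  }
  1 / (1 - r2)
}

#' Build the single-trial regressor table from a learner trace
#'
#' Assembles, per trial, the Bayesian prediction error `pe`, the confidence
#' `conf`, and the residual confidence `resid_conf` (confidence with
#' block-wise intercepts, the predicted probability, its square and its
#' logarithms regressed out).
#'
#' @param trace tibble pooling [run_learner()] traces across blocks, with
#'   columns `block`, `trial`, `intensity`, `p_next`, `confidence`, `pe`.
#' @return tibble `block`, `trial`, `intensity`, `pe`, `conf`, `resid_conf`.
#' @export
build_regressor_table <- function(trace) {
  need <- c("block", "trial", "intensity", "p_next", "confidence", "pe")
  stopifnot(all(need %in% names(trace)))
  tibble::tibble(
    block = trace$block, trial = trace$trial, intensity = trace$intensity,
    pe = trace$pe, conf = trace$confidence,
    resid_conf = residual_confidence(trace$confidence, trace$p_next,
                                     trace$block)
  )
}

#' Single-trial EEG regression maps for one participant
#'
#' Independent OLS of the epoched signal on prediction error and residual
#' confidence at every channel x timepoint, with block fixed intercepts
#' (`z_n = b0_k + b1 * pe_n + b2 * resid_conf_n + noise`), computed across
#' all available trials. Trials are analyzed separately per delivered
#' intensity, given the different component latencies of the cool and hot
#' vertex potentials.
#'
#' @param epochs a `ps_epochs` (after [reject_trials()]).
#' @param regressors tibble aligned with `epochs$trial_meta` (same trial
#'   order) holding `block`, `intensity`, `pe`, `resid_conf`; defaults to
#'   the columns of `epochs$trial_meta`.
#' @return list with one element per intensity (`"I1"`, `"I2"`): numeric
#'   array `[channels x timepoints x 2]` of coefficients, regressor slices
#'   named `pe` and `resid_conf`.
#' @export
trial_regression <- function(epochs, regressors = epochs$trial_meta) {
  stopifnot(inherits(epochs, "ps_epochs"))
  need <- c("block", "intensity", "pe", "resid_conf")
  stopifnot(all(need %in% names(regressors)))
  if (nrow(regressors) != dim(epochs$data)[3]) {
    stop("regressors must align with the surviving trials")
  }
  d <- dim(epochs$data)
  out <- list()
  for (ii in 1:2) {
    idx <- which(regressors$intensity == ii)
    ri <- regressors[idx, , drop = FALSE]
    X <- stats::model.matrix(~ 0 + factor(block), data = ri)
    X <- cbind(X, pe = ri$pe, resid_conf = ri$resid_conf)
    if (length(idx) <= ncol(X)) stop("fewer trials than regression parameters")
    if (stats::var(ri$pe) == 0 || stats::var(ri$resid_conf) == 0) {
      stop("zero-variance regressor")
    }
    ## flatten channels x time into columns: one shared design, one solve
    Z <- t(matrix(epochs$data[, , idx], d[1] * d[2], length(idx)))
    B <- qr.coef(qr(X), Z)
    beta <- array(t(B[c("pe", "resid_conf"), , drop = FALSE]),
                  dim = c(d[1], d[2], 2),
                  dimnames = list(epochs$channel_labels, NULL,
                                  c("pe", "resid_conf")))
    out[[paste0("I", ii)]] <- beta
  }
  out
}

#' Group-level t-maps with FDR correction
#'
#' One-sample two-tailed t-tests against 0 of the per-participant
#' regression coefficients at every channel x timepoint, corrected with
#' Benjamini-Hochberg FDR jointly across the analysis electrodes and all
#' timepoints, separately per regressor. Points where the coefficient is
#' identical and nonzero across participants (zero variance) cannot yield a
#' t-statistic and are flagged as significant-by-convention rather than
#' propagating NaN.
#'
#' @param beta_maps list over participants of arrays
#'   `[channels x timepoints x regressors]` (one intensity at a time; run
#'   once per intensity).
#' @param alpha significance level (default 0.05).
#' @return a `ps_maps`: arrays `beta_mean`, `t`, `p`, `p_fdr`, `mask`
#'   (logical, BH-significant), `flagged` (zero-variance convention), plus
#'   `alpha` and `n_participants`.
#' @export
group_stats <- function(beta_maps, alpha = 0.05) {
  S <- length(beta_maps)
  if (S < 2) stop("need at least 2 participants")
  d <- dim(beta_maps[[1]])
  stacked <- array(unlist(beta_maps), dim = c(d, S))
  mean_b <- rowMeans(stacked, dims = 3)
  centered <- stacked - as.vector(mean_b)   # mean recycles over participants
  sd_b <- sqrt(rowSums(centered^2, dims = 3) / (S - 1))
  t_map <- mean_b / (sd_b / sqrt(S))
  p_map <- 2 * stats::pt(-abs(t_map), df = S - 1)
  flagged <- sd_b == 0 & mean_b != 0
  t_map[sd_b == 0] <- ifelse(mean_b[sd_b == 0] == 0, 0, Inf)
  p_map[sd_b == 0] <- ifelse(mean_b[sd_b == 0] == 0, 1, 0)
  p_fdr <- p_map
  n_reg <- d[3]
  for (r in seq_len(n_reg)) {
    p_fdr[, , r] <- stats::p.adjust(p_map[, , r], method = "BH")
  }
  mask <- p_fdr <= alpha
  dn <- dimnames(beta_maps[[1]])
  dimnames(mean_b) <- dimnames(t_map) <- dimnames(p_map) <-
    dimnames(p_fdr) <- dimnames(mask) <- dn
  structure(
    list(beta_mean = mean_b, t = t_map, p = p_map, p_fdr = p_fdr,
         mask = mask, flagged = flagged, alpha = alpha,
         n_participants = S),
    class = "ps_maps"
  )
}

#' @export
print.ps_maps <- function(x, ...) {
  d <- dim(x$t)
  cat(sprintf(
    "<ps_maps> %d channels x %d timepoints x %d regressors, N = %d, alpha = %g\n",
    d[1], d[2], d[3], x$n_participants, x$alpha))
  for (r in seq_len(d[3])) {
    cat(sprintf("  %s: %d / %d points FDR-significant\n",
                dimnames(x$t)[[3]][r], sum(x$mask[, , r]), d[1] * d[2]))
  }
  invisible(x)
}
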