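#' Default biphasic vertex-potential template parameters
#'
#' The vertex potential is modelled as the sum of a negative (N2) and a
#' positive (P2) Gaussian bump. Component latencies are intensity specific:
#' 205/318 ms after onset for the cool stimulus I1 and 369/518 ms for the
#' hot stimulus I2, with widths and amplitudes (microvolts) typical of
#' central thermal evoked potentials.
#'
#' @return nested list with per-intensity `n2_lat`, `p2_lat` (s), `n2_sd`,
#'   `p2_sd` (s), `n2_amp`, `p2_amp` (uV).
#' @export
erp_template_params <- function() {
  list(
    I1 = list(n2_lat = 0.205, p2_lat = 0.318, n2_sd = 0.030, p2_sd = 0.055,
              n2_amp = -8, p2_amp = 10),
    I2 = list(n2_lat = 0.369, p2_lat = 0.518, n2_sd = 0.040, p2_sd = 0.065,
              n2_amp = -8, p2_amp = 10)
  )
}

#' Evaluate the biphasic ERP template
#'
#' @param times numeric vector of sample times (s, 0 = stimulus onset).
#' @param intensity 1 or 2 (cool / hot).
#' @param params template parameters, see [erp_template_params()].
#' @return numeric template (uV) at `times`.
#' @export
erp_template <- function(times, intensity,
                         params = erp_template_params()) {
  p <- params[[intensity]]
  p$n2_amp * exp(-(times - p$n2_lat)^2 / (2 * p$n2_sd^2)) +
    p$p2_amp * exp(-(times - p$p2_lat)^2 / (2 * p$p2_sd^2))
}

.EEG_CHANNELS <- c("C3", "Cz", "FCz", "CPz", "C4")
## fixed channel gains: vertex electrodes Cz/FCz carry the largest amplitude
.EEG_GAINS <- c(C3 = 0.60, Cz = 1.00, FCz = 0.95, CPz = 0.80, C4 = 0.60)

#' Construct an epoched-EEG container
#'
#' @param data numeric array `[n_channels x n_samples x n_trials]`, uV.
#' @param trial_meta tibble with one row per trial (at least `block`,
#'   `trial`, `intensity`).
#' @param channel_labels channel names (default the five central analysis
#'   electrodes C3, Cz, FCz, CPz, C4).
#' @param sample_rate_hz sampling rate (default 500).
#' @param window_s epoch window `(t_start, t_end)` relative to stimulus
#'   onset (default `c(-0.5, 1.0)`); the closed interval is sampled, so
#'   `n_samples = round((t_end - t_start) * sample_rate_hz) + 1`.
#' @return a `ps_epochs` object.
#' @export
eeg_epochs <- function(data, trial_meta,
                       channel_labels = .EEG_CHANNELS,
                       sample_rate_hz = 500,
                       window_s = c(-0.5, 1.0)) {
  stopifnot(length(dim(data)) == 3)
  n_samples_exp <- round((window_s[2] - window_s[1]) * sample_rate_hz) + 1
  if (dim(data)[2] != n_samples_exp) {
    stop("n_samples must equal round((t_end - t_start) * sample_rate_hz) + 1")
  }
  if (dim(data)[1] != length(channel_labels)) {
    stop("channel_labels length must match dim(data)[1]")
  }
  if (nrow(trial_meta) != dim(data)[3]) {
    stop("trial_meta must have one row per trial")
  }
  times <- window_s[1] + (seq_len(n_samples_exp) - 1) / sample_rate_hz
  dimnames(data) <- list(channel_labels, NULL, NULL)
  structure(
    list(data = data, times = times, channel_labels = channel_labels,
         sample_rate_hz = sample_rate_hz, window_s = window_s,
         trial_meta = tibble::as_tibble(trial_meta)),
    class = "ps_epochs"
  )
}

#' @export
print.ps_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<ps_epochs> %d channels (%s) x %d samples (%.1f..%.1f s @ %g Hz) x %d trials\n",
    d[1], paste(x$channel_labels, collapse = ", "), d[2],
    x$window_s[1], x$window_s[2], x$sample_rate_hz, d[3]))
  invisible(x)
}

#' Simulate vertex-potential epochs modulated by learner outcomes
#'
#' Per trial, the epoch is
#' `block_intercept + (1 + beta_conf * resid_conf + beta_pe * pe) * gain_c *
#' template(intensity) + white noise`, with fixed channel gains peaking at
#' Cz/FCz, so trial-to-trial N2/P2 amplitude is an exact linear function of
#' residual confidence and prediction error in the noiseless case.
#'
#' @param regressors tibble with one row per trial: `block`, `trial`,
#'   `intensity` (1/2), `resid_conf`, `pe` (see [build_regressor_table()]).
#' @param template_params see [erp_template_params()].
#' @param beta_conf,beta_pe modulation weights (fractional amplitude change
#'   per unit regressor).
#' @param noise_sd white-noise SD in uV.
#' @param seed integer seed.
#' @param block_intercept_sd SD (uV) of the per-block DC offset.
#' @param sample_rate_hz,window_s epoch geometry, see [eeg_epochs()].
#' @return a `ps_epochs` object; `trial_meta` carries the regressors.
#' @export
simulate_eeg_epochs <- function(regressors,
                                template_params = erp_template_params(),
                                beta_conf = 0, beta_pe = 0,
                                noise_sd = 5, seed,
                                block_intercept_sd = 2,
                                sample_rate_hz = 500,
                                window_s = c(-0.5, 1.0)) {
  need <- c("block", "trial", "intensity", "resid_conf", "pe")
  if (!all(need %in% names(regressors))) {
    stop("regressors must contain columns: ", paste(need, collapse = ", "))
  }
  set.seed(as.integer(seed))
  n_trials <- nrow(regressors)
  n_samples <- round((window_s[2] - window_s[1]) * sample_rate_hz) + 1
  times <- window_s[1] + (seq_len(n_samples) - 1) / sample_rate_hz
  n_ch <- length(.EEG_CHANNELS)
  templates <- lapply(1:2, function(i) erp_template(times, i, template_params))
  blocks <- sort(unique(regressors$block))
  b0 <- stats::rnorm(length(blocks), 0, block_intercept_sd)
  names(b0) <- as.character(blocks)
  dat <- array(stats::rnorm(n_ch * n_samples * n_trials, 0, noise_sd),
               dim = c(n_ch, n_samples, n_trials))
  for (t in seq_len(n_trials)) {
    scale <- 1 + beta_conf * regressors$resid_conf[t] +
      beta_pe * regressors$pe[t]
    wave <- templates[[regressors$intensity[t]]] * scale
    dat[, , t] <- dat[, , t] + outer(unname(.EEG_GAINS), wave) +
      b0[as.character(regressors$block[t])]
  }
  eeg_epochs(dat, regressors, sample_rate_hz = sample_rate_hz,
             window_s = window_s)
}
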