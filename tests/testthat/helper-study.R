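## Shared fixture builders; everything is generated in code at test time.

## Small analysis grids for recovery tests (grid resolution is an analysis
## choice; the generator itself always uses the study design).
coarse_omega <- function() c(exp(seq(log(1), log(400), length.out = 24)), Inf)
coarse_alpha <- function() seq(0.005, 0.95, length.out = 25)

## Ratings for n_participants simulated raters driven by one generating
## model over the full 10-block design; returns per-participant ratings
## and sequences ready for grid_fit().
simulated_cohort <- function(n_participants, family, statistic, param,
                             noise_sd = 0.05, seed = 1) {
  cfg <- study_config(n_participants = n_participants,
                      generating_model = list(family = family,
                                              statistic = statistic,
                                              param = param),
                      rater_noise_sd = noise_sd, seed = seed)
  simulate_study(cfg, seed = seed)
}

## Per-participant regression beta maps for a small EEG cohort.
eeg_cohort_maps <- function(n_participants = 8, beta_conf = -0.5,
                            beta_pe = 0, noise_sd = 5, seed = 3) {
  cfg <- study_config(
    n_participants = n_participants,
    eeg = list(beta_conf = beta_conf, beta_pe = beta_pe,
               noise_sd = noise_sd, reject_threshold = 80,
               block_intercept_sd = 2))
  st <- simulate_study(cfg, seed = seed)
  maps <- list(I1 = list(), I2 = list())
  for (pt in st$participants) {
    ep <- reject_trials(simulate_participant_epochs(pt, cfg, seed), 80)
    reg <- pt$regressors[match(paste(ep$trial_meta$block, ep$trial_meta$trial),
                               paste(pt$regressors$block,
                                     pt$regressors$trial)), ]
    m <- trial_regression(ep, reg)
    maps$I1[[length(maps$I1) + 1L]] <- m$I1
    maps$I2[[length(maps$I2) + 1L]] <- m$I2
  }
  maps
}

## One tiny noiseless epoch set with known modulation, for exact-recovery
## checks.
toy_epochs <- function(n_trials = 40, beta_conf = -1, beta_pe = 0.5,
                       noise_sd = 0, seed = 11) {
  set.seed(seed)
  reg <- tibble::tibble(
    block = rep(1:2, each = n_trials / 2),
    trial = rep(seq_len(n_trials / 2), 2),
    intensity = rep(rep(1:2, each = n_trials / 4), 2),
    resid_conf = stats::rnorm(n_trials, 0, 0.3),
    pe = stats::runif(n_trials))
  list(epochs = simulate_eeg_epochs(reg, beta_conf = beta_conf,
                                    beta_pe = beta_pe, noise_sd = noise_sd,
                                    seed = seed + 1,
                                    block_intercept_sd = 1),
       reg = reg)
}
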