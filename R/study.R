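.TP_DESIGN <- list(c(0.5, 0.5), c(0.3, 0.7), c(0.7, 0.3),
                   c(0.3, 0.3), c(0.7, 0.7))

#' Study configuration
#'
#' Defaults reproduce the experimental design: 31 participants, 10 testing
#' blocks of 100 stimuli each (two blocks per transition-probability pair,
#' five pairs), ISI 3 s, question trials every 15 +/- 3 stimuli, a Bayesian
#' TP learner with omega = 8 as the generating/report model, rating noise
#' SD 0.05, and the full parameter grids (103 omegas, 99 alphas).
#'
#' @param n_participants cohort size.
#' @param tp_design list of `(p(I1|I2), p(I2|I1))` pairs.
#' @param blocks_per_pair sequences per pair per participant.
#' @param n_stimuli stimuli per sequence.
#' @param isi_seconds interstimulus interval (s).
#' @param question_interval,question_jitter question-trial spacing.
#' @param generating_model list `family`, `statistic`, `param` of the
#'   learner that produces simulated reports and EEG modulation.
#' @param rater_noise_sd Gaussian noise SD on simulated reports.
#' @param omega,alpha analysis parameter grids.
#' @param eeg list: `beta_conf`, `beta_pe` (fractional amplitude modulation
#'   per unit regressor), `noise_sd` (uV), `reject_threshold` (uV),
#'   `block_intercept_sd` (uV).
#' @param alpha_level significance level for group maps.
#' @param seed global seed; expands deterministically into per-participant,
#'   per-block, per-stage streams via [derive_seed()].
#' @return a validated `ps_study_config` list.
#' @export
study_config <- function(n_participants = 31,
                         tp_design = .TP_DESIGN,
                         blocks_per_pair = 2,
                         n_stimuli = 100,
                         isi_seconds = 3,
                         question_interval = 15,
                         question_jitter = 3,
                         generating_model = list(family = "bayes",
                                                 statistic = "TP",
                                                 param = 8),
                         rater_noise_sd = 0.05,
                         omega = omega_grid(),
                         alpha = alpha_grid(),
                         eeg = list(beta_conf = -0.5, beta_pe = 0,
                                    noise_sd = 5, reject_threshold = 80,
                                    block_intercept_sd = 2),
                         alpha_level = 0.05,
                         seed = 1) {
  cfg <- list(n_participants = n_participants, tp_design = tp_design,
              blocks_per_pair = blocks_per_pair, n_stimuli = n_stimuli,
              isi_seconds = isi_seconds,
              question_interval = question_interval,
              question_jitter = question_jitter,
              generating_model = generating_model,
              rater_noise_sd = rater_noise_sd,
              omega = omega, alpha = alpha, eeg = eeg,
              alpha_level = alpha_level, seed = seed)
  validate_study_config(cfg)
  structure(cfg, class = "ps_study_config")
}

validate_study_config <- function(cfg) {
  fail <- function(path, msg) stop("config error at '", path, "': ", msg,
                                   call. = FALSE)
  if (!is.numeric(cfg$n_participants) || cfg$n_participants < 1)
    fail("n_participants", "must be a positive integer")
  if (!is.list(cfg$tp_design) || length(cfg$tp_design) < 1)
    fail("tp_design", "must be a non-empty list of TP pairs")
  for (i in seq_along(cfg$tp_design)) {
    tp <- cfg$tp_design[[i]]
    if (length(tp) != 2 || any(tp <= 0) || any(tp >= 1))
      fail(sprintf("tp_design[%d]", i), "TP pair must lie strictly in (0,1)^2")
  }
  if (cfg$n_stimuli < 1) fail("n_stimuli", "must be >= 1")
  if (cfg$isi_seconds <= 0) fail("isi_seconds", "must be positive")
  if (cfg$question_interval <= cfg$question_jitter ||
      cfg$question_jitter < 0)
    fail("question_interval", "need interval > jitter >= 0")
  gm <- cfg$generating_model
  if (!is.list(gm) || !all(c("family", "statistic", "param") %in% names(gm)))
    fail("generating_model", "needs family, statistic, param")
  if (!gm$family %in% c("bayes", "rw"))
    fail("generating_model.family", "must be 'bayes' or 'rw'")
  if (!gm$statistic %in% c("IF", "AF", "TP"))
    fail("generating_model.statistic", "must be 'IF', 'AF' or 'TP'")
  if (cfg$rater_noise_sd < 0) fail("rater_noise_sd", "must be >= 0")
  if (cfg$alpha_level <= 0 || cfg$alpha_level >= 1)
    fail("alpha_level", "must lie in (0, 1)")
  invisible(cfg)
}

#' Read a study configuration from YAML or JSON
#'
#' Fields present in the file override [study_config()] defaults; unknown
#' fields are reported with their path.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return a `ps_study_config`.
#' @export
read_study_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(study_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("config error at '", unknown[1], "': unknown field", call. = FALSE)
  }
  if (!is.null(raw$tp_design)) {
    if (is.matrix(raw$tp_design)) {
      raw$tp_design <- lapply(seq_len(nrow(raw$tp_design)),
                              function(i) as.numeric(raw$tp_design[i, ]))
    } else if (!is.list(raw$tp_design)) {
      raw$tp_design <- list(as.numeric(raw$tp_design))
    }
  }
  do.call(study_config, raw)
}

#' Simulate a full synthetic study
#'
#' Per participant: a randomized block order containing each TP pair of the
#' design exactly `blocks_per_pair` times, one Markov sequence and question
#' schedule per block, the generating learner's trace, simulated
#' probability/confidence reports at the question trials, the single-trial
#' regressor table (prediction error and residual confidence), and
#' optionally simulated vertex-potential epochs.
#'
#' @param config a [study_config()].
#' @param seed global seed (default `config$seed`).
#' @param eeg also simulate epochs per participant (memory-heavy for large
#'   cohorts; default FALSE — the pipeline's EEG stage streams them).
#' @return a `ps_study`: list with `participants` (each holding
#'   `sequences`, `schedules`, `tp_order`, `trace`, `ratings`,
#'   `regressors`, and optionally `epochs`), `config`, `seed`.
#' @export
simulate_study <- function(config = study_config(), seed = config$seed,
                           eeg = FALSE) {
  stopifnot(inherits(config, "ps_study_config"))
  n_pairs <- length(config$tp_design)
  n_blocks <- n_pairs * config$blocks_per_pair
  gm <- config$generating_model
  spec <- model_spec(gm$family, gm$statistic, gm$param)
  participants <- vector("list", config$n_participants)
  for (p in seq_len(config$n_participants)) {
    set.seed(derive_seed(seed, p, 1))
    tp_order <- sample(rep(seq_len(n_pairs), config$blocks_per_pair))
    sequences <- vector("list", n_blocks)
    schedules <- vector("list", n_blocks)
    traces <- vector("list", n_blocks)
    ratings <- vector("list", n_blocks)
    for (b in seq_len(n_blocks)) {
      sequences[[b]] <- generate_sequence(
        config$tp_design[[tp_order[b]]], config$n_stimuli,
        seed = derive_seed(seed, p, 2, b), block_id = b,
        isi_seconds = config$isi_seconds)
      schedules[[b]] <- schedule_questions(
        config$n_stimuli, config$question_interval, config$question_jitter,
        seed = derive_seed(seed, p, 3, b))
      tr <- run_learner(sequences[[b]], spec)
      tr <- tibble::add_column(tr, block = b, .before = 1)
      traces[[b]] <- tr
      rt <- simulate_rater(sequences[[b]], schedules[[b]], spec,
                           noise_sd = config$rater_noise_sd,
                           seed = derive_seed(seed, p, 4, b), trace = tr)
      ratings[[b]] <- tibble::add_column(rt, block = b, .before = 1)
    }
    trace <- do.call(rbind, traces)
    part <- list(
      id = p, tp_order = tp_order, sequences = sequences,
      schedules = schedules, trace = trace,
      ratings = do.call(rbind, ratings),
      ## regressors need model confidence; RW generators provide none
      regressors = if (!anyNA(trace$confidence))
        build_regressor_table(trace) else NULL
    )
    if (eeg) {
      part$epochs <- simulate_participant_epochs(part, config, seed)
    }
    participants[[p]] <- part
  }
  structure(list(participants = participants, config = config, seed = seed),
            class = "ps_study")
}

#' Simulate one participant's epochs from their regressor table
#'
#' @param participant element of `simulate_study()$participants`.
#' @param config the study config (EEG settings).
#' @param seed the study's global seed.
#' @return a `ps_epochs`.
#' @export
simulate_participant_epochs <- function(participant, config, seed) {
  simulate_eeg_epochs(
    participant$regressors,
    beta_conf = config$eeg$beta_conf, beta_pe = config$eeg$beta_pe,
    noise_sd = config$eeg$noise_sd,
    block_intercept_sd = config$eeg$block_intercept_sd,
    seed = derive_seed(seed, participant$id, 5))
}

#' @export
print.ps_study <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<ps_study> %d participants x %d blocks x %d stimuli (seed %d)\n",
    length(x$participants),
    length(cfg$tp_design) * cfg$blocks_per_pair, cfg$n_stimuli, x$seed))
  invisible(x)
}
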