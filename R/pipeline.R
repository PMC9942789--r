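## Pipeline stages. Each stage reads only the previous stage's files, so the
## full pipeline is the composition of independently runnable steps:
## simulate -> learn -> fit -> eeg -> report.

.msg <- function(...) message(sprintf(...))

write_csv_plain <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
}

#' Simulate stage: write behavioral tables and epoch files
#'
#' Writes `behavior.csv` (tidy: participant, block, trial, intensity,
#' is_question, p_report, conf_report), `ratings.csv` (question trials
#' only), and one `epochs_p<id>.rds` per participant (after amplitude-based
#' trial rejection).
#'
#' @param config a [study_config()].
#' @param out_dir output directory (created if missing).
#' @param seed global seed (default `config$seed`).
#' @param eeg simulate and write epoch files (default TRUE).
#' @return invisibly, the `ps_study` (without epochs attached).
#' @export
stage_simulate <- function(config = study_config(), out_dir,
                           seed = config$seed, eeg = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  study <- simulate_study(config, seed = seed, eeg = FALSE)
  rows <- lapply(study$participants, function(pt) {
    beh <- do.call(rbind, lapply(seq_along(pt$sequences), function(b) {
      y <- pt$sequences[[b]]$intensities
      data.frame(participant = pt$id, block = b,
                 trial = seq_along(y), intensity = y,
                 is_question = seq_along(y) %in% pt$ratings$trial[
                   pt$ratings$block == b])
    }))
    r <- pt$ratings
    beh$p_report <- NA_real_; beh$conf_report <- NA_real_
    key <- match(paste(r$block, r$trial), paste(beh$block, beh$trial))
    beh$p_report[key] <- r$p_report
    beh$conf_report[key] <- r$conf_report
    beh
  })
  beh <- do.call(rbind, rows)
  write_csv_plain(beh, file.path(out_dir, "behavior.csv"))
  write_csv_plain(beh[beh$is_question, ], file.path(out_dir, "ratings.csv"))
  if (eeg) {
    for (pt in study$participants) {
      ep <- simulate_participant_epochs(pt, config, seed)
      ep <- reject_trials(ep, config$eeg$reject_threshold)
      saveRDS(ep, file.path(out_dir, sprintf("epochs_p%02d.rds", pt$id)))
    }
  }
  .msg("simulate: %d participants in %.1fs", length(study$participants),
       as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(study)
}

.read_behavior <- function(out_dir) {
  utils::read.csv(file.path(out_dir, "behavior.csv"))
}

.sequences_from_behavior <- function(beh, participant) {
  bp <- beh[beh$participant == participant, ]
  lapply(sort(unique(bp$block)), function(b) {
    bb <- bp[bp$block == b, ]
    as.integer(bb$intensity[order(bb$trial)])
  })
}

#' Learn stage: learner traces for the report model
#'
#' Reads `behavior.csv`, runs the configured model on every sequence, and
#' writes `traces.csv` (participant, block, trial, model, param, p_next,
#' p_obs, confidence, pe, surprise).
#'
#' @param out_dir directory holding `behavior.csv`; traces are written there.
#' @param spec the learner [model_spec()] (default Bayesian TP, omega = 8).
#' @return invisibly, the traces data frame.
#' @export
stage_learn <- function(out_dir, spec = model_spec("bayes", "TP", 8)) {
  t0 <- Sys.time()
  beh <- .read_behavior(out_dir)
  out <- list()
  for (p in sort(unique(beh$participant))) {
    seqs <- .sequences_from_behavior(beh, p)
    for (b in seq_along(seqs)) {
      tr <- run_learner(seqs[[b]], spec)
      out[[length(out) + 1L]] <- data.frame(
        participant = p, block = b, trial = tr$trial,
        intensity = tr$intensity, model = spec$label,
        param = spec$param, p_next = tr$p_next, p_obs = tr$p_obs,
        confidence = tr$confidence, pe = tr$pe, surprise = tr$surprise)
    }
  }
  traces <- do.call(rbind, out)
  write_csv_plain(traces, file.path(out_dir, "traces.csv"))
  .msg("learn: %d trace rows in %.1fs", nrow(traces),
       as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(traces)
}

#' Fit stage: grid fits, random-effects BMS, and BMA over omega
#'
#' Reads `behavior.csv`/`ratings.csv`, fits all six models per participant
#' over the configured grids, and writes `fits.csv` (best fit per
#' participant x model), `bms.json` (expected model probabilities and
#' exceedance), and `bma_omega.csv` (group posterior over omega).
#'
#' @param out_dir directory holding the simulate-stage files.
#' @param config a [study_config()] (grids; default full grids).
#' @param seed seed for the exceedance Monte-Carlo.
#' @return invisibly, a list `fits`, `bms`, `bma`.
#' @export
stage_fit <- function(out_dir, config = study_config(), seed = config$seed) {
  t0 <- Sys.time()
  beh <- .read_behavior(out_dir)
  pids <- sort(unique(beh$participant))
  fits <- list(); le <- NULL
  bayes_bics <- list()
  for (p in pids) {
    bp <- beh[beh$participant == p & beh$is_question, ]
    ratings <- tibble::tibble(block = bp$block, trial = bp$trial,
                              p_report = bp$p_report)
    fit <- grid_fit(ratings, .sequences_from_behavior(beh, p),
                    omega = config$omega, alpha = config$alpha)
    fits[[as.character(p)]] <- tibble::add_column(fit$best, participant = p,
                                                  .before = 1)
    le <- rbind(le, stats::setNames(fit$best$log_evidence, fit$best$model))
    gb <- fit$grid[fit$grid$family == "bayes", ]
    bayes_bics[[as.character(p)]] <- matrix(
      gb$bic, nrow = 3, byrow = TRUE,
      dimnames = list(unique(gb$model), NULL))
  }
  fits_tbl <- do.call(rbind, fits)
  write_csv_plain(fits_tbl, file.path(out_dir, "fits.csv"))
  bms <- rfx_bms(le, seed = derive_seed(seed, 7))
  jsonlite::write_json(
    list(expected_probs = as.list(bms$expected_probs),
         exceedance = as.list(bms$exceedance)),
    file.path(out_dir, "bms.json"), auto_unbox = TRUE, digits = NA)
  bic_arr <- array(NA_real_, dim = c(length(pids), 3, length(config$omega)))
  for (i in seq_along(pids)) bic_arr[i, , ] <- bayes_bics[[i]]
  bma <- bma_omega(bic_arr, config$omega)
  write_csv_plain(
    data.frame(omega = bma$grid, posterior = bma$group),
    file.path(out_dir, "bma_omega.csv"))
  .msg("fit: %d participants in %.1fs", length(pids),
       as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(list(fits = fits_tbl, bms = bms, bma = bma))
}

#' EEG stage: single-trial regression maps and group statistics
#'
#' Reads the per-participant epoch files and `traces.csv`, builds the
#' prediction-error / residual-confidence regressors, runs the per-
#' participant channel x timepoint regressions separately per intensity,
#' and writes `maps.rds` (group `ps_maps` per intensity) plus
#' `significant.tsv` (FDR-significant time intervals).
#'
#' @param out_dir directory holding epoch files and `traces.csv`.
#' @param alpha_level significance level (default 0.05).
#' @return invisibly, list of `ps_maps` per intensity.
#' @export
stage_eeg <- function(out_dir, alpha_level = 0.05) {
  t0 <- Sys.time()
  traces <- utils::read.csv(file.path(out_dir, "traces.csv"))
  files <- sort(list.files(out_dir, pattern = "^epochs_p[0-9]+\\.rds$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no epoch files found in ", out_dir)
  beta_by_int <- list(I1 = list(), I2 = list())
  times <- NULL; vifs <- c()
  for (f in files) {
    ep <- readRDS(f)
    times <- ep$times
    pid <- as.integer(sub(".*epochs_p([0-9]+)\\.rds$", "\\1", f))
    tp <- traces[traces$participant == pid, ]
    reg <- build_regressor_table(tibble::tibble(
      block = tp$block, trial = tp$trial,
      intensity = .intensity_from_trace(tp), p_next = tp$p_next,
      confidence = tp$confidence, pe = tp$pe))
    ## align regressors with surviving trials
    key_ep <- paste(ep$trial_meta$block, ep$trial_meta$trial)
    reg <- reg[match(key_ep, paste(reg$block, reg$trial)), ]
    for (ii in 1:2) {
      idx <- reg$intensity == ii
      vifs <- c(vifs, vif(reg$resid_conf[idx], reg$pe[idx]))
    }
    maps <- trial_regression(ep, reg)
    beta_by_int$I1[[length(beta_by_int$I1) + 1L]] <- maps$I1
    beta_by_int$I2[[length(beta_by_int$I2) + 1L]] <- maps$I2
  }
  group <- lapply(beta_by_int, group_stats, alpha = alpha_level)
  saveRDS(list(maps = group, times = times, mean_vif = mean(vifs)),
          file.path(out_dir, "maps.rds"))
  sig <- .significant_intervals(group, times)
  utils::write.table(sig, file.path(out_dir, "significant.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  .msg("eeg: %d participants in %.1fs", length(files),
       as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(group)
}

.intensity_from_trace <- function(tp) {
  if ("intensity" %in% names(tp)) return(tp$intensity)
  stop("traces.csv must carry the delivered intensity")
}

.significant_intervals <- function(group, times) {
  rows <- list()
  for (int in names(group)) {
    g <- group[[int]]
    chs <- dimnames(g$mask)[[1]]
    regs <- dimnames(g$mask)[[3]]
    for (r in regs) for (ch in seq_along(chs)) {
      m <- g$mask[ch, , r]
      if (!any(m)) next
      runs <- rle(m)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1
      for (k in which(runs$values)) {
        rows[[length(rows) + 1L]] <- data.frame(
          intensity = int, regressor = r, channel = chs[ch],
          t_start = times[starts[k]], t_end = times[ends[k]])
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(intensity = character(), regressor = character(),
                      channel = character(), t_start = numeric(),
                      t_end = numeric()))
  }
  do.call(rbind, rows)
}

#' Run the full pipeline
#'
#' simulate -> learn -> fit -> eeg, then write `report.json` with the
#' headline quantities: winning model and its exceedance probability,
#' the BMA `omega_star`, the mean per-participant quadratic confidence-
#' probability R^2, the mean VIF of residual confidence against prediction
#' error, and the number of FDR-significant points per regressor and
#' intensity. Identical seeds yield byte-identical outputs.
#'
#' @param config a [study_config()], or a path to a YAML/JSON config file.
#' @param out_dir artifact directory.
#' @param seed global seed (default `config$seed`).
#' @param eeg run the EEG stages (default TRUE).
#' @return invisibly, the report list.
#' @export
run_pipeline <- function(config = study_config(), out_dir,
                         seed = NULL, eeg = TRUE) {
  if (is.character(config)) config <- read_study_config(config)
  stopifnot(inherits(config, "ps_study_config"))
  if (is.null(seed)) seed <- config$seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  study <- stage_simulate(config, out_dir, seed = seed, eeg = eeg)
  gm <- config$generating_model
  stage_learn(out_dir, model_spec(gm$family, gm$statistic, gm$param))
  fit_res <- stage_fit(out_dir, config, seed = seed)
  report <- list(seed = seed, n_participants = config$n_participants)
  win <- names(which.max(fit_res$bms$expected_probs))
  report$winning_model <- win
  report$exceedance <- as.list(fit_res$bms$exceedance)
  report$omega_star <- fit_res$bma$omega_star
  ## quadratic confidence law on the generating model at question trials
  r2 <- vapply(study$participants, function(pt) {
    q <- pt$trace[paste(pt$trace$block, pt$trace$trial) %in%
                    paste(pt$ratings$block, pt$ratings$trial), ]
    quadratic_fit(q$p_next, q$confidence)$r_squared
  }, numeric(1))
  report$mean_quadratic_r2 <- mean(r2)
  report$mean_vif <- mean(vapply(study$participants, function(pt) {
    mean(vapply(1:2, function(ii) {
      idx <- pt$regressors$intensity == ii
      vif(pt$regressors$resid_conf[idx], pt$regressors$pe[idx])
    }, numeric(1)))
  }, numeric(1)))
  if (eeg) {
    group <- stage_eeg(out_dir, config$alpha_level)
    report$n_significant <- lapply(group, function(g) {
      as.list(apply(g$mask, 3, sum))
    })
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
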