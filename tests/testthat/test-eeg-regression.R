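test_that("amplitude-based trial rejection drops exactly the offending trials", {
  meta <- tibble::tibble(block = 1L, trial = 1:5, intensity = 1L)
  dat <- array(0, c(5, 751, 5))
  ep <- eeg_epochs(dat, meta)
  expect_equal(dim(reject_trials(ep, 80)$data)[3], 5)
  dat2 <- dat
  dat2[3, 100, 4] <- 100                  # one 100 uV sample in trial 4
  ep2 <- eeg_epochs(dat2, meta)
  kept <- reject_trials(ep2, 80)
  expect_equal(dim(kept$data)[3], 4)
  expect_identical(kept$trial_meta$trial, c(1:3, 5L))
  noisy <- eeg_epochs(array(stats::rnorm(5 * 751 * 5), c(5, 751, 5)), meta)
  expect_error(reject_trials(noisy, 0.001), "all trials rejected")
})

test_that("residual confidence removes everything in the probability span", {
  set.seed(8)
  p <- stats::runif(200, 0.05, 0.95)
  blocks <- rep(1:4, each = 50)
  ## c within the regressor span: residuals vanish
  c1 <- 2 + 3 * p - p^2
  expect_lt(max(abs(residual_confidence(c1, p, blocks))), 1e-9)
  ## block-constant offsets fully absorbed
  c2 <- c1 + c(0, 5, -3, 2)[blocks]
  r2 <- residual_confidence(c2, p, blocks)
  for (b in 1:4) expect_lt(abs(mean(r2[blocks == b])), 1e-10)
  ## an orthogonal signal survives residualization
  set.seed(9)
  sig <- stats::rnorm(200)
  sig <- stats::lm.fit(cbind(1, p, p^2, log(p), log(1 - p)), sig)$residuals
  r3 <- residual_confidence(c1 + sig, p, blocks)
  expect_gt(stats::cor(r3, sig), 0.99)
  ## near-zero correlation with each projection regressor
  for (reg in list(p, p^2, log(p), log(1 - p))) {
    expect_lt(abs(stats::cor(r3, reg)), 1e-8)
  }
})

test_that("VIF reflects shared variance between regressors", {
  set.seed(10)
  y <- stats::rnorm(500)
  x_orth <- stats::rnorm(500)
  x_orth <- stats::lm.fit(cbind(1, y), x_orth)$residuals
  expect_equal(vif(x_orth, y), 1, tolerance = 1e-10)
  expect_warning(v <- vif(y, y), "collinear")
  expect_identical(v, Inf)
  ## agrees with 1 / (1 - R^2) from an explicit intercept regression
  x_half <- y + stats::rnorm(500, 0, stats::sd(y))
  r2 <- summary(stats::lm(x_half ~ y))$r.squared
  expect_equal(vif(x_half, y), 1 / (1 - r2), tolerance = 1e-12)
  expect_error(vif(y, rep(1, 500)), "positive")
})

test_that("single-trial regression recovers the constructed coefficients exactly", {
  tmp <- toy_epochs(n_trials = 40, beta_conf = -1, beta_pe = 0.5,
                    noise_sd = 0)
  maps <- trial_regression(tmp$epochs, tmp$reg)
  times <- tmp$epochs$times
  gains <- c(C3 = 0.60, Cz = 1.00, FCz = 0.95, CPz = 0.80, C4 = 0.60)
  for (ii in 1:2) {
    tmpl <- erp_template(times, ii)
    ## z = b0_k + gain * T(t) * (1 + bc * rc + bp * pe):
    ## true coefficient maps are gain * T(t) * bc and gain * T(t) * bp
    want_rc <- outer(unname(gains), tmpl) * -1
    want_pe <- outer(unname(gains), tmpl) * 0.5
    got <- maps[[paste0("I", ii)]]
    expect_equal(unname(got[, , "resid_conf"]), want_rc, tolerance = 1e-9)
    expect_equal(unname(got[, , "pe"]), want_pe, tolerance = 1e-9)
  }
  ## zero-variance regressor raises
  bad <- tmp$reg
  bad$pe <- 0.3
  expect_error(trial_regression(tmp$epochs, bad), "zero-variance")
})

test_that("noisy regression recovers coefficients within sampling error", {
  set.seed(12)
  n <- 500
  reg <- tibble::tibble(block = rep(1:5, each = 100), trial = rep(1:100, 5),
                        intensity = rep(rep(1:2, each = 50), 5),
                        resid_conf = stats::rnorm(n, 0, 0.3),
                        pe = stats::runif(n))
  ep <- simulate_eeg_epochs(reg, beta_conf = -0.5, beta_pe = 0.3,
                            noise_sd = 5, seed = 13)
  maps <- trial_regression(ep, reg)
  i_p2 <- which.min(abs(ep$times - 0.318))
  got <- maps$I1["Cz", i_p2, "resid_conf"]
  want <- erp_template(0.318, 1) * -0.5
  ## OLS sampling theory: se ~ noise_sd / (sd(rc) * sqrt(n_I1))
  se <- 5 / (0.3 * sqrt(250))
  expect_lt(abs(got - want), 3 * se)
})

test_that("group maps apply the BH step-up rule and the zero-variance policy", {
  set.seed(14)
  S <- 10
  maps <- replicate(S, array(stats::rnorm(5 * 40 * 2, 0, 1), c(5, 40, 2),
                             dimnames = list(paste0("ch", 1:5), NULL,
                                             c("pe", "resid_conf"))),
                    simplify = FALSE)
  ## plant a strong common effect in a small region of one regressor
  for (s in seq_len(S)) maps[[s]][2, 1:5, 2] <- maps[[s]][2, 1:5, 2] + 4
  g <- group_stats(maps, alpha = 0.05)
  ## independent BH oracle per regressor: step-up on the raw p-values
  for (r in 1:2) {
    pv <- as.vector(g$p[, , r])
    m <- length(pv)
    ord <- order(pv)
    thresh <- 0.05 * seq_len(m) / m
    k <- max(c(0, which(pv[ord] <= thresh)))
    reject <- rep(FALSE, m)
    if (k > 0) reject[ord[seq_len(k)]] <- TRUE
    expect_identical(as.vector(g$mask[, , r]), reject)
  }
  expect_true(all(g$mask[2, 1:5, 2]))
  ## mask implies raw p below the BH threshold; monotone in alpha
  expect_true(all(g$p[g$mask] <= 0.05))
  g_strict <- group_stats(maps, alpha = 0.01)
  expect_true(all(g_strict$mask <= g$mask))
  ## zero-variance identical nonzero betas: flagged, not NaN
  flat <- replicate(4, array(1, c(2, 3, 1),
                             dimnames = list(NULL, NULL, "pe")),
                    simplify = FALSE)
  gf <- group_stats(flat)
  expect_true(all(gf$flagged))
  expect_true(all(gf$mask))
  expect_false(any(is.nan(gf$t)))
  expect_error(group_stats(flat[1]), "at least 2")
})

test_that("BH-FDR keeps the empirical false discovery rate at the nominal level", {
  set.seed(15)
  n_rep <- 200; S <- 12
  fdp <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    maps <- replicate(S, array(stats::rnorm(5 * 151), c(5, 151, 1),
                               dimnames = list(NULL, NULL, "pe")),
                      simplify = FALSE)
    g <- group_stats(maps, alpha = 0.05)
    n_rej <- sum(g$mask)
    fdp[r] <- if (n_rej > 0) 1 else 0    # all rejections are false here
  }
  ## empirical FDR under the global null, within Monte-Carlo error of 0.05
  mc_margin <- 2 * sqrt(0.05 * 0.95 / n_rep)
  expect_lte(mean(fdp), 0.05 + mc_margin)
})

test_that("a negative confidence modulation is recovered end to end, with no false error effect", {
  maps <- eeg_cohort_maps(n_participants = 12, beta_conf = -0.5,
                          beta_pe = 0, noise_sd = 5, seed = 3)
  times <- seq(-0.5, 1, by = 1 / 500)
  lat <- list(I1 = c(n2 = 0.205, p2 = 0.318), I2 = c(n2 = 0.369, p2 = 0.518))
  near <- function(t0) which(abs(times - t0) <= 0.04)
  for (int in c("I1", "I2")) {
    g <- group_stats(maps[[int]], alpha = 0.05)
    ## no prediction-error modulation was generated: none detected
    expect_equal(sum(g$mask[, , "pe"]), 0, label = paste(int, "pe"))
    ## confidence effect: a significant negative vertex cluster at P2
    ## (high confidence shrinks the P2) ...
    w_p2 <- near(lat[[int]]["p2"])
    sig_p2 <- g$mask["Cz", w_p2, "resid_conf"]
    expect_gt(sum(sig_p2), 0, label = paste(int, "P2 cluster"))
    expect_true(all(g$beta_mean["Cz", w_p2, "resid_conf"][sig_p2] < 0))
    ## ... and a significant positive one at N2 (shallower negativity)
    w_n2 <- near(lat[[int]]["n2"])
    sig_n2 <- g$mask["Cz", w_n2, "resid_conf"]
    expect_gt(sum(sig_n2), 0, label = paste(int, "N2 cluster"))
    expect_true(all(g$beta_mean["Cz", w_n2, "resid_conf"][sig_n2] > 0))
    ## effects concentrate around the vertex-potential components; FDR
    ## admits ~5% false discoveries anywhere on the time axis
    sig_t <- times[which(apply(g$mask[, , "resid_conf"], 2, any))]
    frac_in_window <- mean(sig_t > 0.05 & sig_t < lat[[int]]["p2"] + 0.3)
    expect_gt(frac_in_window, 0.8)
  }
})
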