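test_that("rating regression recovers exact linear maps and flags degenerate input", {
  p <- seq(0.1, 0.9, length.out = 20)
  f1 <- fit_ratings(p, p)
  expect_equal(f1$beta0, 0, tolerance = 1e-12)
  expect_equal(f1$beta1, 1, tolerance = 1e-12)
  expect_equal(f1$mse, 0, tolerance = 1e-14)
  f2 <- fit_ratings(0.2 + 0.5 * p, p)
  expect_equal(f2$beta0, 0.2, tolerance = 1e-12)
  expect_equal(f2$beta1, 0.5, tolerance = 1e-12)
  ## independent noise: slope near 0, mse near var(x)
  set.seed(2)
  x <- stats::runif(5000); pr <- stats::runif(5000)
  f3 <- fit_ratings(x, pr)
  expect_lt(abs(f3$beta1), 0.05)
  expect_equal(f3$mse, stats::var(x), tolerance = 0.01)
  ## constant regressor
  f4 <- fit_ratings(x[1:10], rep(0.5, 10))
  expect_true(f4$degenerate)
  expect_identical(bic_score(f4$mse, 10), Inf)
  expect_error(fit_ratings(1:2, 1:2), "at least 3")
})

test_that("BIC follows N log(mse) + q log(N) and orders with MSE at equal q", {
  expect_equal(bic_score(0.04, 10), 10 * log(0.04) + 3 * log(10),
               tolerance = 1e-12)
  expect_lt(bic_score(0.02, 10), bic_score(0.04, 10))
  expect_identical(bic_score(0.3, 25), bic_score(0.3, 25))
  ## floor keeps noiseless fits finite
  expect_true(is.finite(bic_score(0, 10)))
  ## equal-q models: BIC ranking equals MSE ranking
  mses <- c(0.01, 0.003, 0.2, 0.05)
  expect_identical(order(bic_score(mses, 40)), order(mses))
})

test_that("grids match the configured counts and ranges", {
  og <- omega_grid()
  expect_length(og, 103)
  expect_equal(og[1], 1)
  expect_equal(og[102], 400)
  expect_identical(og[103], Inf)
  ag <- alpha_grid()
  expect_length(ag, 99)
  expect_equal(range(ag), c(0.005, 0.95))
})

test_that("grid fitting recovers the generating model per participant", {
  ## TP-bayes generator
  st <- simulated_cohort(1, "bayes", "TP", 8, noise_sd = 0.05, seed = 31)
  pt <- st$participants[[1]]
  fit <- grid_fit(pt$ratings, pt$sequences,
                  omega = coarse_omega(), alpha = coarse_alpha())
  expect_equal(sum(fit$best$model_prob), 1, tolerance = 1e-12)
  expect_identical(fit$best$model[which.max(fit$best$model_prob)], "TP-bayes")
  best_row <- fit$best[fit$best$model == "TP-bayes", ]
  grid_rows <- fit$grid[fit$grid$model == "TP-bayes", ]
  expect_equal(best_row$bic, min(grid_rows$bic))
  ## RW-IF generator
  st2 <- simulated_cohort(1, "rw", "IF", 0.2, noise_sd = 0.05, seed = 32)
  pt2 <- st2$participants[[1]]
  fit2 <- grid_fit(pt2$ratings, pt2$sequences,
                   omega = coarse_omega(), alpha = coarse_alpha())
  expect_identical(fit2$best$model[which.max(fit2$best$model_prob)], "IF-rw")
})

test_that("random-effects BMS behaves under symmetry, dominance and permutation", {
  set.seed(1)
  le_eq <- matrix(rep(stats::rnorm(12), 2), ncol = 2,
                  dimnames = list(NULL, c("A", "B")))
  b <- rfx_bms(le_eq, seed = 5)
  expect_equal(unname(b$expected_probs), c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(unname(b$exceedance), c(0.5, 0.5), tolerance = 0.02)
  expect_equal(sum(b$exceedance), 1, tolerance = 1e-12)

  le_dom <- cbind(A = stats::rnorm(12), B = stats::rnorm(12))
  le_dom[, "A"] <- le_dom[, "B"] + 10      # A dominates by >= e^10 everywhere
  bd <- rfx_bms(le_dom, seed = 6)
  expect_gte(bd$exceedance[["A"]], 0.99)

  perm <- sample(nrow(le_dom))
  bp <- rfx_bms(le_dom[perm, ], seed = 6)
  expect_equal(bp$exceedance, bd$exceedance, tolerance = 1e-12)

  ## single model: exceedance trivially 1
  b1 <- rfx_bms(matrix(stats::rnorm(5), ncol = 1,
                       dimnames = list(NULL, "only")))
  expect_identical(unname(b1$exceedance), 1)
  ## identical duplicated models split probability equally
  le3 <- cbind(A = stats::rnorm(10), B = 0, C = 0)
  le3[, "B"] <- le3[, "A"]; le3[, "C"] <- le3[, "A"] - 8
  b3 <- rfx_bms(le3, seed = 7)
  expect_equal(b3$expected_probs[["A"]], b3$expected_probs[["B"]],
               tolerance = 1e-6)
})

test_that("model recovery: each generator wins the group comparison", {
  gens <- list(c("bayes", "IF"), c("bayes", "AF"), c("bayes", "TP"),
               c("rw", "IF"), c("rw", "AF"), c("rw", "TP"))
  n_per <- 8
  for (gi in seq_along(gens)) {
    fam <- gens[[gi]][1]; sta <- gens[[gi]][2]
    par <- if (fam == "bayes") 8 else 0.2
    st <- simulated_cohort(n_per, fam, sta, par, noise_sd = 0.05,
                           seed = 500 + gi)
    le <- t(vapply(st$participants, function(pt) {
      fit <- grid_fit(pt$ratings, pt$sequences,
                      omega = coarse_omega(), alpha = coarse_alpha())
      stats::setNames(fit$best$log_evidence, fit$best$model)
    }, numeric(6)))
    bms <- rfx_bms(le, seed = 600 + gi)
    win <- names(which.max(bms$expected_probs))
    expect_identical(win, sprintf("%s-%s", sta, fam),
                     label = sprintf("generator %s-%s", sta, fam))
  }
})

test_that("BMA over omega recovers the generating time constant within one grid step", {
  og <- omega_grid()
  for (om_true in c(4, 8, 16)) {
    st <- simulated_cohort(8, "bayes", "TP", om_true, noise_sd = 0.05,
                           seed = 700 + om_true)
    bic_arr <- array(NA_real_, c(8, 3, length(og)))
    for (i in 1:8) {
      pt <- st$participants[[i]]
      fit <- grid_fit(pt$ratings, pt$sequences, omega = og,
                      alpha = numeric(0),
                      models = c("IF-bayes", "AF-bayes", "TP-bayes"))
      gb <- fit$grid
      bic_arr[i, , ] <- matrix(gb$bic, nrow = 3, byrow = TRUE)
    }
    bma <- bma_omega(bic_arr, og)
    k_star <- which(og == bma$omega_star)
    k_true <- which.min(abs(log(og[-103]) - log(om_true)))
    expect_lte(abs(k_star - k_true), 1,
               label = sprintf("omega recovery at %d", om_true))
  }
})

test_that("BMA degenerate cases: point mass and flat evidence", {
  grid <- c(1, 2, 4, 8)
  bic1 <- array(1000, c(1, 2, 4)); bic1[1, , 3] <- 0
  b <- bma_omega(bic1, grid)
  expect_equal(b$omega_star, 4)
  expect_equal(b$group[3], 1, tolerance = 1e-10)
  bic_flat <- array(5, c(2, 2, 4))
  bf <- bma_omega(bic_flat, grid)
  expect_equal(bf$group, rep(0.25, 4), tolerance = 1e-12)
})

test_that("quadratic confidence fits behave at the exact and null extremes", {
  p <- seq(0.05, 0.95, length.out = 30)
  qf <- quadratic_fit(p, 1 - (p - 0.5)^2)
  expect_equal(qf$r_squared, 1, tolerance = 1e-10)
  expect_equal(unname(qf$coefficients), c(0.75, 1, -1), tolerance = 1e-8)
  set.seed(4)
  q0 <- quadratic_fit(p, stats::rnorm(30))
  expect_lt(q0$r_squared, 0.25)
  expect_error(quadratic_fit(p[1:3], p[1:3]), "at least 4")
  expect_error(quadratic_fit(rep(0.5, 10), stats::rnorm(10)), "rank-deficient")
})

test_that("accuracy correlations: identity, null, and zero-variance policy", {
  reports <- replicate(6, stats::runif(40), simplify = FALSE)
  acc <- accuracy_correlations(reports, reports)
  expect_equal(unname(acc$r), rep(1, 6))
  ## independent noise: group t near 0 over many participants
  set.seed(11)
  rep_n <- replicate(60, stats::rnorm(50), simplify = FALSE)
  mod_n <- replicate(60, stats::rnorm(50), simplify = FALSE)
  accn <- accuracy_correlations(rep_n, mod_n)
  expect_lt(abs(accn$t), 2.5)
  ## constant r across participants: Cohen's d undefined, flagged
  x <- stats::runif(30)
  accz <- accuracy_correlations(list(x, x), list(2 * x, 2 * x))
  expect_true(accz$zero_variance)
  expect_true(is.na(accz$cohens_d))
})
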