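test_that("design rows are one-hot over contrast windows with offset always on", {
  blk <- make_targeted_block(n_trials = 8, seed = 3)
  d <- build_design_matrix(blk$rec)
  X <- d$X
  n_win <- d$n_win
  win_cols <- seq_len(2 * n_win)
  on_rows <- d$on_bin
  expect_true(all(rowSums(X[on_rows, win_cols]) == 1))
  expect_true(all(X[!on_rows, "after_stim"] == 1))
  expect_true(all(rowSums(X[!on_rows, win_cols]) == 0))
  expect_true(all(X[, "offset"] == 1))
  # high-contrast presentations activate the high-contrast group only
  hc_rows <- rep(blk$rec$meta$contrast == "high", each = d$Tb) & on_rows
  expect_true(all(rowSums(X[hc_rows, seq_len(n_win)]) == 1))
  expect_true(all(rowSums(X[hc_rows, n_win + seq_len(n_win)]) == 0))
})

test_that("downstream design gains a drift column; modulator column is z-scored", {
  blk <- make_targeted_block(n_trials = 8, seed = 4)
  rec <- blk$rec
  rec$area <- "downstream"
  rec$meta$drift_dir <- rep_len(c("left", "right"), nrow(rec$meta))
  d <- build_design_matrix(rec)
  expect_true("drift_right" %in% colnames(d$X))
  dm <- build_design_matrix(blk$rec, modulator = blk$block$modulator)
  mv <- dm$X[, "modulator"]
  expect_lt(abs(mean(mv)), 1e-10)
  expect_equal(sd(mv), 1, tolerance = 1e-10)
})

test_that("SR fit recovers the MLE in closed-form cases", {
  # offset-only design: MLE of a constant Poisson rate is log(mean)
  set.seed(8)
  k <- rpois(4000, 3.3)
  X <- matrix(1, length(k), 1, dimnames = list(NULL, "offset"))
  beta <- modlabel:::fit_poisson_ridge(X, k, alpha = 0, penalty_mask = 0)
  expect_equal(unname(beta[1]), log(mean(k)), tolerance = 1e-6)
  # large ridge shrinks stimulus coefficients toward 0, offset absorbs mean
  blk <- make_targeted_block(n_trials = 15, seed = 9)
  d <- build_design_matrix(blk$rec)
  f_inf <- fit_sr(blk$rec, d, alpha = 1e7)
  expect_lt(max(abs(f_inf$coef[, colnames(f_inf$coef) != "offset"])), 1e-2)
})

test_that("SR fit recovers the generating log rates", {
  # the offset is collinear with the one-hot groups, so only the fitted
  # log rates (not raw coefficients) are identifiable at alpha = 0
  blk <- make_targeted_block(n_trials = 150, seed = 10, sigma_m = 0)
  d <- build_design_matrix(blk$rec)
  f <- fit_sr(blk$rec, d, alpha = 0)
  bins <- modlabel:::fitting_bins(d)
  X <- d$X[bins, , drop = FALSE]
  truth_lr <- blk$block$sr_coefs %*% t(X)
  fit_lr <- f$coef %*% t(X)
  active <- blk$pop$kind != "inactive"
  rmse <- sqrt(mean((fit_lr[active, ] - truth_lr[active, ])^2))
  expect_lt(rmse, 0.06)          # log-rate units; Poisson noise floor
  expect_lt(rmse / sqrt(mean(truth_lr[active, ]^2)), 0.08)
  expect_true(all(f$pseudo_r2[active] > 0))
})

test_that("pseudo-R2 endpoints and determinism of the SR fit", {
  expect_equal(pseudo_r2(-50, -50, -10), 0)
  expect_equal(pseudo_r2(-10, -50, -10), 1)
  expect_true(is.na(pseudo_r2(-10, -10, -10)))
  blk <- make_targeted_block(n_trials = 10, seed = 12)
  d <- build_design_matrix(blk$rec)
  f1 <- fit_sr(blk$rec, d)
  f2 <- fit_sr(blk$rec, d)
  expect_identical(f1$coef, f2$coef)
})

test_that("SR+modulator improves informative fits and collapses under shuffling", {
  blk <- make_targeted_block(n_trials = 50, seed = 13)
  U2 <- 16
  coup <- rep(c(0.7, 0), each = U2 / 2)
  ds <- simulate_downstream_units(blk$rec, blk$block$modulator,
    tuning = list(base_hz = rep(20, U2)), couplings = coup, seed = 14)
  f <- fit_sr_plus_modulator(ds, blk$block$modulator)
  expect_gt(mean(f$improvement[coup > 0]), mean(f$improvement[coup == 0]) + 0.01)
  # coupled units recover positive modulator coefficients
  expect_true(all(f$coupling[coup > 0] > 0.3))
  # shuffled modulator: improvement collapses toward zero
  set.seed(15)
  shuf <- blk$block$modulator[sample(nrow(blk$block$modulator)), ]
  fs <- fit_sr_plus_modulator(ds, shuf)
  expect_lt(mean(fs$improvement[coup > 0]),
            mean(f$improvement[coup > 0]) / 5)
})
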