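test_that("ideal-observer weights and threshold follow the log-odds of the model", {
  d <- optimal_decoder(c(1, 4), c(4, 1), couplings = c(0, 0), sigma_m = 0,
                       mode = "modulator")
  expect_equal(d$weights, c(log(4), -log(4)))
  expect_equal(d$threshold_fun(0), (4 - 1) + (1 - 4))   # = 0
  # uninformative population: all weights zero
  d0 <- optimal_decoder(c(2, 3), c(2, 3), couplings = c(0, 0), sigma_m = 0,
                        mode = "modulator")
  expect_true(all(d0$weights == 0))
  expect_error(optimal_decoder(c(0, 1), c(2, 1), mode = "modulator"),
               "zero rate")
})

test_that("linear-threshold decision matches exhaustive Bayes on small populations", {
  lam0 <- c(1.5, 3, 2); lam1 <- c(3.5, 1, 2); coup <- c(1, 0.6, 0)
  for (sg in c(0.25, 1)) {
    dec <- optimal_decoder(lam0, lam1, coup, sg, mode = "modulator")
    grid <- as.matrix(expand.grid(0:5, 0:5, 0:5))
    for (m in c(-0.7, 0, 0.9)) {
      mine <- apply(grid, 1, function(k)
        decode(dec, array(k, c(3, 1, 1)), modulator = matrix(m, 1, 1)))
      oracle <- apply(grid, 1, function(k)
        bayes_oracle_decision(k, lam0, lam1, coup, m, sg))
      expect_identical(as.integer(mine), as.integer(oracle))
    }
  }
})

test_that("MG weight magnitudes estimate lambda*c*sigma^2 and signs follow feedback", {
  cfg <- population_sim_config(n_informative = 0, n_uninformative = 2,
                               n_inactive = 0, sigma_m = 0.5,
                               low_contrast_scale = 1, seed = 2)
  cfg$lambda0 <- c(10, 10); cfg$lambda1 <- c(10, 10)
  cfg$couplings <- c(1, 0)
  sim <- simulate_iid_population(cfg, 30000, seed = 3)
  d <- mg_decoder(sim$recording$counts, sim$modulator,
                  sim$recording$meta$stimulus)
  # oracle: E[(1/T) sum m k] = lambda c sigma^2 = 10 * 1 * 0.25 = 2.5
  expect_lt(abs(abs(d$weights[1]) - 2.5), 0.15)
  expect_lt(abs(d$weights[2]), 0.15)
  # modulator identically zero -> all magnitudes zero
  dz <- mg_decoder(sim$recording$counts, sim$modulator * 0,
                   sim$recording$meta$stimulus)
  expect_true(all(dz$weights == 0))
  # sign follows the stimulus preference on labeled data
  x <- make_iid_recording(n_per_stim = 300)
  dm <- mg_decoder(x$sim$recording$counts, x$sim$modulator,
                   x$rec$meta$stimulus)
  pref1 <- x$cfg$lambda1 > x$cfg$lambda0
  inf <- x$cfg$kind == "informative"
  expect_true(all(sign(dm$weights[inf & pref1]) >= 0))
  expect_true(all(sign(dm$weights[inf & !pref1]) <= 0))
})

test_that("SO decoder signs, constant threshold, and chance-level behavior", {
  x <- make_iid_recording(n_per_stim = 200)
  d <- so_decoder(x$cfg$lambda0, x$cfg$lambda1, x$rec$counts,
                  x$rec$meta$stimulus)
  expect_true(all(d$weights %in% c(-1, 1)))
  expect_equal(unname(d$weights[x$cfg$lambda1 > x$cfg$lambda0]),
               rep(1, sum(x$cfg$lambda1 > x$cfg$lambda0)))
  # all-uninformative population decodes at chance
  cfg0 <- population_sim_config(n_informative = 0, n_uninformative = 20,
                                n_inactive = 0, sigma_m = 0.3, seed = 9)
  s0 <- simulate_iid_population(cfg0, 600, seed = 10)
  tr <- 1:600; te <- 601:1200
  d0 <- so_decoder(cfg0$lambda0, cfg0$lambda1,
                   s0$recording$counts[, tr, , drop = FALSE],
                   s0$recording$meta$stimulus[tr])
  acc <- decoder_accuracy(d0, s0$recording$counts[, te, , drop = FALSE],
                          s0$recording$meta$stimulus[te])
  expect_lt(abs(acc - 0.5), 0.06)
})

test_that("decisions are invariant to positive rescaling of weights and threshold", {
  x <- make_iid_recording(n_per_stim = 50)
  d <- so_decoder(x$cfg$lambda0, x$cfg$lambda1, x$rec$counts,
                  x$rec$meta$stimulus)
  d2 <- d; d2$weights <- 7 * d$weights; d2$threshold <- 7 * d$threshold
  expect_identical(decode(d, x$rec$counts), decode(d2, x$rec$counts))
})

test_that("constant threshold lands mid-interval and baselines separate separable data", {
  scores <- c(1, 2, 3, 10, 11, 12)
  labels <- c(0, 0, 0, 1, 1, 1)
  expect_equal(modlabel:::fit_constant_threshold(scores, labels), 6.5)
  counts <- array(0L, c(2, 6, 1))
  counts[1, , 1] <- c(9:11, 0:2); counts[2, , 1] <- c(0:2, 9:11)
  lab <- c(0, 0, 0, 1, 1, 1)
  for (kind in c("logistic", "svm")) {
    d <- suppressWarnings(baseline_decoder(counts, lab, kind))
    expect_equal(decode(d, counts), lab, info = kind)
  }
  expect_error(baseline_decoder(counts, rep(0, 6), "logistic"), "both classes")
})

test_that("logistic regression approaches ideal-observer accuracy with ample data", {
  cfg <- population_sim_config(n_informative = 6, n_uninformative = 10,
                               n_inactive = 20, sigma_m = 0.4, seed = 20)
  sim <- simulate_iid_population(cfg, 4000, seed = 21)
  P <- dim(sim$recording$counts)[2]
  tr <- 1:6000; te <- setdiff(seq_len(P), tr)
  lab <- sim$recording$meta$stimulus
  dl <- baseline_decoder(sim$recording$counts[, tr, , drop = FALSE], lab[tr],
                         "logistic")
  dopt <- optimal_decoder(cfg$lambda0, cfg$lambda1, cfg$couplings, cfg$sigma_m,
                          mode = "modulator")
  acc_l <- decoder_accuracy(dl, sim$recording$counts[, te, , drop = FALSE], lab[te])
  acc_o <- decoder_accuracy(dopt, sim$recording$counts[, te, , drop = FALSE],
                            lab[te], modulator = sim$modulator[te, , drop = FALSE])
  expect_gt(acc_l, acc_o - 0.03)
})

test_that("MG learns from less data than logistic regression when the modulator is fast", {
  # the MG advantage comes from estimating couplings at the modulator's
  # (bin) time scale rather than the trial time scale
  cfg <- population_sim_config(n_informative = 8, n_uninformative = 40,
                               n_inactive = 150, seed = 30)
  cfg$sigma_m <- iid_sigma_for_strength(cfg, 1)
  sim <- simulate_iid_population(cfg, 700, modulator_timescale = "bin",
                                 seed = 31)
  counts <- sim$recording$counts
  lab <- sim$recording$meta$stimulus
  contrast <- sim$recording$meta$contrast
  mod <- sim$modulator
  factory_mg <- function(tr) mg_decoder(counts[, tr, , drop = FALSE],
                                        mod[tr, , drop = FALSE], lab[tr])
  factory_lr <- function(tr) suppressWarnings(
    baseline_decoder(counts[, tr, , drop = FALSE], lab[tr], "logistic"))
  tc_mg <- evaluate_training_curve(factory_mg, counts, lab, contrast,
                                   grid = c(4, 16, 64, 256), n_resample = 16,
                                   seed = 32)
  tc_lr <- evaluate_training_curve(factory_lr, counts, lab, contrast,
                                   grid = c(4, 16, 64, 256), n_resample = 16,
                                   seed = 32)
  # with minimal training (4 presentations) MG is ahead of regression
  expect_gt(tc_mg$mean_acc[1], tc_lr$mean_acc[1])
  # MG weights are more stable between minimal and maximal training
  expect_gt(tc_mg$weight_agreement, tc_lr$weight_agreement)
})
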