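test_that("mean correction leaves the mean rate at lambda", {
  # oracle: E[exp(c m)] = exp(c^2 sigma^2 / 2), cancelled by the correction
  cfg <- population_sim_config(n_informative = 1, n_uninformative = 0,
                               n_inactive = 0, sigma_m = 0.5,
                               low_contrast_scale = 1, seed = 1)
  cfg$lambda0[] <- 10; cfg$lambda1[] <- 10; cfg$couplings[] <- 1
  sim <- simulate_iid_population(cfg, 40000, seed = 2)
  m <- mean(sim$recording$counts)
  expect_lt(abs(m - 10) / 10, 0.02)
  # without modulation, plain Poisson with Fano ~ 1
  cfg0 <- cfg; cfg0$couplings[] <- 0
  sim0 <- simulate_iid_population(cfg0, 5000, seed = 3)
  summed <- apply(sim0$recording$counts, c(1, 2), sum)
  expect_lt(abs(var(as.numeric(summed)) / mean(summed) - 1), 0.1)
})

test_that("coupling corruption clips at zero and degrades rank order", {
  cc <- c(0, 0.2, 0.5, 1, 1.5, 2, 3)
  expect_identical(corrupt_couplings(cc, 0), cc)
  expect_true(all(corrupt_couplings(rep(0, 100), 1, seed = 4) >= 0))
  rho <- sapply(1:50, function(s) {
    c(lo = cor(cc, corrupt_couplings(cc, 0.1, seed = s), method = "spearman"),
      hi = cor(cc, corrupt_couplings(cc, 2, seed = s), method = "spearman"))
  })
  expect_gt(mean(rho["lo", ]), mean(rho["hi", ]))
})

test_that("multiunits conserve total spike count and pair rates add", {
  x <- make_iid_recording(n_per_stim = 200)
  mu <- simulate_multiunits(x$rec, seed = 9)
  expect_equal(dim(mu$counts)[1], dim(x$rec$counts)[1] / 2)
  expect_identical(sum(mu$counts), sum(x$rec$counts))
  # summed unit mean ~ sum of pair means
  expect_equal(mean(mu$counts) * dim(mu$counts)[1],
               mean(x$rec$counts) * dim(x$rec$counts)[1], tolerance = 1e-12)
})

test_that("AR(1) block: latent restarts per trial with the configured time scale", {
  blk <- make_targeted_block(n_trials = 120, seed = 21,
                             ar_coef = exp(-50 / 75))
  m <- as.vector(t(blk$block$modulator))
  Tb <- dim(blk$rec$counts)[3]
  trial <- rep(blk$rec$meta$trial, each = Tb)
  # lag-k autocorrelation within trials
  ac <- sapply(1:3, function(L) {
    xs <- ys <- c()
    for (tr in unique(trial)) {
      mm <- m[trial == tr]
      xs <- c(xs, mm[seq_len(length(mm) - L)])
      ys <- c(ys, mm[-seq_len(L)])
    }
    cor(xs, ys)
  })
  tau_hat <- -1 / log(ac[1])            # bins; 75 ms at 50 ms bins = 1.5
  expect_gt(tau_hat, 1.5 * 0.75)
  expect_lt(tau_hat, 1.5 * 1.25)
  # stationary variance matches sigma_m^2
  expect_lt(abs(var(m) - 0.6^2) / 0.36, 0.15)
})

test_that("simulation is deterministic under a fixed seed", {
  a <- make_targeted_block(n_trials = 10, seed = 31)
  b <- make_targeted_block(n_trials = 10, seed = 31)
  expect_identical(a$rec$counts, b$rec$counts)
  expect_identical(a$block$modulator, b$block$modulator)
  c2 <- make_targeted_block(n_trials = 10, seed = 32)
  expect_false(identical(a$rec$counts, c2$rec$counts))
})

test_that("configured relative modulator strength matches the strength metric", {
  cfg <- population_sim_config(seed = 6)
  for (s in c(0.25, 1, 2)) {
    sig <- iid_sigma_for_strength(cfg, s)
    expect_equal(iid_relative_strength(cfg, sig), s, tolerance = 1e-10)
  }
})

test_that("downstream units inherit modulation with the configured lag", {
  blk <- make_targeted_block(n_trials = 60, seed = 41)
  U2 <- 12
  coup <- rep(c(0.8, 0), each = U2 / 2)
  ds <- simulate_downstream_units(blk$rec, blk$block$modulator,
    tuning = list(base_hz = rep(25, U2)), couplings = coup,
    lag_bins = 2, seed = 42)
  expect_s3_class(ds, "population_recording")
  expect_identical(ds$area, "downstream")
  # modulated downstream units are supra-Poisson, unmodulated are not
  ff <- fano_factor(ds$counts, ds$meta, seq_len(ds$bins_on))
  expect_gt(mean(ff[coup > 0]), mean(ff[coup == 0]) + 0.3)
  # lagged modulator: counts of coupled units correlate more with the
  # lagged than the instantaneous modulator
  Tb <- dim(ds$counts)[3]
  m <- as.vector(t(blk$block$modulator))
  ksum <- colSums(matrix(aperm(ds$counts[coup > 0, , , drop = FALSE], c(1, 3, 2)),
                         sum(coup > 0)))
  trial <- rep(ds$meta$trial, each = Tb)
  lag_shift <- function(v, L) {
    out <- v
    for (tr in unique(trial)) {
      idx <- which(trial == tr)
      out[idx] <- c(rep(v[idx[1]], L), v[idx[seq_len(length(idx) - L)]])
    }
    out
  }
  expect_gt(cor(ksum, lag_shift(m, 2)), cor(ksum, m))
})
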