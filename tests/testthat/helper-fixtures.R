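# shared fixtures, all generated in code

# small AR(1) block with a targeted modulator, V1-like
make_targeted_block <- function(n_trials = 30, seed = 7, sigma_m = 0.6,
                                ar_coef = 0.5) {
  pc <- population_sim_config(n_informative = 8, n_uninformative = 14,
                              n_inactive = 2, sigma_m = sigma_m,
                              modulator_law = "ar1", ar_coef = ar_coef,
                              bins_off = 4, uninformative_ratio = c(1, 1.25),
                              seed = seed)
  bl <- simulate_ar1_block(pc, block_sim_config(n_trials = n_trials),
                           seed = seed + 1)
  list(pop = pc, block = bl, rec = bl$recording)
}

# tiny iid recording for I/O and decoding tests
make_iid_recording <- function(n_per_stim = 50, seed = 3, ...) {
  cfg <- population_sim_config(n_informative = 4, n_uninformative = 6,
                               n_inactive = 10, sigma_m = 0.5, seed = seed, ...)
  sim <- simulate_iid_population(cfg, n_per_stim, seed = seed + 1)
  list(cfg = cfg, sim = sim, rec = sim$recording)
}

# exhaustive Bayes decision for the modulated-Poisson pair model: decide
# s = 1 iff log P(k | s=1, m) >= log P(k | s=0, m)
bayes_oracle_decision <- function(k, lambda0, lambda1, couplings, m, sigma_m,
                                  mean_correction = TRUE) {
  corr <- if (mean_correction) exp(-sigma_m^2 * couplings^2 / 2) else 1
  gain <- corr * exp(couplings * m)
  r1 <- lambda1 * gain
  r0 <- lambda0 * gain
  llr <- sum(k * log(r1) - r1) - sum(k * log(r0) - r0)
  as.integer(llr >= 0)
}
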