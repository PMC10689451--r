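#' Configuration for a modulated-Poisson population
#'
#' Defines the generative population used throughout: a small informative
#' subpopulation whose firing rates differ between the two task stimuli, a
#' larger uninformative-but-active group, and many near-silent units. A
#' shared one-dimensional stochastic modulator scales all rates through the
#' exponential link, coupled to each unit with strength
#' `c_n = coupling_scale * |log lambda_n(1) - log lambda_n(0)|`, so the
#' coupling magnitude labels task-informativeness by construction.
#'
#' Rates are stored per bin (`bin_ms` wide). Informative units draw a base
#' rate uniformly from `active_rate_hz` and a stimulus log-ratio uniformly
#' from `informative_ratio`, with preferred stimulus alternating across
#' units; uninformative units respond equally to both stimuli; inactive
#' units sit at `inactive_rate_hz` for both (hence coupling 0).
#'
#' @param n_informative,n_uninformative,n_inactive subpopulation sizes.
#' @param sigma_m modulator standard deviation (stationary SD for the AR(1)
#'   law).
#' @param coupling_scale proportionality constant between coupling and the
#'   log rate ratio (default 1, the definition used by the theory).
#' @param modulator_law `"iid-gaussian"` or `"ar1"`.
#' @param ar_coef AR(1) coefficient `A` (|A| < 1); default `exp(-50/75)`,
#'   a 75 ms time constant at 50 ms bins.
#' @param bins_on,bins_off stimulus-on and inter-stimulus bins per
#'   presentation.
#' @param bin_ms bin width in ms.
#' @param mean_correction divide modulated rates by `exp(sigma_m^2 c^2 / 2)`
#'   so the modulator changes variability but not mean rate (default TRUE).
#' @param active_rate_hz range of base rates for active units (Hz).
#' @param informative_ratio range of rate ratios between preferred and
#'   non-preferred stimulus for informative units.
#' @param uninformative_ratio range of rate ratios for "uninformative"
#'   units. The default `c(1, 1)` makes them exactly uninformative (the
#'   discrete-group theory setting); block simulations emulating recordings
#'   use a narrow range just above 1 to reproduce the graded continuum of
#'   informativeness seen in data.
#' @param inactive_rate_hz rate of inactive units (Hz).
#' @param low_contrast_scale multiplicative rate scaling at low contrast.
#' @param target_only if TRUE (block simulations) the stimulus-1 rate
#'   difference applies only to target presentations.
#' @param seed RNG seed used to draw the per-unit rate table.
#' @return A `population_sim_config`.
#' @export
population_sim_config <- function(n_informative = 10, n_uninformative = 40,
                                  n_inactive = 150, sigma_m = 0.5,
                                  coupling_scale = 1,
                                  modulator_law = c("iid-gaussian", "ar1"),
                                  ar_coef = exp(-50 / 75),
                                  bins_on = 4, bins_off = 0, bin_ms = 50,
                                  mean_correction = TRUE,
                                  active_rate_hz = c(10, 40),
                                  informative_ratio = c(1.5, 3.5),
                                  uninformative_ratio = c(1, 1),
                                  inactive_rate_hz = 1,
                                  low_contrast_scale = 0.5,
                                  target_only = FALSE, seed = 1) {
  modulator_law <- match.arg(modulator_law)
  if (sigma_m < 0) stop("sigma_m must be >= 0")
  if (modulator_law == "ar1" && abs(ar_coef) >= 1)
    stop("AR(1) coefficient must satisfy |A| < 1")
  set.seed(seed)
  N <- n_informative + n_uninformative + n_inactive
  bin_s <- bin_ms / 1000
  kind <- rep(c("informative", "uninformative", "inactive"),
              c(n_informative, n_uninformative, n_inactive))

  base <- stats::runif(N, active_rate_hz[1], active_rate_hz[2]) * bin_s
  base[kind == "inactive"] <- inactive_rate_hz * bin_s
  ratio <- stats::runif(N, informative_ratio[1], informative_ratio[2])
  # alternate preferred stimulus across informative units
  pref1 <- rep_len(c(TRUE, FALSE), N)
  lambda0 <- base
  lambda1 <- base
  inf_idx <- which(kind == "informative")
  lambda0[inf_idx] <- ifelse(pref1[inf_idx],
                             base[inf_idx] / sqrt(ratio[inf_idx]),
                             base[inf_idx] * sqrt(ratio[inf_idx]))
  lambda1[inf_idx] <- ifelse(pref1[inf_idx],
                             base[inf_idx] * sqrt(ratio[inf_idx]),
                             base[inf_idx] / sqrt(ratio[inf_idx]))
  uni_idx <- which(kind == "uninformative")
  if (length(uni_idx) > 0 && any(uninformative_ratio != 1)) {
    ur <- stats::runif(length(uni_idx), uninformative_ratio[1], uninformative_ratio[2])
    lambda0[uni_idx] <- ifelse(pref1[uni_idx],
                               base[uni_idx] / sqrt(ur), base[uni_idx] * sqrt(ur))
    lambda1[uni_idx] <- ifelse(pref1[uni_idx],
                               base[uni_idx] * sqrt(ur), base[uni_idx] / sqrt(ur))
  }
  if (any(lambda0 <= 0) || any(lambda1 <= 0)) stop("rates must be positive")
  couplings <- coupling_scale * abs(log(lambda1) - log(lambda0))

  structure(list(n_units = N, kind = kind,
                 lambda0 = lambda0, lambda1 = lambda1,
                 couplings = couplings, coupling_scale = coupling_scale,
                 sigma_m = sigma_m, modulator_law = modulator_law,
                 ar_coef = ar_coef, bins_on = as.integer(bins_on),
                 bins_off = as.integer(bins_off), bin_ms = bin_ms,
                 mean_correction = mean_correction,
                 low_contrast_scale = low_contrast_scale,
                 target_only = target_only, seed = seed),
            class = "population_sim_config")
}

#' Relative modulator strength implied by a population configuration
#'
#' Uses the same definition as [modulator_summaries()]: modulator variance
#' times the coupling norm, divided by the stimulus drive
#' `sum_{n,i} Var(s_i B_{n,i})`. For the i.i.d. population the stimulus
#' design is an offset plus a target indicator, so the drive reduces to
#' `0.25 * sum_n (log lambda_n(1) - log lambda_n(0))^2` over balanced
#' presentations.
#'
#' @param cfg a `population_sim_config`.
#' @param sigma_m optional modulator SD overriding `cfg$sigma_m`.
#' @return Scalar relative strength.
#' @export
iid_relative_strength <- function(cfg, sigma_m = cfg$sigma_m) {
  delta <- log(cfg$lambda1) - log(cfg$lambda0)
  drive <- 0.25 * sum(delta^2)
  if (drive == 0) return(Inf)
  sigma_m^2 * sqrt(sum(cfg$couplings^2)) / drive
}

#' Modulator SD achieving a target relative strength
#'
#' Inverse of [iid_relative_strength()].
#'
#' @param cfg a `population_sim_config`.
#' @param strength target relative modulator strength (>= 0).
#' @return `sigma_m` giving the requested strength.
#' @export
iid_sigma_for_strength <- function(cfg, strength) {
  delta <- log(cfg$lambda1) - log(cfg$lambda0)
  drive <- 0.25 * sum(delta^2)
  norm_c <- sqrt(sum(cfg$couplings^2))
  if (norm_c == 0) {
    if (strength > 0) stop("population has zero couplings; only strength 0 is attainable")
    return(0)
  }
  sqrt(strength * drive / norm_c)
}

# modulated Poisson rate for one stimulus: lambda * exp(c m - correction)
modulated_rate <- function(lambda, couplings, m, sigma_m, mean_correction) {
  corr <- if (mean_correction) exp(-sigma_m^2 * couplings^2 / 2) else 1
  lambda * corr * exp(outer(couplings, m))
}

#' Simulate an i.i.d.-modulator population
#'
#' Generates balanced presentations of the two task stimuli at high and low
#' contrast from the static modulated-Poisson model: counts are Poisson with
#' rate `lambda_n(s) * exp(c_n m - sigma_m^2 c_n^2 / 2)` (the correction
#' applied when `cfg$mean_correction` is on). By default the modulator takes
#' one draw per stimulus presentation (the same time scale as the stimulus);
#' with `modulator_timescale = "bin"` it is redrawn every 50 ms bin.
#'
#' @param cfg a `population_sim_config` with `modulator_law = "iid-gaussian"`.
#' @param n_per_stim presentations per stimulus identity.
#' @param modulator_timescale `"presentation"` or `"bin"`.
#' @param seed RNG seed.
#' @return List with `recording` (a [population_recording()]) and
#'   `modulator` (P x T_b matrix of modulator values per bin).
#' @export
simulate_iid_population <- function(cfg, n_per_stim,
                                    modulator_timescale = c("presentation", "bin"),
                                    seed = 1) {
  stopifnot(inherits(cfg, "population_sim_config"))
  if (cfg$modulator_law != "iid-gaussian")
    stop("cfg$modulator_law must be 'iid-gaussian' for simulate_iid_population")
  modulator_timescale <- match.arg(modulator_timescale)
  set.seed(seed)
  Tb <- cfg$bins_on
  P <- 2L * n_per_stim
  # balanced, interleaved: stimulus alternates, contrast alternates in pairs
  stim <- rep_len(c(0L, 1L), P)
  contrast <- rep_len(c("high", "high", "low", "low"), P)
  if (modulator_timescale == "presentation") {
    m_pres <- stats::rnorm(P, 0, cfg$sigma_m)
    modulator <- matrix(m_pres, P, Tb)
  } else {
    modulator <- matrix(stats::rnorm(P * Tb, 0, cfg$sigma_m), P, Tb)
  }
  cscale <- ifelse(contrast == "low", cfg$low_contrast_scale, 1)
  N <- cfg$n_units
  lam <- outer(cfg$lambda0, cscale)                       # N x P
  lam[, stim == 1L] <- outer(cfg$lambda1, cscale)[, stim == 1L]
  corr <- if (cfg$mean_correction) exp(-cfg$sigma_m^2 * cfg$couplings^2 / 2) else 1
  m_flat <- as.vector(t(modulator))                       # P*Tb, bin-minor
  log_rate <- log(lam * corr)[, rep(seq_len(P), each = Tb)] +
    outer(cfg$couplings, m_flat)
  counts_flat <- matrix(stats::rpois(length(log_rate), exp(log_rate)), N)
  counts <- aperm(array(as.integer(counts_flat), c(N, Tb, P)), c(1, 3, 2))
  meta <- data.frame(block = 1L, trial = seq_len(P), repeat_index = 1L,
                     contrast = contrast, stimulus = stim,
                     outcome = "hit", stringsAsFactors = FALSE)
  rec <- population_recording(counts, meta, bin_ms = cfg$bin_ms,
                              bins_on = Tb, area = "primary")
  list(recording = rec, modulator = modulator)
}

#' Corrupt modulator couplings with Gaussian noise
#'
#' Adds i.i.d. Gaussian noise to a coupling vector and clips at zero
#' (couplings act as gain-exponent magnitudes, so negative values are
#' meaningless).
#'
#' @param couplings non-negative coupling vector.
#' @param noise_sd noise standard deviation (>= 0).
#' @param seed RNG seed.
#' @return Corrupted, non-negative coupling vector.
#' @export
corrupt_couplings <- function(couplings, noise_sd, seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (noise_sd == 0) return(couplings)
  set.seed(seed)
  pmax(couplings + stats::rnorm(length(couplings), 0, noise_sd), 0)
}

#' Merge units into simulated multiunits
#'
#' Emulates multiunit contamination by summing the binned activity of
#' disjoint random pairs of units. Total spike count is conserved exactly.
#'
#' @param rec a `population_recording` (even number of units; with an odd
#'   number one unit is dropped at random, with a message).
#' @param seed RNG seed for the pairing.
#' @return A `population_recording` with `U/2` units.
#' @export
simulate_multiunits <- function(rec, seed = 1) {
  stopifnot(inherits(rec, "population_recording"))
  U <- dim(rec$counts)[1]
  if (U < 2) stop("need at least 2 units to form multiunits")
  set.seed(seed)
  idx <- sample.int(U)
  if (U %% 2 == 1) {
    message(sprintf("odd number of units; dropping unit %s", rec$unit_ids[idx[U]]))
    idx <- idx[-U]
  }
  first <- idx[seq(1, length(idx), by = 2)]
  second <- idx[seq(2, length(idx), by = 2)]
  counts <- rec$counts[first, , , drop = FALSE] + rec$counts[second, , , drop = FALSE]
  out <- rec
  out$counts <- counts
  out$unit_ids <- paste(rec$unit_ids[first], rec$unit_ids[second], sep = "+")
  out
}

#' Configuration of a simulated task block
#'
#' @param n_trials trials in the block.
#' @param repeat_geom_p geometric parameter of the number of repeated
#'   stimulus-0 presentations before the target (truncated to
#'   `repeat_range`).
#' @param repeat_range inclusive truncation bounds for repeats.
#' @param hit_slope,hit_offset logistic model of the hit probability as a
#'   function of the z-scored pooled informative-unit response to the
#'   target.
#' @param seed RNG seed.
#' @return A `block_sim_config`.
#' @export
block_sim_config <- function(n_trials = 60, repeat_geom_p = 0.25,
                             repeat_range = c(2, 12),
                             hit_slope = 1.5, hit_offset = 1.0, seed = 1) {
  structure(list(n_trials = n_trials, repeat_geom_p = repeat_geom_p,
                 repeat_range = repeat_range, hit_slope = hit_slope,
                 hit_offset = hit_offset, seed = seed),
            class = "block_sim_config")
}

# truncated-geometric repeats before target
draw_repeats <- function(n, p, range) {
  lo <- range[1]; hi <- range[2]
  out <- integer(0)
  while (length(out) < n) {
    k <- lo + stats::rgeom(2 * n + 20, p)
    out <- c(out, k[k <= hi])
  }
  out[seq_len(n)]
}

#' Simulate a block of trials with an AR(1) modulator
#'
#' Generates a full experimental block: each trial is a run of repeated
#' stimulus-0 presentations ending in one target presentation, with 200 ms
#' on-windows and inter-stimulus off-bins. Counts follow
#' `Poisson(exp(C m_t + B s_t))` where `s_t` is the stimulus-response design
#' row of the bin and the latent modulator follows
#' `m_{t+1} = A m_t + eps, eps ~ N(0, Q)` with stationary variance
#' `sigma_m^2`, restarting from the stationary distribution at each trial.
#' Informative units additionally shift their log rate by the per-unit
#' target contrast `delta_n = log lambda_n(1) - log lambda_n(0)` during
#' target presentations (the stimulus-identity change is not part of the SR
#' design, mirroring the task where orientation never changes within the
#' repeats). Behavioral outcomes are drawn from a logistic model of the
#' pooled informative-unit target response.
#'
#' @param pop_cfg a `population_sim_config` with `modulator_law = "ar1"`.
#' @param block_cfg a [block_sim_config()].
#' @param sr_coefs optional per-unit SR coefficient matrix (units x design
#'   columns, V1 design); defaults to [default_sr_coefs()].
#' @param seed RNG seed.
#' @return List with `recording`, `modulator` (P x T_b matrix) and
#'   `sr_coefs` (the generating coefficients).
#' @export
simulate_ar1_block <- function(pop_cfg, block_cfg = block_sim_config(),
                               sr_coefs = NULL, seed = 1) {
  stopifnot(inherits(pop_cfg, "population_sim_config"))
  if (pop_cfg$modulator_law != "ar1")
    stop("pop_cfg$modulator_law must be 'ar1' for simulate_ar1_block")
  A <- pop_cfg$ar_coef
  if (abs(A) >= 1) stop("AR(1) coefficient must satisfy |A| < 1")
  set.seed(seed)
  Tb <- pop_cfg$bins_on + pop_cfg$bins_off
  N <- pop_cfg$n_units

  n_tr <- block_cfg$n_trials
  reps <- draw_repeats(n_tr, block_cfg$repeat_geom_p, block_cfg$repeat_range)
  pres_per_trial <- reps + 1L
  P <- sum(pres_per_trial)

  contrast <- sample(c("high", "low"), P, replace = TRUE)
  trial_id <- rep(seq_len(n_tr), pres_per_trial)
  repeat_index <- unlist(lapply(pres_per_trial, seq_len))
  stim <- as.integer(unlist(lapply(pres_per_trial, function(k) c(rep(0L, k - 1L), 1L))))

  if (is.null(sr_coefs)) sr_coefs <- default_sr_coefs(pop_cfg)
  design <- block_design_rows(contrast, Tb, pop_cfg$bins_on)  # (P*Tb) x ncol

  # AR(1) modulator, independent across trials, stationary variance sigma_m^2
  sig2 <- pop_cfg$sigma_m^2
  Q <- (1 - A^2) * sig2
  m <- numeric(P * Tb)
  bin_trial <- rep(trial_id, each = Tb)
  for (tr in seq_len(n_tr)) {
    idx <- which(bin_trial == tr)
    Ttr <- length(idx)
    mm <- numeric(Ttr)
    mm[1] <- stats::rnorm(1, 0, sqrt(sig2))
    if (Ttr > 1) {
      eps <- stats::rnorm(Ttr - 1, 0, sqrt(Q))
      for (t in 2:Ttr) mm[t] <- A * mm[t - 1] + eps[t - 1]
    }
    m[idx] <- mm
  }

  # log-rate: B s_t + C m_t (+ target shift on target on-bins)
  log_rate <- sr_coefs %*% t(design)              # N x (P*Tb)
  log_rate <- log_rate + outer(pop_cfg$couplings, m)
  delta <- log(pop_cfg$lambda1) - log(pop_cfg$lambda0)
  on_bin <- rep(rep(c(TRUE, FALSE), c(pop_cfg$bins_on, pop_cfg$bins_off)), P)
  target_bin <- rep(stim == 1L, each = Tb) & on_bin
  log_rate[, target_bin] <- log_rate[, target_bin] + delta

  counts_flat <- matrix(stats::rpois(length(log_rate), exp(log_rate)), N)
  # columns are presentation-major, bin-minor: reshape to units x pres x bins
  counts <- aperm(array(as.integer(counts_flat), c(N, Tb, P)), c(1, 3, 2))

  # behavioral outcome from pooled informative-unit target response
  inf_idx <- which(pop_cfg$kind == "informative")
  tgt_pres <- which(stim == 1L)
  pooled <- vapply(tgt_pres, function(p)
    sum(counts[inf_idx, p, seq_len(pop_cfg$bins_on)]), numeric(1))
  z <- if (stats::sd(pooled) > 0) (pooled - mean(pooled)) / stats::sd(pooled) else pooled * 0
  p_hit <- stats::plogis(block_cfg$hit_offset + block_cfg$hit_slope * z)
  hit <- stats::rbinom(length(tgt_pres), 1, p_hit) == 1
  outcome_trial <- ifelse(hit, "hit", "miss")
  outcome <- outcome_trial[trial_id]

  meta <- data.frame(block = 1L, trial = trial_id, repeat_index = repeat_index,
                     contrast = contrast, stimulus = stim, outcome = outcome,
                     stringsAsFactors = FALSE)
  rec <- population_recording(counts, meta, bin_ms = pop_cfg$bin_ms,
                              bins_on = pop_cfg$bins_on, area = "primary")
  list(recording = rec,
       modulator = matrix(m, nrow = P, ncol = Tb, byrow = TRUE),
       sr_coefs = sr_coefs)
}

#' Default stimulus-response coefficients for a simulated block
#'
#' Builds per-unit SR coefficients on the V1 design (contrast-specific
#' one-hot time windows, after-stimulus dimension, offset): the offset is
#' the unit's log spontaneous rate, on-windows carry a decaying transient
#' relative to baseline, low contrast scales rates by
#' `cfg$low_contrast_scale`, and the after-stimulus dimension relaxes back
#' to baseline.
#'
#' @param cfg a `population_sim_config`.
#' @param spont_frac spontaneous rate as a fraction of the stimulus-0 rate.
#' @param transient per-window log-gain profile of the stimulus transient.
#' @return Matrix units x design columns matching [build_design_matrix()].
#' @export
default_sr_coefs <- function(cfg, spont_frac = 0.4,
                             transient = c(1.25, 1.0, 0.85, 0.75)) {
  n_win <- cfg$bins_on
  tr <- rep_len(transient, n_win)
  base_on <- log(cfg$lambda0)          # stimulus-0 per-bin log rate
  offset <- log(pmax(cfg$lambda0 * spont_frac, 1e-4))
  B <- matrix(0, cfg$n_units, 2 * n_win + 2)
  for (w in seq_len(n_win)) {
    gain <- log(tr[w])
    B[, w] <- base_on + gain - offset                     # high contrast
    B[, n_win + w] <- base_on + gain + log(cfg$low_contrast_scale) - offset
  }
  B[, 2 * n_win + 1] <- 0               # after-stimulus: back to baseline
  B <- cbind(B[, seq_len(2 * n_win + 1)], offset)
  colnames(B) <- v1_design_names(n_win)
  B
}

#' Simulate a downstream population inheriting the primary modulator
#'
#' Downstream (MT-like) units are Poisson with a tuning-defined rate
#' multiplicatively gated by the primary-area modulator:
#' `Poisson(tuning * exp(c_n m_{t - lag}))`. Units with coupling 0 are
#' modulator-independent. The lag is applied within trials (feedforward
#' delay in bins); the first `lag` bins of each trial reuse the trial's
#' initial modulator value.
#'
#' @param primary_rec the primary-area `population_recording` defining the
#'   presentation/bin grid and metadata.
#' @param modulator P x T_b matrix of primary modulator values.
#' @param tuning list with `base_hz` (per-unit rate, Hz), optional
#'   `target_delta` (log-rate shift on target on-bins), optional
#'   `drift_gain` (log-rate shift when drift direction is "right"), and
#'   optional `spont_frac` (off-bin rate fraction, default 0.4).
#' @param couplings inherited coupling vector (length = number of
#'   downstream units).
#' @param lag_bins non-negative integer feedforward delay.
#' @param seed RNG seed.
#' @return A `population_recording` with `area = "downstream"` and a
#'   `drift_dir` metadata column.
#' @export
simulate_downstream_units <- function(primary_rec, modulator, tuning, couplings,
                                      lag_bins = 0, seed = 1) {
  stopifnot(inherits(primary_rec, "population_recording"))
  P <- dim(primary_rec$counts)[2]; Tb <- dim(primary_rec$counts)[3]
  if (!all(dim(modulator) == c(P, Tb)))
    stop("modulator must be a P x T_b matrix aligned to the recording")
  if (lag_bins < 0) stop("lag_bins must be >= 0")
  set.seed(seed)
  U <- length(tuning$base_hz)
  if (length(couplings) != U) stop("couplings length must match tuning")
  bin_s <- primary_rec$bin_ms / 1000
  spont_frac <- if (is.null(tuning$spont_frac)) 0.4 else tuning$spont_frac
  target_delta <- if (is.null(tuning$target_delta)) rep(0, U) else tuning$target_delta
  drift_gain <- if (is.null(tuning$drift_gain)) rep(0, U) else tuning$drift_gain

  meta <- primary_rec$meta
  if (is.null(meta$drift_dir))
    meta$drift_dir <- sample(c("left", "right"), P, replace = TRUE)

  # lag the modulator within each trial
  m_flat <- as.vector(t(modulator))            # time-ordered, P*Tb
  bin_trial <- rep(paste(meta$block, meta$trial), each = Tb)
  m_lag <- m_flat
  if (lag_bins > 0) {
    for (tr in unique(bin_trial)) {
      idx <- which(bin_trial == tr)
      if (lag_bins >= length(idx))
        stop("lag_bins exceeds trial length in bins")
      src <- c(rep(idx[1], lag_bins), idx[seq_len(length(idx) - lag_bins)])
      m_lag[idx] <- m_flat[src]
    }
  }

  on_bin <- rep(rep(c(TRUE, FALSE), c(primary_rec$bins_on, Tb - primary_rec$bins_on)), P)
  target_bin <- rep(meta$stimulus == 1L, each = Tb) & on_bin
  right_bin <- rep(meta$drift_dir == "right", each = Tb) & on_bin

  base_bin <- tuning$base_hz * bin_s
  log_rate <- matrix(log(base_bin), U, P * Tb)
  log_rate[, !on_bin] <- log(pmax(base_bin * spont_frac, 1e-4))
  log_rate[, target_bin] <- log_rate[, target_bin] + target_delta
  log_rate[, right_bin] <- log_rate[, right_bin] + drift_gain
  log_rate <- log_rate + outer(couplings, m_lag)

  counts_flat <- matrix(stats::rpois(length(log_rate), exp(log_rate)), U)
  counts <- aperm(array(as.integer(counts_flat), c(U, Tb, P)), c(1, 3, 2))
  population_recording(counts, meta, bin_ms = primary_rec$bin_ms,
                       bins_on = primary_rec$bins_on, area = "downstream")
}
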