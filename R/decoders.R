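# Linear-threshold decoder suite: ideal observer, modulator-guided (MG),
# sign-only (SO), and regression baselines, plus the evaluation protocol.
#
# All decoders share one decision form: sum_n a_n k_n > q, with either a
# constant threshold fitted on training data or (ideal observer) a
# modulator-dependent threshold q(m_t). Counts are summed over the 200 ms
# decoding window before thresholding; the modulator-dependent rule sums
# the per-50 ms-bin log-odds contributions a'k_t - q(m_t) over the window
# (bins are conditionally independent, so this is the exact window
# decision; ties decide s = 1).

new_decoder <- function(weights, threshold, type,
                        threshold_fun = NULL) {
  structure(list(weights = weights, threshold = threshold,
                 threshold_fun = threshold_fun, type = type),
            class = "linear_threshold_decoder")
}

#' @export
print.linear_threshold_decoder <- function(x, ...) {
  cat(sprintf("<linear_threshold_decoder> %s: %d weights (%d nonzero), %s threshold\n",
              x$type, length(x$weights), sum(x$weights != 0),
              if (is.null(x$threshold_fun)) sprintf("constant %.3g", x$threshold)
              else "modulator-dependent"))
  invisible(x)
}

# best constant threshold on training scores; ties over an interval of
# optimal cut points resolve to the interval midpoint
fit_constant_threshold <- function(scores, labels) {
  u <- sort(unique(scores))
  cands <- if (length(u) > 1) {
    c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  } else c(u - 1, u + 1)
  acc <- vapply(cands, function(q) mean((scores >= q) == (labels == 1)),
                numeric(1))
  best <- which(acc == max(acc))
  mean(range(cands[best]))
}

# presentation scores: weights applied to window-summed counts
decoder_scores <- function(weights, counts, window_bins = NULL) {
  Tb <- dim(counts)[3]
  if (is.null(window_bins)) window_bins <- seq_len(Tb)
  summed <- apply(counts[, , window_bins, drop = FALSE], c(1, 2), sum)
  drop(crossprod(summed, weights))
}

#' Decode stimulus identity for a set of presentations
#'
#' @param decoder a `linear_threshold_decoder`.
#' @param counts U x P x T_b count array.
#' @param modulator P x T_b modulator matrix (required for a
#'   modulator-dependent threshold; per-bin log-odds contributions are
#'   summed over the window, ties deciding s = 1).
#' @param window_bins bins of the decoding window (default all).
#' @return Integer vector of decisions (0/1) per presentation.
#' @export
decode <- function(decoder, counts, modulator = NULL, window_bins = NULL) {
  if (!is.null(decoder$threshold_fun)) {
    if (is.null(modulator))
      stop("modulator-dependent threshold requires a modulator trace")
    Tb <- dim(counts)[3]
    if (is.null(window_bins)) window_bins <- seq_len(Tb)
    P <- dim(counts)[2]
    # per-bin log-odds contributions are additive over the window
    dec <- integer(P)
    for (p in seq_len(P)) {
      llr <- sum(vapply(window_bins, function(t)
        sum(decoder$weights * counts[, p, t]) -
          decoder$threshold_fun(modulator[p, t]), numeric(1)))
      dec[p] <- as.integer(llr >= 0)
    }
    dec
  } else {
    scores <- decoder_scores(decoder$weights, counts, window_bins)
    as.integer(scores >= decoder$threshold)
  }
}

#' Ideal-observer decoder for the modulated-Poisson population
#'
#' Weights are the log rate ratios `a_n = log lambda_n(1) - log lambda_n(0)`
#' (zero for units with equal rates). In `"modulator"` mode the threshold is
#' modulator-dependent,
#' `q(m) = sum_n gain_n(m) (lambda_n(1) - lambda_n(0))` with
#' `gain_n(m) = exp(c_n m - sigma_m^2 c_n^2 / 2)` when mean correction is
#' on — the exact log-odds threshold of the generative model. In
#' `"constant"` mode a single threshold is fitted on training data.
#'
#' @param lambda0,lambda1 per-unit, per-bin rates for the two stimuli.
#' @param couplings modulator couplings (modulator mode).
#' @param sigma_m modulator SD (for the mean-correction term).
#' @param mean_correction whether the population is mean-corrected.
#' @param mode `"modulator"` or `"constant"`.
#' @param train_scores,train_labels training scores/labels for constant
#'   mode (scores of window-summed counts under the optimal weights).
#' @return A `linear_threshold_decoder`.
#' @export
optimal_decoder <- function(lambda0, lambda1, couplings = NULL, sigma_m = 0,
                            mean_correction = TRUE,
                            mode = c("modulator", "constant"),
                            train_scores = NULL, train_labels = NULL) {
  mode <- match.arg(mode)
  informative <- lambda0 != lambda1
  bad <- informative & (lambda0 <= 0 | lambda1 <= 0)
  if (any(bad))
    stop(sprintf("zero rate in weighted unit(s): %s",
                 paste(which(bad), collapse = ", ")))
  a <- ifelse(informative, log(lambda1) - log(lambda0), 0)
  if (mode == "modulator") {
    if (is.null(couplings)) couplings <- rep(0, length(a))
    corr <- if (mean_correction) sigma_m^2 * couplings^2 / 2 else 0
    diff <- lambda1 - lambda0
    qfun <- function(m) sum(exp(couplings * m - corr) * diff)
    new_decoder(a, NA_real_, "optimal", threshold_fun = qfun)
  } else {
    if (is.null(train_scores) || is.null(train_labels))
      stop("constant mode requires training scores and labels")
    q <- fit_constant_threshold(train_scores, train_labels)
    new_decoder(a, q, "optimal")
  }
}

#' Modulator-guided (MG) decoder
#'
#' Weight magnitudes are the temporal correlation of each unit's binned
#' activity with the modulator, `|a_n| = (1/T) sum_t m_t k_{n,t}` over
#' 50 ms bins, clipped at zero; signs come from trial feedback (mean
#' response to s = 1 minus s = 0 on labeled training presentations; zero
#' differences get +1). The threshold is constant, fitted on training data.
#'
#' @param counts U x P x T_b training count array.
#' @param modulator P x T_b modulator values for the training bins.
#' @param labels stimulus identity (0/1) of the training presentations.
#' @param window_bins decoding-window bins for the threshold fit.
#' @return A `linear_threshold_decoder`.
#' @export
mg_decoder <- function(counts, modulator, labels, window_bins = NULL) {
  if (!any(labels == 0) || !any(labels == 1))
    stop("sign estimation needs labeled presentations of both stimuli")
  U <- dim(counts)[1]
  K <- matrix(aperm(counts, c(1, 3, 2)), U)      # U x (P*Tb)
  m <- as.vector(t(modulator))
  mag <- pmax(drop(K %*% m) / length(m), 0)
  mean1 <- apply(counts[, labels == 1, , drop = FALSE], 1, mean)
  mean0 <- apply(counts[, labels == 0, , drop = FALSE], 1, mean)
  sgn <- ifelse(mean1 - mean0 >= 0, 1, -1)
  a <- sgn * mag
  scores <- decoder_scores(a, counts, window_bins)
  q <- fit_constant_threshold(scores, labels)
  new_decoder(a, q, "MG")
}

#' Sign-only (SO) decoder
#'
#' Compares the summed responses of the preferred and anti-preferred
#' subpopulations: weights are `sign(lambda_n(1) - lambda_n(0))` in
#' {-1, +1} (zero differences assigned +1). The threshold is constant,
#' fitted on training data.
#'
#' @param lambda0,lambda1 per-unit mean responses to the two stimuli (true
#'   rates or training-data estimates).
#' @param counts,labels training data for the threshold fit.
#' @param window_bins decoding-window bins.
#' @return A `linear_threshold_decoder`.
#' @export
so_decoder <- function(lambda0, lambda1, counts, labels, window_bins = NULL) {
  a <- ifelse(lambda1 - lambda0 >= 0, 1, -1)
  scores <- decoder_scores(a, counts, window_bins)
  q <- fit_constant_threshold(scores, labels)
  new_decoder(a, q, "SO")
}

#' Regression baseline decoders
#'
#' `"logistic"`: L2-penalized logistic regression (total penalty strength 1)
#' on per-presentation window-summed counts. `"svm"`: linear-kernel
#' support-vector machine at default regularization. Both are returned in
#' the common linear-threshold form.
#'
#' @param counts U x P x T_b training count array.
#' @param labels stimulus identity (0/1).
#' @param kind `"logistic"` or `"svm"`.
#' @param window_bins decoding-window bins.
#' @return A `linear_threshold_decoder`.
#' @export
baseline_decoder <- function(counts, labels, kind = c("logistic", "svm"),
                             window_bins = NULL) {
  kind <- match.arg(kind)
  if (length(unique(labels)) < 2)
    stop("training data must contain both classes")
  Tb <- dim(counts)[3]
  if (is.null(window_bins)) window_bins <- seq_len(Tb)
  Xs <- t(apply(counts[, , window_bins, drop = FALSE], c(1, 2), sum))  # P x U
  if (kind == "logistic") {
    n <- nrow(Xs)
    fit <- glmnet::glmnet(Xs, factor(labels), family = "binomial",
                          alpha = 0, lambda = 1 / n, standardize = FALSE)
    w <- as.numeric(fit$beta)
    b <- as.numeric(fit$a0)
    new_decoder(w, -b, "logistic")
  } else {
    fit <- e1071::svm(Xs, factor(labels), kernel = "linear", scale = FALSE)
    w <- drop(t(fit$coefs) %*% fit$SV)
    # e1071 labels the first factor level +1 internally; orient to s = 1
    if (fit$labels[1] == which(levels(factor(labels)) == "1")) {
      w <- -w; rho <- -fit$rho
    } else rho <- fit$rho
    new_decoder(-w, -rho, "svm")
  }
}

#' Accuracy of a decoder on labeled presentations
#'
#' @param decoder a `linear_threshold_decoder`.
#' @param counts,labels evaluation data.
#' @param modulator modulator trace (modulator-dependent thresholds).
#' @param window_bins decoding-window bins.
#' @return Fraction of correct decisions.
#' @export
decoder_accuracy <- function(decoder, counts, labels, modulator = NULL,
                             window_bins = NULL) {
  mean(decode(decoder, counts, modulator, window_bins) == labels)
}

# balanced sample of n training presentations (n/4 per stimulus x contrast
# cell, as available)
balanced_sample <- function(labels, contrast, n, pool) {
  cells <- split(pool, list(labels[pool], contrast[pool]))
  per <- max(1, floor(n / length(cells)))
  idx <- unlist(lapply(cells, function(ix)
    sample(ix, min(per, length(ix)))))
  if (length(idx) > n) idx <- sample(idx, n)
  idx
}

#' Accuracy as a function of training-set size
#'
#' Trains a decoder on balanced subsamples of increasing size (minimum 4:
#' one presentation per stimulus-contrast pair) and evaluates on a fixed
#' held-out test set, resampling the training subset at each size. Records
#' the minimal size whose mean accuracy exceeds chance (one-sided test of
#' proportion at 0.05) and the correlation between the weights learned at
#' minimal and maximal training.
#'
#' @param factory function(train_idx) returning a fitted
#'   `linear_threshold_decoder`.
#' @param counts,labels,contrast the full data set.
#' @param grid training sizes (default 4, 8, 16, ... up to the pool).
#' @param n_resample resamples per size (default 20).
#' @param test_frac fraction of presentations held out for testing.
#' @param modulator optional modulator for the test decisions.
#' @param seed RNG seed.
#' @return A `training_curve` list: `grid`, `accuracy` (size x resample),
#'   `mean_acc`, `se_acc`, `min_size_above_chance`, `weight_agreement`,
#'   `minimal_accuracy`.
#' @export
evaluate_training_curve <- function(factory, counts, labels, contrast,
                                    grid = NULL, n_resample = 20,
                                    test_frac = 0.3, modulator = NULL,
                                    seed = 1) {
  set.seed(seed)
  P <- dim(counts)[2]
  test_idx <- sort(sample.int(P, round(test_frac * P)))
  pool <- setdiff(seq_len(P), test_idx)
  if (is.null(grid)) {
    grid <- 4 * 2^(0:10)
    grid <- grid[grid <= length(pool)]
  }
  if (max(grid) > length(pool)) {
    warning("training grid exceeds available data; truncating")
    grid <- grid[grid <= length(pool)]
  }
  acc <- matrix(NA_real_, length(grid), n_resample)
  w_min <- w_max <- NULL
  for (i in seq_along(grid)) {
    for (r in seq_len(n_resample)) {
      tr <- balanced_sample(labels, contrast, grid[i], pool)
      dec <- factory(tr)
      acc[i, r] <- decoder_accuracy(dec,
        counts[, test_idx, , drop = FALSE], labels[test_idx],
        modulator = if (is.null(modulator)) NULL else modulator[test_idx, , drop = FALSE])
      if (r == 1 && i == 1) w_min <- dec$weights
      if (r == 1 && i == length(grid)) w_max <- dec$weights
    }
  }
  mean_acc <- rowMeans(acc)
  se_acc <- apply(acc, 1, stats::sd) / sqrt(n_resample)
  n_test <- length(test_idx)
  above <- vapply(seq_along(grid), function(i) {
    k <- round(mean_acc[i] * n_test)
    stats::binom.test(k, n_test, p = 0.5, alternative = "greater")$p.value < 0.05
  }, logical(1))
  min_size <- if (any(above)) grid[which(above)[1]] else NA_integer_
  wa <- if (stats::sd(w_min) > 0 && stats::sd(w_max) > 0)
    stats::cor(w_min, w_max) else NA_real_
  structure(list(grid = grid, accuracy = acc, mean_acc = mean_acc,
                 se_acc = se_acc, min_size_above_chance = min_size,
                 weight_agreement = wa, minimal_accuracy = mean_acc[1]),
            class = "training_curve")
}

#' Decoder accuracy as a function of relative modulator strength
#'
#' Simulates i.i.d.-modulator populations over a grid of relative modulator
#' strengths and evaluates the ideal-observer, MG and SO decoders, with
#' optional coupling corruption or multiunit variants.
#'
#' @param base_cfg a `population_sim_config` (iid-gaussian law); its
#'   `sigma_m` is overridden per grid point via [iid_sigma_for_strength()].
#' @param strength_grid relative-strength grid (should include 0).
#' @param n_train,n_test training/test presentations per stimulus.
#' @param n_seeds independent simulations per grid point.
#' @param decoders subset of c("optimal", "mg", "so", "logistic").
#' @param variant `"none"`, `"corrupted"` (coupling noise `corrupt_sd`)
#'   or `"multiunit"` (random pair sums).
#' @param corrupt_sd coupling noise SD for the corrupted variant.
#' @param seed base RNG seed.
#' @return Tidy data frame: decoder, strength, seed, accuracy.
#' @export
modulator_strength_sweep <- function(base_cfg, strength_grid,
                                     n_train = 1000, n_test = 500,
                                     n_seeds = 5,
                                     decoders = c("optimal", "mg", "so"),
                                     variant = c("none", "corrupted", "multiunit"),
                                     corrupt_sd = 0.5, seed = 1) {
  variant <- match.arg(variant)
  res <- list()
  for (g in seq_along(strength_grid)) {
    strength <- strength_grid[g]
    sig <- iid_sigma_for_strength(base_cfg, strength)
    cfg <- base_cfg
    cfg$sigma_m <- sig
    for (sd_i in seq_len(n_seeds)) {
      sim_seed <- seed + 1000 * g + sd_i
      if (variant == "corrupted")
        cfg$couplings <- corrupt_couplings(base_cfg$couplings, corrupt_sd,
                                           seed = sim_seed)
      sim <- simulate_iid_population(cfg, n_per_stim = n_train + n_test,
                                     seed = sim_seed)
      rec <- sim$recording; mod <- sim$modulator
      P <- dim(rec$counts)[2]
      labels <- rec$meta$stimulus
      contrast <- rec$meta$contrast
      set.seed(sim_seed + 1)
      train_idx <- sort(sample.int(P, 2 * n_train))
      test_idx <- setdiff(seq_len(P), train_idx)
      counts <- rec$counts
      lam0 <- cfg$lambda0; lam1 <- cfg$lambda1; coup <- cfg$couplings
      if (variant == "multiunit") {
        mrec <- simulate_multiunits(rec, seed = sim_seed)
        counts <- mrec$counts
        U <- dim(rec$counts)[1]
        set.seed(sim_seed)                # reproduce the pairing
        idx <- sample.int(U)
        first <- idx[seq(1, U, 2)]; second <- idx[seq(2, U, 2)]
        lam0 <- cfg$lambda0[first] + cfg$lambda0[second]
        lam1 <- cfg$lambda1[first] + cfg$lambda1[second]
        coup <- (cfg$couplings[first] + cfg$couplings[second]) / 2
      }
      ctr <- counts[, train_idx, , drop = FALSE]
      cte <- counts[, test_idx, , drop = FALSE]
      ltr <- labels[train_idx]; lte <- labels[test_idx]
      mtr <- mod[train_idx, , drop = FALSE]; mte <- mod[test_idx, , drop = FALSE]
      for (dk in decoders) {
        dec <- switch(dk,
          optimal = {
            if (variant == "multiunit") {
              sc <- decoder_scores(ifelse(lam0 != lam1, log(lam1) - log(lam0), 0), ctr)
              optimal_decoder(lam0, lam1, mode = "constant",
                              train_scores = sc, train_labels = ltr)
            } else {
              optimal_decoder(lam0, lam1, coup, cfg$sigma_m,
                              mean_correction = cfg$mean_correction,
                              mode = "modulator")
            }
          },
          mg = mg_decoder(ctr, mtr, ltr),
          so = so_decoder(lam0, lam1, ctr, ltr),
          logistic = baseline_decoder(ctr, ltr, "logistic"))
        accu <- decoder_accuracy(dec, cte, lte, modulator = mte)
        res[[length(res) + 1]] <- data.frame(decoder = dk,
                                             strength = strength,
                                             seed = sd_i, accuracy = accu,
                                             stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, res)
}

#' Summarize a strength sweep with mean accuracy and 95\% CI
#'
#' @param sweep output of [modulator_strength_sweep()].
#' @return Data frame: decoder, strength, mean, lo, hi (normal-theory CI).
#' @export
summarize_sweep <- function(sweep) {
  agg <- stats::aggregate(accuracy ~ decoder + strength, sweep,
                          function(x) c(mean = mean(x),
                                        se = stats::sd(x) / sqrt(length(x))))
  out <- data.frame(decoder = agg$decoder, strength = agg$strength,
                    mean = agg$accuracy[, "mean"],
                    lo = agg$accuracy[, "mean"] - 1.96 * agg$accuracy[, "se"],
                    hi = agg$accuracy[, "mean"] + 1.96 * agg$accuracy[, "se"])
  out[order(out$decoder, out$strength), ]
}
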