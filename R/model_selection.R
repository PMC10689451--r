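# Latent dimensionality selection by cross-validated leave-one-neuron-out
# prediction.

#' Select the modulator dimensionality by cross-validation
#'
#' Fits the SR model (D = 0) and modulated-SR models over a range of latent
#' dimensionalities, scoring each by held-out leave-one-neuron-out
#' predictive log-likelihood (whole trials held out, folds stratified by
#' trial; latent posterior uncertainty integrated by sampling). Ties are
#' broken toward the smaller dimensionality.
#'
#' @param rec a `population_recording`.
#' @param design an `sr_design` (default built from `rec`).
#' @param D_range candidate dimensionalities (default 0:4).
#' @param folds cross-validation folds over trials (default 10; reduced
#'   with a warning when there are too few trials).
#' @param seed RNG seed (fold assignment and posterior sampling).
#' @param alpha ridge strength.
#' @param n_samples posterior path samples for the predictive score.
#' @param max_iter EM iteration cap for the fold fits.
#' @return A list: `selected_D`, `scores` (mean per-bin held-out LOO
#'   log-likelihood per D), `fold_scores` (folds x D matrix).
#' @export
select_dimensionality <- function(rec, design = build_design_matrix(rec),
                                  D_range = 0:4, folds = 10, seed = 1,
                                  alpha = 1, n_samples = 100, max_iter = 50) {
  prep <- plds_prepare(rec, design)
  n_trials <- length(prep$trials)
  if (n_trials < folds) {
    warning(sprintf("only %d trials; reducing folds from %d", n_trials, folds))
    folds <- max(2, n_trials)
  }
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(folds), n_trials))
  U <- prep$U
  fold_scores <- matrix(NA_real_, folds, length(D_range),
                        dimnames = list(NULL, paste0("D", D_range)))
  trial_key_all <- paste(rec$meta$block, rec$meta$trial)
  fit_mask <- fitting_bins(design)
  Tb <- design$Tb
  bin_trial <- rep(trial_key_all, each = Tb)
  trial_ids <- unique(bin_trial[fit_mask])

  for (f in seq_len(folds)) {
    train_tr <- trial_ids[fold_of != f]
    test_tr <- trial_ids[fold_of == f]
    train_trials <- prep$trials[fold_of != f]
    test_trials <- prep$trials[fold_of == f]
    # a reduced recording containing only the training trials, for fitting
    train_pres <- trial_key_all %in% train_tr
    sub <- rec
    sub$counts <- rec$counts[, train_pres, , drop = FALSE]
    sub$meta <- rec$meta[train_pres, , drop = FALSE]
    rownames(sub$meta) <- NULL
    sub_design <- build_design_matrix(sub,
      drift = "drift_right" %in% design$names,
      modulator = NULL)
    for (j in seq_along(D_range)) {
      D <- D_range[j]
      if (D == 0) {
        srf <- fit_sr(sub, sub_design, alpha = alpha)
        ll <- 0; nb <- 0
        for (tr in test_trials) {
          eta <- srf$coef %*% t(tr$X)
          ll <- ll + poisson_ll(tr$K, eta)
          nb <- nb + length(tr$K)
        }
        fold_scores[f, j] <- ll / nb
      } else {
        pf <- fit_plds_em(sub, sub_design, D = D, alpha = alpha,
                          max_iter = max_iter)
        loo <- plds_loo_ll(pf, trials = test_trials, n_samples = n_samples,
                           seed = seed + 1000 * f + D)
        nb <- sum(vapply(test_trials, function(tr) length(tr$K), numeric(1)))
        fold_scores[f, j] <- sum(loo) / nb
      }
    }
  }
  scores <- colMeans(fold_scores, na.rm = TRUE)
  # ties (within numerical noise) break toward the smaller dimensionality
  best <- max(scores)
  selected <- D_range[which(scores >= best - 1e-12)[1]]
  list(selected_D = selected, scores = scores, fold_scores = fold_scores)
}
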