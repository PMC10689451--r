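# Task statistics: d' informativeness with a permutation null, choice-d',
# Fano factors, rank-based partial correlations, group comparisons and
# modulator cross-correlograms.

dprime_value <- function(x0, x1) {
  pooled <- 0.5 * (stats::var(x0) + stats::var(x1))
  if (pooled == 0) return(NA_real_)
  abs(mean(x0) - mean(x1)) / sqrt(pooled)
}

#' Unit informativeness (d') with a permutation null
#'
#' `d' = |mu_0 - mu_1| / sqrt(0.5 (sigma_0^2 + sigma_1^2))` over responses
#' to the two task stimuli. The null distribution is built from random
#' splits of the stimulus-0 responses into two disjoint subsets matching
#' the group sizes (sizes `n0 - n1` and `n1` when `n0 > n1`, else equal
#' halves); the p-value is the fraction of null values at or above the
#' observed d'.
#'
#' @param x0,x1 per-presentation responses (e.g. window-summed counts) to
#'   stimulus 0 and 1.
#' @param n_perm permutation count (default 1000).
#' @param seed RNG seed.
#' @return List with `dprime`, `p_value`, `n_perm`.
#' @export
dprime <- function(x0, x1, n_perm = 1000, seed = 1) {
  if (length(x0) < 2 || length(x1) < 2)
    stop("need at least 2 presentations per stimulus")
  d_obs <- dprime_value(x0, x1)
  if (is.na(d_obs))
    return(list(dprime = NA_real_, p_value = NA_real_, n_perm = n_perm))
  set.seed(seed)
  n0 <- length(x0); n1 <- length(x1)
  nb <- if (n0 > n1) n1 else floor(n0 / 2)
  na_ <- n0 - nb
  if (na_ < 2 || nb < 2)
    return(list(dprime = d_obs, p_value = NA_real_, n_perm = n_perm))
  null_d <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n0, nb)
    dprime_value(x0[-idx], x0[idx])
  }, numeric(1))
  p <- mean(null_d >= d_obs, na.rm = TRUE)
  list(dprime = d_obs, p_value = p, n_perm = n_perm)
}

#' Choice-d': linking neural activity to behavioral outcome
#'
#' The d' formula applied to target responses grouped by the behavioral
#' outcome (hit vs miss) instead of stimulus identity.
#'
#' @param x_hit,x_miss per-trial target responses on hit and miss trials.
#' @return Scalar choice-d' (NA with fewer than 2 trials per outcome or
#'   zero pooled variance).
#' @export
choice_dprime <- function(x_hit, x_miss) {
  if (length(x_hit) < 2 || length(x_miss) < 2) return(NA_real_)
  dprime_value(x_hit, x_miss)
}

#' Rank-based partial correlation
#'
#' Linearly regresses the covariates out of the target (and, symmetrically,
#' out of the predictor), then Spearman-correlates the residuals. With an
#' empty covariate set this is the ordinary Spearman correlation.
#'
#' @param target,predictor numeric vectors.
#' @param covariates numeric matrix/data.frame with 0-2 columns.
#' @return List with `estimate`, `p_value`.
#' @export
partial_correlation <- function(target, predictor, covariates = NULL) {
  ok <- stats::complete.cases(target, predictor,
                              if (is.null(covariates)) target else covariates)
  target <- target[ok]; predictor <- predictor[ok]
  if (length(target) < 5) stop("need at least 5 complete observations")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)[ok, , drop = FALSE]
    if (qr(cbind(1, covariates))$rank < ncol(covariates) + 1)
      stop("covariate matrix is rank deficient")
    rt <- stats::resid(stats::lm.fit(cbind(1, covariates), target))
    rp <- stats::resid(stats::lm.fit(cbind(1, covariates), predictor))
  } else {
    rt <- target; rp <- predictor
  }
  if (stats::sd(rt) == 0 || stats::sd(rp) == 0)
    return(list(estimate = NA_real_, p_value = NA_real_))
  ct <- suppressWarnings(stats::cor.test(rt, rp, method = "spearman"))
  list(estimate = unname(ct$estimate), p_value = ct$p.value)
}

#' Two-group comparison (rank-sum or t)
#'
#' The two-sided tests used for relevant-vs-control modulator strength,
#' informative-vs-uninformative fit improvements and coupling-rank
#' comparisons.
#'
#' @param x,y the two groups.
#' @param test `"ranksum"` (Mann-Whitney U) or `"t"`.
#' @return List with `statistic`, `p_value`, `test`.
#' @export
compare_groups <- function(x, y, test = c("ranksum", "t")) {
  test <- match.arg(test)
  if (length(x) < 2 || length(y) < 2) stop("each group needs at least 2 values")
  h <- if (test == "ranksum") suppressWarnings(stats::wilcox.test(x, y))
       else stats::t.test(x, y)
  list(statistic = unname(h$statistic), p_value = h$p.value, test = test)
}

#' Within-trial cross-correlogram of two traces
#'
#' Pearson correlation of two aligned traces at integer lags, computed only
#' over bin pairs falling within the same trial. Positive lag means trace A
#' leads trace B.
#'
#' @param a,b equal-length traces (concatenated within-trial segments).
#' @param trial trial identifier per bin (correlations never cross trial
#'   boundaries).
#' @param max_lag largest lag in bins.
#' @return List with `lags`, `correlation`, `peak_lag`.
#' @export
cross_correlogram <- function(a, b, trial, max_lag) {
  stopifnot(length(a) == length(b), length(trial) == length(a))
  if (min(table(trial)) <= max_lag)
    stop("max_lag must be smaller than the shortest trial")
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(L) {
    xs <- ys <- list()
    for (tr in unique(trial)) {
      idx <- which(trial == tr)
      Tt <- length(idx)
      if (L >= 0) {
        t1 <- seq_len(Tt - L)
        xs[[length(xs) + 1]] <- a[idx[t1]]
        ys[[length(ys) + 1]] <- b[idx[t1 + L]]
      } else {
        t1 <- seq_len(Tt + L)
        xs[[length(xs) + 1]] <- a[idx[t1 - L]]
        ys[[length(ys) + 1]] <- b[idx[t1]]
      }
    }
    stats::cor(unlist(xs), unlist(ys))
  }, numeric(1))
  list(lags = lags, correlation = cc, peak_lag = lags[which.max(cc)])
}

#' Fano factor of window-summed counts
#'
#' Variance over mean of per-presentation summed counts, computed within
#' matched stimulus conditions (contrast by stimulus identity) and averaged
#' across conditions, to avoid stimulus-driven variance inflation.
#'
#' @param counts U x P x T_b array (or P-vector of summed counts for a
#'   single unit/condition).
#' @param meta presentation metadata (for the condition grouping); omit to
#'   treat all presentations as one condition.
#' @param window_bins bins to sum (default stimulus window = all supplied).
#' @return Per-unit Fano factors (scalar for vector input).
#' @export
fano_factor <- function(counts, meta = NULL, window_bins = NULL) {
  if (is.null(dim(counts))) {
    if (length(counts) < 2) stop("need at least 2 presentations")
    mu <- mean(counts)
    if (mu == 0) return(NA_real_)
    return(stats::var(counts) / mu)
  }
  Tb <- dim(counts)[3]
  if (is.null(window_bins)) window_bins <- seq_len(Tb)
  summed <- apply(counts[, , window_bins, drop = FALSE], c(1, 2), sum)
  cond <- if (is.null(meta)) rep(1, ncol(summed))
          else paste(meta$contrast, meta$stimulus)
  apply(summed, 1, function(x) {
    ff <- tapply(seq_along(x), cond, function(ix) {
      if (length(ix) < 2 || mean(x[ix]) == 0) return(NA_real_)
      stats::var(x[ix]) / mean(x[ix])
    })
    mean(unlist(ff), na.rm = TRUE)
  })
}

#' Per-unit statistics table for a fitted block
#'
#' Combines response statistics, informativeness, choice-d' and modulator
#' couplings into one tidy table.
#'
#' @param rec a `population_recording`.
#' @param fit optional `plds_fit` supplying coupling magnitudes.
#' @param n_perm permutations for the d' test.
#' @param seed RNG seed.
#' @return Data frame, one row per unit: mean rate (Hz), Fano factor, d',
#'   d' p-value, choice-d', coupling magnitude and within-block coupling
#'   rank (in [0, 1]).
#' @export
unit_statistics <- function(rec, fit = NULL, n_perm = 1000, seed = 1) {
  on_bins <- seq_len(rec$bins_on)
  U <- dim(rec$counts)[1]
  summed <- apply(rec$counts[, , on_bins, drop = FALSE], c(1, 2), sum)
  s <- rec$meta$stimulus
  hit_trials <- rec$meta$outcome == "hit"
  mean_rate <- rowMeans(summed) / (rec$bins_on * rec$bin_ms / 1000)
  fano <- fano_factor(rec$counts, rec$meta, on_bins)
  dp <- pp <- cdp <- numeric(U)
  # informativeness over behaviorally correct trials, as in the task analysis
  use0 <- s == 0 & hit_trials
  use1 <- s == 1 & hit_trials
  tgt <- s == 1
  for (u in seq_len(U)) {
    r <- dprime(summed[u, use0], summed[u, use1], n_perm = n_perm,
                seed = seed + u)
    dp[u] <- r$dprime; pp[u] <- r$p_value
    cdp[u] <- choice_dprime(summed[u, tgt & rec$meta$outcome == "hit"],
                            summed[u, tgt & rec$meta$outcome == "miss"])
  }
  coupling <- if (!is.null(fit)) sqrt(rowSums(fit$C^2)) else rep(NA_real_, U)
  coupling_rank <- if (!is.null(fit)) (rank(coupling) - 1) / (U - 1) else rep(NA_real_, U)
  data.frame(unit_id = rec$unit_ids, mean_rate_hz = mean_rate, fano = fano,
             dprime = dp, dprime_p = pp, choice_dprime = cdp,
             coupling = coupling, coupling_rank = coupling_rank,
             stringsAsFactors = FALSE)
}
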