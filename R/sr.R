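# Stimulus-response (SR) Poisson regression with a ridge penalty.
#
# Per unit, maximizes sum_t [ k_t (beta' s_t) - exp(beta' s_t) ] -
# alpha * sum_{j != offset} beta_j^2 by damped Newton iteration. The offset
# is unpenalized so the penalty shrinks stimulus structure, not base rate.

poisson_ll <- function(k, log_rate) {
  sum(k * log_rate - exp(log_rate) - lgamma(k + 1))
}

# saturated Poisson log-likelihood (rate = observed count; 0*log(0) = 0)
poisson_ll_saturated <- function(k) {
  lk <- ifelse(k > 0, log(k), 0)
  sum(k * lk - k - lgamma(k + 1))
}

# single-unit ridge Poisson regression; returns coefficient vector
fit_poisson_ridge <- function(X, k, alpha, penalty_mask, beta0 = NULL,
                              max_iter = 50, tol = 1e-9) {
  p <- ncol(X)
  pen <- alpha * penalty_mask
  beta <- if (is.null(beta0)) {
    b <- numeric(p)
    off <- which(colnames(X) == "offset")
    if (length(off) == 1) b[off] <- log(mean(k) + 1e-3)
    b
  } else beta0
  obj <- function(b) {
    eta <- drop(X %*% b)
    sum(k * eta - exp(eta)) - sum(pen * b^2)
  }
  f <- obj(beta)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    grad <- drop(crossprod(X, k - mu)) - 2 * pen * beta
    if (sqrt(sum(grad^2)) < tol * (1 + abs(f))) break
    H <- crossprod(X * mu, X)
    diag(H) <- diag(H) + 2 * pen + 1e-10
    step <- solve(H, grad)
    # damped update
    s <- 1
    repeat {
      bnew <- beta + s * step
      fnew <- obj(bnew)
      if (is.finite(fnew) && fnew >= f - 1e-12) break
      s <- s / 2
      if (s < 1e-8) { bnew <- beta; fnew <- f; break }
    }
    if (abs(fnew - f) < tol * (1 + abs(f))) { beta <- bnew; f <- fnew; break }
    beta <- bnew; f <- fnew
  }
  beta
}

#' Fit the stimulus-response model
#'
#' Ridge-penalized Poisson regression of each unit's binned counts on the
#' SR design, fitted independently per unit by Newton iteration (the offset
#' coefficient is unpenalized). By default target presentations are held
#' out of the fit; their responses are reserved for informativeness and
#' decoding analyses.
#'
#' @param rec a `population_recording`.
#' @param design an `sr_design` from [build_design_matrix()] (default:
#'   built from `rec`).
#' @param alpha ridge strength on non-offset coefficients (default 1).
#' @param include_target include target-presentation bins in the fit.
#' @param bins optional logical vector over design rows overriding the bin
#'   selection.
#' @return An `sr_fit`: `coef` (units x design columns), `alpha`, `design`,
#'   per-unit training log-likelihood `ll`, the `bins` used, and per-unit
#'   pseudo-R^2 against the mean-rate null (`pseudo_r2`).
#' @export
fit_sr <- function(rec, design = build_design_matrix(rec), alpha = 1,
                   include_target = FALSE, bins = NULL) {
  stopifnot(inherits(design, "sr_design"))
  if (is.null(bins)) bins <- fitting_bins(design, include_target)
  K <- flatten_counts(rec)[, bins, drop = FALSE]
  X <- design$X[bins, , drop = FALSE]
  U <- nrow(K)
  pmask <- as.numeric(colnames(X) != "offset")
  coef <- matrix(0, U, ncol(X), dimnames = list(rec$unit_ids, colnames(X)))
  ll <- ll_null <- ll_sat <- numeric(U)
  for (u in seq_len(U)) {
    k <- K[u, ]
    coef[u, ] <- fit_poisson_ridge(X, k, alpha, pmask)
    ll[u] <- poisson_ll(k, drop(X %*% coef[u, ]))
    ll_null[u] <- poisson_ll(k, rep(log(mean(k) + 1e-12), length(k)))
    ll_sat[u] <- poisson_ll_saturated(k)
  }
  structure(list(coef = coef, alpha = alpha, design = design,
                 bins = bins, ll = ll, ll_null = ll_null, ll_sat = ll_sat,
                 pseudo_r2 = mapply(pseudo_r2, ll, ll_null, ll_sat)),
            class = "sr_fit")
}

#' @export
print.sr_fit <- function(x, ...) {
  cat(sprintf("<sr_fit> %d units, %d design columns, alpha = %g, median pseudo-R2 = %.3f\n",
              nrow(x$coef), ncol(x$coef), x$alpha,
              stats::median(x$pseudo_r2, na.rm = TRUE)))
  invisible(x)
}

#' Predicted log rates of an SR fit
#'
#' @param fit an `sr_fit`.
#' @param X design rows (default: the rows the model was fitted on).
#' @return units x rows matrix of log rates.
#' @export
predict_log_rate <- function(fit, X = fit$design$X[fit$bins, , drop = FALSE]) {
  fit$coef %*% t(X)
}

#' Pseudo-R^2 of a model against a null and saturated reference
#'
#' The fraction of the maximum potential log-likelihood gain relative to
#' the null model achieved by the fitted model:
#' `(LL_model - LL_null) / (LL_saturated - LL_null)`.
#'
#' @param ll_model,ll_null,ll_sat log-likelihoods of the fitted, null and
#'   saturated models on the same observations.
#' @return Scalar pseudo-R^2, or `NA` when the denominator is zero.
#' @export
pseudo_r2 <- function(ll_model, ll_null, ll_sat) {
  den <- ll_sat - ll_null
  if (!is.finite(den) || den == 0) return(NA_real_)
  (ll_model - ll_null) / den
}

#' Fit the SR model with an external modulator covariate
#'
#' Augments the SR design with a z-scored modulator trace (typically the
#' posterior-mean modulator extracted from a simultaneously recorded
#' primary population) and reports the per-unit pseudo-R^2 improvement over
#' the plain SR fit.
#'
#' @param rec a downstream `population_recording`.
#' @param modulator P x T_b matrix of modulator values aligned to `rec`.
#' @param alpha ridge strength.
#' @param include_target include target-presentation bins.
#' @return A list: `fit_sr` (plain SR), `fit_mod` (SR + modulator),
#'   `improvement` (per-unit pseudo-R^2 difference), `coupling` (the
#'   fitted modulator coefficient per unit).
#' @export
fit_sr_plus_modulator <- function(rec, modulator, alpha = 1,
                                  include_target = FALSE) {
  d0 <- build_design_matrix(rec)
  d1 <- build_design_matrix(rec, modulator = modulator)
  f0 <- fit_sr(rec, d0, alpha = alpha, include_target = include_target)
  f1 <- fit_sr(rec, d1, alpha = alpha, include_target = include_target)
  list(fit_sr = f0, fit_mod = f1,
       improvement = f1$pseudo_r2 - f0$pseudo_r2,
       coupling = f1$coef[, "modulator"])
}
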