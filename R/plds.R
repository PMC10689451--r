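# Modulated-SR model: Poisson linear dynamical system fitted by EM with a
# Laplace E-step.
#
#   k_t ~ Poisson(exp(C m_t + B s_t))
#   m_{t+1} = A m_t + eps,  eps ~ N(0, Q),  m_1 ~ N(0, Q0)
#
# Trials are independent latent sequences. The E-step maximizes the joint
# latent posterior per trial by Newton iteration, exploiting the
# block-tridiagonal Hessian; marginal and one-step cross covariances come
# from the standard block-tridiagonal inverse recursions. The M-step is
# closed-form for (A, Q, Q0) and damped-Newton for (C, B) on the expected
# complete-data log-likelihood, with the same ridge on B as the SR model.
#
# Scale convention: the latent is normalized to stationary variance 1 per
# dimension (the coupling magnitudes carry the modulation strength) and the
# sign is fixed so that each column of C sums to >= 0.

# split fitted bins into per-trial contiguous segments
plds_prepare <- function(rec, design, include_target = FALSE) {
  bins <- fitting_bins(design, include_target)
  K <- flatten_counts(rec)
  Tb <- design$Tb
  trial_key <- paste(rec$meta$block, rec$meta$trial)
  bin_trial <- rep(trial_key, each = Tb)
  keep <- which(bins)
  trials <- lapply(unique(bin_trial[keep]), function(tr) {
    idx <- keep[bin_trial[keep] == tr]
    list(idx = idx,
         K = K[, idx, drop = FALSE],
         X = design$X[idx, , drop = FALSE],
         lgam = sum(lgamma(K[, idx, drop = FALSE] + 1)))
  })
  list(trials = trials, U = nrow(K), p = ncol(design$X))
}

# fast scalar path for the 1-d latent: identical algorithm, no small-matrix
# allocations in the Thomas recursions
plds_estep_trial_1d <- function(trial, C, B, A, Q, Q0, units = NULL,
                                max_iter = 30, tol = 1e-9) {
  Kt <- t(trial$K); X <- trial$X
  if (!is.null(units)) Kt <- Kt[, units, drop = FALSE]
  cu <- if (is.null(units)) C[, 1] else C[units, 1]
  Bu <- if (is.null(units)) B else B[units, , drop = FALSE]
  Tt <- nrow(Kt)
  XB <- X %*% t(Bu)
  a <- A[1, 1]; q <- Q[1, 1]; q0 <- Q0[1, 1]
  qi <- 1 / q; q0i <- 1 / q0
  a2qi <- a^2 * qi
  uoff <- -a * qi
  ld_prior <- -0.5 * log(2 * pi * q0) - 0.5 * (Tt - 1) * log(2 * pi * q)
  cu2 <- cu^2
  m <- numeric(Tt)
  fval <- function(m) {
    eta <- outer(m, cu, `*`) + XB
    ll <- sum(Kt * eta - exp(eta))
    pr <- -0.5 * q0i * m[1]^2
    if (Tt > 1) {
      r <- m[-1] - a * m[-Tt]
      pr <- pr - 0.5 * qi * sum(r^2)
    }
    ll + pr + ld_prior
  }
  f <- fval(m)
  phi <- numeric(Tt)
  for (it in seq_len(max_iter)) {
    eta <- outer(m, cu, `*`) + XB
    lam <- exp(eta)
    g <- drop((Kt - lam) %*% cu)
    if (Tt > 1) {
      r <- m[-1] - a * m[-Tt]
      g[1] <- g[1] - q0i * m[1] + a * qi * r[1]
      if (Tt > 2)
        g[2:(Tt - 1)] <- g[2:(Tt - 1)] - qi * r[1:(Tt - 2)] + a * qi * r[2:(Tt - 1)]
      g[Tt] <- g[Tt] - qi * r[Tt - 1]
    } else {
      g[1] <- g[1] - q0i * m[1]
    }
    w <- drop(lam %*% cu2)
    w[1] <- w[1] + q0i + if (Tt > 1) a2qi else 0
    if (Tt > 2) w[2:(Tt - 1)] <- w[2:(Tt - 1)] + qi + a2qi
    if (Tt > 1) w[Tt] <- w[Tt] + qi
    cc <- numeric(Tt)
    phi[1] <- w[1]
    cc[1] <- g[1] / phi[1]
    if (Tt > 1) {
      for (t in 2:Tt) {
        phi[t] <- w[t] - uoff^2 / phi[t - 1]
        cc[t] <- (g[t] - uoff * cc[t - 1]) / phi[t]
      }
    }
    dlt <- numeric(Tt)
    dlt[Tt] <- cc[Tt]
    if (Tt > 1)
      for (t in (Tt - 1):1) dlt[t] <- cc[t] - uoff * dlt[t + 1] / phi[t]
    s <- 1
    repeat {
      mn <- m + s * dlt
      fn <- fval(mn)
      if (is.finite(fn) && fn >= f - 1e-12) break
      s <- s / 2
      if (s < 1e-10) { mn <- m; fn <- f; break }
    }
    conv <- abs(fn - f) < tol * (1 + abs(f)) || sqrt(sum(g^2)) < 1e-7 * Tt
    m <- mn; f <- fn
    if (conv && it > 1) break
  }
  lam <- exp(outer(m, cu, `*`) + XB)
  w <- drop(lam %*% cu2)
  w[1] <- w[1] + q0i + if (Tt > 1) a2qi else 0
  if (Tt > 2) w[2:(Tt - 1)] <- w[2:(Tt - 1)] + qi + a2qi
  if (Tt > 1) w[Tt] <- w[Tt] + qi
  phi[1] <- w[1]
  if (Tt > 1) for (t in 2:Tt) phi[t] <- w[t] - uoff^2 / phi[t - 1]
  sig <- numeric(Tt); crs <- if (Tt > 1) numeric(Tt - 1) else NULL
  sig[Tt] <- 1 / phi[Tt]
  if (Tt > 1) {
    for (t in (Tt - 1):1) {
      gt <- uoff / phi[t]
      sig[t] <- 1 / phi[t] + gt^2 * sig[t + 1]
      crs[t] <- -gt * sig[t + 1]
    }
  }
  lgam_u <- if (is.null(units)) trial$lgam else sum(lgamma(Kt + 1))
  ll <- f - lgam_u + 0.5 * Tt * log(2 * pi) - 0.5 * sum(log(phi))
  list(M = matrix(m, Tt, 1), Sig = array(sig, c(Tt, 1, 1)),
       Cross = if (Tt > 1) array(crs, c(Tt - 1, 1, 1)) else NULL,
       ll = ll, Phi = lapply(phi, function(x) matrix(x, 1, 1)),
       Uoff = matrix(uoff, 1, 1))
}

# Laplace E-step for one trial. `units` restricts the likelihood to a unit
# subset (leave-one-neuron-out); the prior always applies.
# Returns posterior mean, marginal/cross covariances, the Laplace
# log-likelihood, and the forward-elimination blocks needed for sampling.
plds_estep_trial <- function(trial, C, B, A, Q, Q0, units = NULL,
                             max_iter = 30, tol = 1e-9) {
  if (ncol(C) == 1L)
    return(plds_estep_trial_1d(trial, C, B, A, Q, Q0, units, max_iter, tol))
  D <- ncol(C)
  Kt <- t(trial$K); X <- trial$X
  if (!is.null(units)) { Kt <- Kt[, units, drop = FALSE] }
  Cu <- if (is.null(units)) C else C[units, , drop = FALSE]
  Bu <- if (is.null(units)) B else B[units, , drop = FALSE]
  Tt <- nrow(Kt)
  XB <- X %*% t(Bu)                       # T x U fixed stimulus drive
  Qi <- solve(Q); Q0i <- solve(Q0)
  AtQi <- t(A) %*% Qi
  AtQiA <- AtQi %*% A
  Uoff <- -AtQi                            # H_{t,t+1}
  ld_prior <- -0.5 * determinant(2 * pi * Q0)$modulus[1] -
    0.5 * (Tt - 1) * determinant(2 * pi * Q)$modulus[1]

  M <- matrix(0, Tt, D)
  fval <- function(M) {
    eta <- M %*% t(Cu) + XB
    ll <- sum(Kt * eta - exp(eta))
    if (Tt > 1) {
      R <- M[-1, , drop = FALSE] - M[-Tt, , drop = FALSE] %*% t(A)
      pr <- -0.5 * sum(M[1, ] * (Q0i %*% M[1, ])) - 0.5 * sum((R %*% Qi) * R)
    } else {
      pr <- -0.5 * sum(M[1, ] * (Q0i %*% M[1, ]))
    }
    ll + pr + ld_prior
  }
  f <- fval(M)
  Phi <- vector("list", Tt)
  for (it in seq_len(max_iter)) {
    eta <- M %*% t(Cu) + XB
    lam <- exp(eta)
    Glik <- (Kt - lam) %*% Cu              # T x D
    G <- Glik
    if (Tt > 1) {
      R <- M[-1, , drop = FALSE] - M[-Tt, , drop = FALSE] %*% t(A)  # (T-1) x D
      RQ <- R %*% t(Qi)
      G[1, ] <- G[1, ] - drop(Q0i %*% M[1, ]) + drop(AtQi %*% R[1, ])
      if (Tt > 2)
        G[2:(Tt - 1), ] <- G[2:(Tt - 1), ] - RQ[1:(Tt - 2), , drop = FALSE] +
          R[2:(Tt - 1), , drop = FALSE] %*% t(AtQi)
      G[Tt, ] <- G[Tt, ] - RQ[Tt - 1, ]
    } else {
      G[1, ] <- G[1, ] - drop(Q0i %*% M[1, ])
    }
    gnorm <- sqrt(sum(G^2))
    # Newton direction via block-tridiagonal (Thomas) elimination
    cc <- matrix(0, Tt, D)
    for (t in seq_len(Tt)) {
      W <- crossprod(Cu * lam[t, ], Cu)
      if (t == 1) {
        W <- W + Q0i + if (Tt > 1) AtQiA else 0
        Phi[[1]] <- W
        cc[1, ] <- solve(Phi[[1]], G[1, ])
      } else {
        W <- W + Qi + if (t < Tt) AtQiA else 0
        Phi[[t]] <- W - t(Uoff) %*% solve(Phi[[t - 1]], Uoff)
        cc[t, ] <- solve(Phi[[t]], G[t, ] - drop(t(Uoff) %*% cc[t - 1, ]))
      }
    }
    Dlt <- matrix(0, Tt, D)
    Dlt[Tt, ] <- cc[Tt, ]
    if (Tt > 1)
      for (t in (Tt - 1):1)
        Dlt[t, ] <- cc[t, ] - solve(Phi[[t]], drop(Uoff %*% Dlt[t + 1, ]))
    s <- 1
    repeat {
      Mn <- M + s * Dlt
      fn <- fval(Mn)
      if (is.finite(fn) && fn >= f - 1e-12) break
      s <- s / 2
      if (s < 1e-10) { Mn <- M; fn <- f; break }
    }
    conv <- abs(fn - f) < tol * (1 + abs(f)) || gnorm < 1e-7 * Tt
    M <- Mn; f <- fn
    if (conv && it > 1) break
  }
  # covariance recursions from the final Hessian elimination blocks
  eta <- M %*% t(Cu) + XB
  lam <- exp(eta)
  for (t in seq_len(Tt)) {
    W <- crossprod(Cu * lam[t, ], Cu)
    if (t == 1) {
      Phi[[1]] <- W + Q0i + if (Tt > 1) AtQiA else 0
    } else {
      W <- W + Qi + if (t < Tt) AtQiA else 0
      Phi[[t]] <- W - t(Uoff) %*% solve(Phi[[t - 1]], Uoff)
    }
  }
  Sig <- array(0, c(Tt, D, D))
  Cross <- if (Tt > 1) array(0, c(Tt - 1, D, D)) else NULL
  Sig[Tt, , ] <- solve(Phi[[Tt]])
  if (Tt > 1) {
    for (t in (Tt - 1):1) {
      Gt <- solve(Phi[[t]], Uoff)
      Snext <- matrix(Sig[t + 1, , ], D, D)
      Sig[t, , ] <- solve(Phi[[t]]) + Gt %*% Snext %*% t(Gt)
      Cross[t, , ] <- -Gt %*% Snext       # Cov(m_t, m_{t+1})
    }
  }
  logdetH <- sum(vapply(Phi, function(W) determinant(W)$modulus[1], numeric(1)))
  lgam_u <- if (is.null(units)) trial$lgam else sum(lgamma(Kt + 1))
  ll <- f - lgam_u + 0.5 * Tt * D * log(2 * pi) - 0.5 * logdetH
  list(M = M, Sig = Sig, Cross = Cross, ll = ll, Phi = Phi, Uoff = Uoff)
}

# draw n sample paths from the Laplace posterior using the block
# bidiagonal Cholesky factor implied by the elimination blocks;
# vectorized across samples (one backward sweep over time)
plds_sample_paths <- function(est, n) {
  Tt <- nrow(est$M); D <- ncol(est$M)
  Lt <- lapply(est$Phi, function(W) t(chol(W)))   # lower triangular
  Uoff <- est$Uoff
  Wt <- vector("list", Tt)
  if (Tt > 1)
    for (t in 2:Tt) Wt[[t]] <- t(solve(Lt[[t - 1]], Uoff))  # U' L^{-T}
  samples <- array(0, c(n, Tt, D))
  Z <- array(stats::rnorm(n * Tt * D), c(n, Tt, D))
  # backward substitution rows-as-samples: x_t' = (z_t' - x_{t+1}' W_{t+1}) L_t^{-1}
  Xs <- matrix(Z[, Tt, ], n, D) %*% solve(Lt[[Tt]])
  samples[, Tt, ] <- sweep(Xs, 2, est$M[Tt, ], `+`)
  if (Tt > 1) {
    for (t in (Tt - 1):1) {
      R <- matrix(Z[, t, ], n, D) - Xs %*% Wt[[t + 1]]
      Xs <- R %*% solve(Lt[[t]])
      samples[, t, ] <- sweep(Xs, 2, est$M[t, ], `+`)
    }
  }
  samples
}

# initialization of C from the top factor(s) of the Pearson-residual
# covariance given the SR-only rates
plds_init_C <- function(trials, B, D) {
  Kall <- do.call(cbind, lapply(trials, function(tr) tr$K))
  Xall <- do.call(rbind, lapply(trials, function(tr) tr$X))
  lam <- exp(B %*% t(Xall))
  Z <- (Kall - lam) / sqrt(lam + 1e-8)
  S <- tcrossprod(Z) / ncol(Z)
  eg <- eigen(S, symmetric = TRUE)
  lbar <- rowMeans(lam)
  C0 <- matrix(0, nrow(Kall), D)
  for (d in seq_len(D)) {
    amp <- sqrt(max(eg$values[d] - 1, 0.05))
    C0[, d] <- eg$vectors[, d] * amp / sqrt(pmax(lbar, 1e-3))
  }
  # cap extreme entries for numerical safety
  pmin(pmax(C0, -2), 2)
}

# expected-complete-data damped-Newton update of (C, B) per unit; ridge
# alpha on non-offset columns of B, C unpenalized
plds_update_CB <- function(trials, post, C, B, alpha, pmask, n_newton = 3) {
  U <- nrow(C); D <- ncol(C)
  MU <- do.call(rbind, lapply(post, function(e) e$M))
  SIG <- do.call(rbind, lapply(post, function(e) matrix(e$Sig, nrow(e$M), D * D)))
  Xall <- do.call(rbind, lapply(trials, function(tr) tr$X))
  Kall <- do.call(cbind, lapply(trials, function(tr) tr$K))
  pen_b <- alpha * pmask
  ID <- diag(1, D)
  for (u in seq_len(U)) {
    cu <- C[u, ]; bu <- B[u, ]
    k <- Kall[u, ]
    eobj <- function(cu, bu) {
      Sc <- SIG %*% kronecker(matrix(cu, ncol = 1), ID)        # T x D
      eta <- drop(MU %*% cu + Xall %*% bu)
      lam <- exp(eta + 0.5 * drop(Sc %*% cu))
      list(f = sum(k * eta - lam) - sum(pen_b * bu^2), Sc = Sc, lam = lam)
    }
    cur <- eobj(cu, bu)
    for (nt in seq_len(n_newton)) {
      Sc <- cur$Sc; lam <- cur$lam
      Mtil <- MU + Sc
      grad_c <- drop(crossprod(MU, k) - crossprod(Mtil, lam))
      grad_b <- drop(crossprod(Xall, k - lam)) - 2 * pen_b * bu
      Hcc <- crossprod(Mtil * lam, Mtil) + matrix(colSums(SIG * lam), D, D)
      Hcb <- crossprod(Mtil * lam, Xall)
      Hbb <- crossprod(Xall * lam, Xall)
      diag(Hbb) <- diag(Hbb) + 2 * pen_b + 1e-10
      H <- rbind(cbind(Hcc + diag(1e-10, D), Hcb), cbind(t(Hcb), Hbb))
      g <- c(grad_c, grad_b)
      if (sqrt(sum(g^2)) < 1e-8 * (1 + abs(cur$f))) break
      step <- tryCatch(solve(H, g), error = function(e) g / max(diag(H)))
      s <- 1
      repeat {
        cn <- cu + s * step[seq_len(D)]
        bn <- bu + s * step[-seq_len(D)]
        nxt <- eobj(cn, bn)
        if (is.finite(nxt$f) && nxt$f >= cur$f - 1e-12) break
        s <- s / 2
        if (s < 1e-8) { cn <- cu; bn <- bu; nxt <- cur; break }
      }
      cu <- cn; bu <- bn; cur <- nxt
    }
    C[u, ] <- cu; B[u, ] <- bu
  }
  list(C = C, B = B)
}

# stationary covariance of the latent AR process (iterated Lyapunov)
plds_stationary_cov <- function(A, Q, iter = 500) {
  S <- Q
  for (i in seq_len(iter)) {
    Sn <- A %*% S %*% t(A) + Q
    if (max(abs(Sn - S)) < 1e-12) { S <- Sn; break }
    S <- Sn
  }
  S
}

#' Fit the modulated-SR model (Poisson linear dynamical system) by EM
#'
#' Estimates a D-dimensional latent modulator shared across the population,
#' its AR(1) dynamics, per-unit couplings `C` and stimulus weights `B`,
#' treating trials as independent sequences. The E-step is a per-trial
#' Laplace approximation (Newton maximization of the joint latent
#' posterior with a block-tridiagonal Hessian); the M-step updates
#' `A, Q, Q0` in closed form and `(C, B)` by damped Newton on the expected
#' complete-data log-likelihood. On return the latent scale is normalized
#' to stationary variance 1 per dimension (couplings carry the magnitude)
#' and signs are flipped so each column of `C` sums to >= 0.
#'
#' `D = 0` delegates to [fit_sr()].
#'
#' @param rec a `population_recording`.
#' @param design an `sr_design` (default built from `rec`).
#' @param D latent dimensionality (0 to 4).
#' @param alpha ridge strength on non-offset stimulus weights.
#' @param max_iter maximum EM iterations (default 100).
#' @param tol relative change in approximate log-likelihood declaring
#'   convergence (default 1e-6).
#' @param include_target include target-presentation bins in the fit
#'   (default FALSE; they are reserved for decoding).
#' @return A `plds_fit` with elements `D`, `A`, `Q`, `Q0`, `C`, `B`,
#'   `posterior` (per-trial E-step results), `trials`, `ll_trace`,
#'   `converged`, `design`, `alpha`. For `D = 0`, the `sr_fit` is returned.
#' @export
fit_plds_em <- function(rec, design = build_design_matrix(rec), D = 1,
                        alpha = 1, max_iter = 100, tol = 1e-6,
                        include_target = FALSE) {
  stopifnot(D >= 0, D <= 4)
  if (D == 0) return(fit_sr(rec, design, alpha = alpha,
                            include_target = include_target))
  prep <- plds_prepare(rec, design, include_target)
  trials <- prep$trials
  U <- prep$U; p <- prep$p
  pmask <- as.numeric(colnames(design$X) != "offset")

  srfit <- fit_sr(rec, design, alpha = alpha, include_target = include_target)
  B <- unname(srfit$coef)
  C <- plds_init_C(trials, B, D)
  A <- diag(0.5, D); Q <- diag(0.75, D); Q0 <- diag(1, D)

  ll_trace <- numeric(0)
  best <- NULL
  for (it in seq_len(max_iter)) {
    post <- lapply(trials, function(tr)
      plds_estep_trial(tr, C, B, A, Q, Q0))
    ll <- sum(vapply(post, function(e) e$ll, numeric(1)))
    ll_trace <- c(ll_trace, ll)
    if (is.null(best) || ll > best$ll) {
      best <- list(ll = ll, A = A, Q = Q, Q0 = Q0, C = C, B = B, post = post)
    } else {
      # approximate objective stopped improving: return the best iterate;
      # only a decrease well beyond the Laplace approximation error warns
      if (ll < best$ll - 1e-4 * abs(best$ll))
        warning("EM objective decreased beyond tolerance; returning best iterate")
      break
    }
    if (it > 1 && abs(ll - ll_trace[it - 1]) < tol * (1 + abs(ll))) break

    # closed-form dynamics updates
    S1 <- S2 <- S3 <- matrix(0, D, D)
    Q0n <- matrix(0, D, D)
    n_pairs <- 0
    for (e in post) {
      Tt <- nrow(e$M)
      Emm <- lapply(seq_len(Tt), function(t)
        matrix(e$Sig[t, , ], D, D) + tcrossprod(e$M[t, ]))
      Q0n <- Q0n + Emm[[1]]
      if (Tt > 1) {
        for (t in seq_len(Tt - 1)) {
          Ecross <- matrix(e$Cross[t, , ], D, D) + tcrossprod(e$M[t, ], e$M[t + 1, ])
          # Ecross = E[m_t m_{t+1}'] ; we need E[m_{t+1} m_t'] = t(Ecross)
          S1 <- S1 + Emm[[t]]
          S2 <- S2 + t(Ecross)
          S3 <- S3 + Emm[[t + 1]]
          n_pairs <- n_pairs + 1
        }
      }
    }
    A <- S2 %*% solve(S1 + diag(1e-9, D))
    Qn <- (S3 - A %*% t(S2) - S2 %*% t(A) + A %*% S1 %*% t(A)) / n_pairs
    Q <- (Qn + t(Qn)) / 2
    if (any(eigen(Q, symmetric = TRUE, only.values = TRUE)$values < 1e-8)) {
      warning("near-singular innovation covariance; adding jitter")
      Q <- Q + diag(1e-6, D)
    }
    Q0 <- (Q0n + t(Q0n)) / (2 * length(post))
    if (any(eigen(Q0, symmetric = TRUE, only.values = TRUE)$values < 1e-8))
      Q0 <- Q0 + diag(1e-6, D)
    # keep dynamics stable
    ev <- abs(eigen(A, only.values = TRUE)$values)
    if (any(ev >= 0.999)) A <- A * 0.998 / max(ev)

    upd <- plds_update_CB(trials, post, C, B, alpha, pmask)
    C <- upd$C; B <- upd$B
  }
  converged <- length(ll_trace) < max_iter
  A <- best$A; Q <- best$Q; Q0 <- best$Q0; C <- best$C; B <- best$B

  # normalize latent scale to stationary variance 1 per dimension,
  # then fix signs so columns of C sum to >= 0
  Sst <- plds_stationary_cov(A, Q)
  sc <- sqrt(pmax(diag(Sst), 1e-12))
  Tm <- diag(1 / sc, D); Tmi <- diag(sc, D)
  A <- Tm %*% A %*% Tmi
  Q <- Tm %*% Q %*% t(Tm); Q0 <- Tm %*% Q0 %*% t(Tm)
  C <- C %*% Tmi
  flip <- ifelse(colSums(C) < 0, -1, 1)
  Sf <- diag(flip, D)
  A <- Sf %*% A %*% Sf; Q <- Sf %*% Q %*% Sf; Q0 <- Sf %*% Q0 %*% Sf
  C <- C %*% Sf

  post <- lapply(trials, function(tr) plds_estep_trial(tr, C, B, A, Q, Q0))
  ll_final <- sum(vapply(post, function(e) e$ll, numeric(1)))
  structure(list(D = D, A = A, Q = Q, Q0 = Q0, C = C, B = B,
                 posterior = post, trials = trials,
                 ll = ll_final, ll_trace = ll_trace, converged = converged,
                 design = design, alpha = alpha, bin_ms = rec$bin_ms,
                 unit_ids = rec$unit_ids),
            class = "plds_fit")
}

#' @export
print.plds_fit <- function(x, ...) {
  cat(sprintf("<plds_fit> D = %d, %d units, %d trials, approx LL = %.1f (%s)\n",
              x$D, nrow(x$C), length(x$trials), x$ll,
              if (x$converged) "converged" else "max iterations"))
  invisible(x)
}

#' Posterior-mean modulator aligned to the recording's bin grid
#'
#' Runs a smoothing E-step over complete trials with the fitted parameters,
#' treating target-presentation bins as unobserved when they were excluded
#' from fitting (their modulator values are AR-smoothed extrapolations).
#'
#' @param fit a `plds_fit`.
#' @param rec the recording the model was fitted to.
#' @param dim latent dimension to return (default 1).
#' @return P x T_b matrix of posterior mean modulator values.
#' @export
plds_modulator_trace <- function(fit, rec, dim = 1) {
  design <- fit$design
  Tb <- design$Tb; P <- design$P
  K <- flatten_counts(rec)
  trial_key <- paste(rec$meta$block, rec$meta$trial)
  bin_trial <- rep(trial_key, each = Tb)
  fit_mask <- fitting_bins(design, include_target = FALSE)
  m <- numeric(P * Tb)
  for (tr in unique(bin_trial)) {
    idx <- which(bin_trial == tr)
    obs <- fit_mask[idx]
    # targets are always the final presentation, so unobserved bins form a
    # trailing segment: smooth over the observed prefix, AR-extrapolate the rest
    if (all(obs)) {
      est <- plds_estep_trial(list(idx = idx, K = K[, idx, drop = FALSE],
                                   X = design$X[idx, , drop = FALSE],
                                   lgam = sum(lgamma(K[, idx, drop = FALSE] + 1))),
                              fit$C, fit$B, fit$A, fit$Q, fit$Q0)
      m[idx] <- est$M[, dim]
    } else {
      oidx <- idx[obs]
      est <- plds_estep_trial(list(idx = oidx, K = K[, oidx, drop = FALSE],
                                   X = design$X[oidx, , drop = FALSE],
                                   lgam = sum(lgamma(K[, oidx, drop = FALSE] + 1))),
                              fit$C, fit$B, fit$A, fit$Q, fit$Q0)
      m[oidx] <- est$M[, dim]
      # AR-extrapolate into the unobserved tail
      tail_idx <- idx[!obs]
      last <- est$M[nrow(est$M), dim]
      a1 <- fit$A[dim, dim]
      for (j in seq_along(tail_idx)) m[tail_idx[j]] <- last * a1^j
    }
  }
  matrix(m, nrow = P, ncol = Tb, byrow = TRUE)
}

#' Leave-one-neuron-out predictive log-likelihood
#'
#' For each unit, infers the latent path on each trial from all other
#' units, then scores the held-out unit's counts under the predictive
#' distribution, averaging the likelihood over `n_samples` posterior path
#' samples (log-mean-exp across samples, summed over trials).
#'
#' @param fit a `plds_fit` (or parameter list with C, B, A, Q, Q0).
#' @param trials trial list as produced internally (default: the fitted
#'   trials).
#' @param n_samples posterior samples per trial (default 100).
#' @param seed RNG seed for the path sampling.
#' @return Numeric vector of per-unit predictive log-likelihoods.
#' @export
plds_loo_ll <- function(fit, trials = fit$trials, n_samples = 100, seed = 1) {
  set.seed(seed)
  U <- nrow(fit$C)
  out <- numeric(U)
  for (u in seq_len(U)) {
    others <- setdiff(seq_len(U), u)
    tot <- 0
    for (tr in trials) {
      est <- plds_estep_trial(tr, fit$C, fit$B, fit$A, fit$Q, fit$Q0,
                              units = others)
      paths <- plds_sample_paths(est, n_samples)
      k <- tr$K[u, ]
      xb <- drop(tr$X %*% fit$B[u, ])
      D <- ncol(fit$C)
      Tt <- nrow(est$M)
      # ETA: samples x bins, vectorized over samples
      ETA <- matrix(0, n_samples, Tt)
      for (d in seq_len(D))
        ETA <- ETA + matrix(paths[, , d], n_samples, Tt) * fit$C[u, d]
      ETA <- sweep(ETA, 2, xb, `+`)
      lls <- drop(ETA %*% k) - rowSums(exp(ETA)) - sum(lgamma(k + 1))
      mx <- max(lls)
      tot <- tot + mx + log(mean(exp(lls - mx)))
    }
    out[u] <- tot
  }
  out
}

#' Per-unit pseudo-R^2 of the modulated-SR model against the SR null
#'
#' Uses leave-one-neuron-out predictive rates: for each unit the latent is
#' inferred from the remaining units and the unit's expected rate is
#' `exp(B s_t + C mu_t + 0.5 C' Sigma_t C)`. The SR model is the null and
#' the saturated model the upper reference.
#'
#' @param fit a `plds_fit`.
#' @param srfit the corresponding `sr_fit` (same design/bins).
#' @return Per-unit pseudo-R^2 gain vector (modulated-SR vs SR null).
#' @export
plds_pseudo_r2 <- function(fit, srfit) {
  U <- nrow(fit$C)
  out <- numeric(U)
  for (u in seq_len(U)) {
    others <- setdiff(seq_len(U), u)
    ll_m <- 0; ll_0 <- 0; ll_s <- 0
    for (tr in fit$trials) {
      est <- plds_estep_trial(tr, fit$C, fit$B, fit$A, fit$Q, fit$Q0,
                              units = others)
      cu <- fit$C[u, ]
      quad <- 0.5 * vapply(seq_len(nrow(est$M)), function(t)
        drop(cu %*% matrix(est$Sig[t, , ], fit$D, fit$D) %*% cu), numeric(1))
      eta <- drop(est$M %*% cu) + drop(tr$X %*% fit$B[u, ]) + quad
      k <- tr$K[u, ]
      ll_m <- ll_m + poisson_ll(k, eta)
      ll_0 <- ll_0 + poisson_ll(k, drop(tr$X %*% srfit$coef[u, ]))
      ll_s <- ll_s + poisson_ll_saturated(k)
    }
    out[u] <- pseudo_r2(ll_m, ll_0, ll_s)
  }
  out
}

#' Summaries of a fitted modulator
#'
#' Reports per-dimension time constants (`tau = -1 / log(A)` in bins,
#' converted to ms), the absolute modulator strength (the variance of the
#' estimated modulator — the posterior-mean path — times the coupling norm
#' `sqrt(sum C_n^2)`), and the relative strength (absolute strength divided
#' by the stimulus drive `sum_{n,i} Var(s_i B_{n,i})` over the fitted
#' design rows). Using the estimated path's variance (rather than the
#' normalized prior) makes the strength vanish when the data carry no
#' shared modulation.
#'
#' @param fit a `plds_fit`.
#' @return List with `tau_bins`, `tau_ms` (NA where the AR eigenvalue is
#'   not in (0, 1)), `absolute_strength`, `relative_strength`,
#'   `stimulus_drive`.
#' @export
modulator_summaries <- function(fit) {
  stopifnot(inherits(fit, "plds_fit"))
  ev <- Re(eigen(fit$A, only.values = TRUE)$values)
  tau_bins <- ifelse(ev > 0 & ev < 1, -1 / log(ev), NA_real_)
  M <- do.call(rbind, lapply(fit$posterior, function(e) e$M))
  var_m <- apply(M, 2, stats::var)
  abs_strength <- sum(var_m * sqrt(colSums(fit$C^2)))
  X <- fit$design$X[fitting_bins(fit$design), , drop = FALSE]
  vs <- apply(X, 2, stats::var)
  drive <- sum(sweep(fit$B^2, 2, vs, `*`))
  list(tau_bins = tau_bins, tau_ms = tau_bins * fit$bin_ms,
       absolute_strength = abs_strength,
       relative_strength = if (drive > 0) abs_strength / drive else NA_real_,
       stimulus_drive = drive)
}

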