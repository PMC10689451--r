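test_that("d' formula and degenerate cases", {
  set.seed(1)
  x0 <- rnorm(400, 10, 2); x1 <- rnorm(400, 14, 2)
  r <- dprime(x0, x1, n_perm = 200, seed = 2)
  expect_lt(abs(r$dprime - 2), 0.2)
  expect_lt(r$p_value, 0.01)
  # identical distributions: small d', non-small p
  x1b <- rnorm(400, 10, 2)
  r0 <- dprime(x0, x1b, n_perm = 200, seed = 3)
  expect_lt(r0$dprime, 0.2)
  expect_gt(r0$p_value, 0.05)
  expect_error(dprime(1, c(1, 2)), "at least 2")
})

test_that("choice-d' is symmetric in the outcome labels and detects constructed coupling", {
  set.seed(4)
  resp <- rnorm(200, 20, 4)
  hit <- resp > 20            # outcome generated by thresholding the response
  expect_gt(choice_dprime(resp[hit], resp[!hit]), 1)
  expect_equal(choice_dprime(resp[hit], resp[!hit]),
               choice_dprime(resp[!hit], resp[hit]))
  # outcome independent of response: near zero
  hit2 <- sample(c(TRUE, FALSE), 200, replace = TRUE)
  expect_lt(choice_dprime(resp[hit2], resp[!hit2]), 0.3)
})

test_that("partial correlation removes covariate-driven association", {
  set.seed(5)
  n <- 300
  rate <- runif(n, 1, 10)
  coupling <- 0.5 * rate + rnorm(n)              # coupling correlates with rate
  inform <- 0.5 * rate + 0.5 * coupling + rnorm(n)
  pc <- partial_correlation(inform, coupling, covariates = rate)
  expect_gt(pc$estimate, 0.2)
  expect_lt(pc$p_value, 0.001)
  # predictor independent given covariate -> near zero
  inform2 <- 0.8 * rate + rnorm(n)
  pc2 <- partial_correlation(inform2, coupling, covariates = rate)
  expect_lt(abs(pc2$estimate), 0.15)
  # empty covariate set reduces to ordinary Spearman
  pc3 <- partial_correlation(inform, coupling)
  expect_equal(pc3$estimate,
               unname(cor.test(inform, coupling, method = "spearman")$estimate),
               tolerance = 1e-10)
})

test_that("group comparisons behave at both extremes", {
  set.seed(6)
  x <- rnorm(30)
  r <- compare_groups(x, x, test = "ranksum")
  expect_gt(r$p_value, 0.9)
  y <- rnorm(30, 3)
  expect_lt(compare_groups(x, y, test = "t")$p_value, 1e-6)
  expect_error(compare_groups(1, x), "at least 2")
})

test_that("cross-correlogram finds constructed lags and respects trial boundaries", {
  set.seed(7)
  trial <- rep(1:20, each = 30)
  a <- rnorm(600)
  xc0 <- cross_correlogram(a, a, trial, max_lag = 5)
  expect_equal(xc0$peak_lag, 0)
  expect_equal(max(xc0$correlation), 1)
  # b = a shifted by +2 within trials
  b <- a
  for (tr in 1:20) {
    idx <- which(trial == tr)
    b[idx] <- c(rep(0, 2), a[idx[1:28]])
  }
  expect_equal(cross_correlogram(a, b, trial, max_lag = 5)$peak_lag, 2)
  # independent traces show no strong peak
  xcn <- cross_correlogram(a, rnorm(600), trial, max_lag = 5)
  expect_lt(max(abs(xcn$correlation)), 0.15)
  expect_error(cross_correlogram(a[1:10], a[1:10], rep(1, 10), max_lag = 20),
               "max_lag")
})

test_that("Fano factor: Poisson ~ 1, deterministic 0, modulated supra-Poisson", {
  set.seed(8)
  expect_lt(abs(fano_factor(rpois(4000, 5)) - 1), 0.1)
  expect_equal(fano_factor(rep(7, 10)), 0)
  # modulated counts are supra-Poisson, increasing with c*sigma
  f_of <- function(csig) {
    m <- rnorm(4000, 0, 1)
    k <- rpois(4000, 5 * exp(csig * m - csig^2 / 2))
    fano_factor(k)
  }
  f1 <- f_of(0.3); f2 <- f_of(0.8)
  expect_gt(f1, 1.1)
  expect_gt(f2, f1)
})

test_that("unit statistics table ties couplings to informativeness on targeted blocks", {
  blk <- make_targeted_block(n_trials = 40, seed = 51)
  fit <- suppressWarnings(fit_plds_em(blk$rec, D = 1, max_iter = 30))
  st <- unit_statistics(blk$rec, fit, n_perm = 300, seed = 52)
  expect_equal(nrow(st), dim(blk$rec$counts)[1])
  inf <- blk$pop$kind == "informative"
  expect_gt(mean(st$dprime[inf], na.rm = TRUE),
            mean(st$dprime[!inf], na.rm = TRUE))
  expect_gt(mean(st$coupling_rank[inf]), mean(st$coupling_rank[!inf]))
  pc <- partial_correlation(st$dprime, st$coupling,
                            covariates = st$mean_rate_hz)
  expect_gt(pc$estimate, 0.3)
})
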