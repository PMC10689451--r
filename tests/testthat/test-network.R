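test_that("parameter counts are consistent and match the full-scale decision layer", {
  full <- network_param_counts(network_config("full"))
  expect_identical(full$decision, 78410L + 0)     # (7840 + 1) x 10
  expect_identical(full$encoding_couplings, 2560)
  expect_identical(full$final_width, 7840)
  small <- network_param_counts(network_config("small"))
  expect_equal(small$total_weights, sum(small$processing) + small$decision)
  expect_equal(small$regimes$decision_layer_retraining, small$decision)
  expect_equal(small$regimes$stochastic_modulator, small$encoding_units)
  net <- build_network(network_config("small"), seed = 1)
  expect_equal(length(net$couplings), small$encoding_couplings)
  expect_equal(ncol(net$W2), small$final_width)
})

test_that("forward pass honors the modulation contract", {
  cfg <- network_config("small")
  net <- build_network(cfg, seed = 2)
  set.seed(3)
  S <- matrix(rnorm(cfg$input_side^2 * 3, 0, 0.3), ncol = 3)
  base <- forward(net, S, m = 0)
  # c = 0 everywhere: output independent of m
  expect_equal(forward(net, S, m = 1.3)$scores, base$scores, tolerance = 1e-12)
  # m = 0, g = 1 reproduces the unmodulated pass exactly
  expect_identical(forward(net, S, m = 0, gains = rep(1, net$H))$scores,
                   base$scores)
  # doubling one gain doubles that unit's contribution to every score
  g <- rep(1, net$H); g[5] <- 2
  delta <- forward(net, S, gains = g)$scores - base$scores
  expect_equal(delta, net$W2[, 5, drop = FALSE] %*% base$hL[5, , drop = FALSE],
               tolerance = 1e-10)
  # couplings shift coupled units only
  net2 <- net; net2$couplings[1:10] <- 0.5
  out2 <- forward(net2, S, m = 1)
  expect_false(isTRUE(all.equal(out2$scores, base$scores)))
})

test_that("the gain rule is the rectified modulator correlation", {
  set.seed(4)
  m <- rnorm(5000, 0, sqrt(0.1))
  # unit with activity 1 + m -> g converges to Var(m) = 0.1
  acts <- rbind(1 + m, rep(2, 5000), 1 - m)
  g <- mg_gain_rule(acts, m)
  expect_lt(abs(g[1] - 0.1), 0.015)
  expect_lt(g[2], 0.01)          # uncorrelated
  expect_equal(g[3], 0)          # negative correlation is rectified to 0
  expect_equal(mg_gain_rule(acts, rep(0, 5000)), c(0, 0, 0))
  expect_error(mg_gain_rule(acts[, 0, drop = FALSE], numeric(0)), "fast time step")
})

test_that("training stages enforce order and freeze the right components", {
  cfg <- network_config("small")
  net <- build_network(cfg, seed = 5)
  gl <- gen_glyphs(200, cfg, seed = 6)
  expect_error(train_stage(net, gl, "readout"), "cannot follow")
  net <- train_stage(net, gl, "pretrain", epochs = 1, lr = 0.05, seed = 7)
  W0_before <- net$W0
  gr <- gen_gratings(200, cfg, seed = 8)
  W1_before <- net$layers[[1]]$W[[1]]
  net <- train_stage(net, gr, "readout", epochs = 1, lr = 0.1, seed = 9)
  expect_identical(net$layers[[1]]$W[[1]], W1_before)  # processing frozen
  tk <- gen_binary_task(100, cfg, seed = 10)
  W2_before <- net$W2
  net <- train_stage(net, tk, "couplings", epochs = 1, batch = 10, lr = 0.5,
                     seed = 11)
  # couplings stage leaves every weight bit-identical, trains c only
  expect_identical(net$W2, W2_before)
  expect_identical(net$layers[[1]]$W[[1]], W1_before)
  expect_identical(net$W0, W0_before)
  expect_gt(max(abs(net$couplings)), 0)
})

test_that("learned couplings concentrate on task-informative encoding units", {
  cfg <- network_config("small")
  base <- build_network(cfg, seed = 12)
  gl <- gen_glyphs(1500, cfg, noise_sd = 0.2, seed = 13)
  base <- train_stage(base, gl, "pretrain", epochs = 25, lr = 0.05, seed = 14)
  gr <- gen_gratings(1500, cfg, seed = 15)
  base <- train_stage(base, gr, "readout", epochs = 4, lr = 0.1, seed = 16)
  tk <- gen_binary_task(1500, cfg, seed = 17)
  net <- train_stage(base, tk, "couplings", epochs = 1, batch = 10, lr = 1,
                     seed = 18)
  # d' of each encoding unit for the two task stimuli (no distractors)
  probe <- gen_binary_task(300, cfg, n_distractors = 0, noise_sd = 0.1,
                           seed = 19)
  H0 <- exp(pmin(net$W0 %*% probe$images, 30))
  dp <- apply(H0, 1, function(h)
    abs(mean(h[probe$labels == probe$orient_pair[1]]) -
        mean(h[probe$labels == probe$orient_pair[2]])) /
      sqrt(0.5 * (var(h[probe$labels == probe$orient_pair[1]]) +
                  var(h[probe$labels == probe$orient_pair[2]])) + 1e-12))
  top <- dp >= quantile(dp, 0.95)
  expect_gt(mean(abs(net$couplings[top])), 2 * mean(abs(net$couplings[!top])))
})
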