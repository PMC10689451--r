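# Hierarchical modulated network: a fixed Gabor encoding layer with
# multiplicative stochastic gain modulation, locally connected processing
# layers with rectification, and a decision layer whose inputs carry
# gain terms set by the modulator-correlation rule.
#
#   h^(0) = exp(W0 s + m_t c)          encoding (fixed filters, couplings c)
#   h^(l) = relu(W_l h^(l-1) + b_l)    locally connected processing
#   scores = W2 (g * h^(L)) + b2       decision layer, gains g >= 0
#   g_n    = (1/T) sum_t m_t h^(L)_{n,t}   (rectified)

# ---- geometry -------------------------------------------------------------

# evenly spaced patch centers of a locally connected layer
lc_centers <- function(in_n, out_n, patch) {
  half <- (patch - 1) / 2
  cs <- round(seq(1 + half, in_n - half, length.out = out_n))
  pmin(pmax(cs, 1 + half), in_n - half)
}

# input indices (into a position-major, channel-minor grid) for each output
# location of a locally connected layer
lc_patch_indices <- function(in_n, in_ch, out_n, patch) {
  cs <- lc_centers(in_n, out_n, patch)
  half <- (patch - 1) / 2
  idx <- vector("list", out_n * out_n)
  k <- 1
  for (oi in seq_len(out_n)) for (oj in seq_len(out_n)) {
    rows <- (cs[oi] - half):(cs[oi] + half)
    cols <- (cs[oj] - half):(cs[oj] + half)
    cells <- as.vector(outer(rows, cols, function(i, j) (i - 1) * in_n + (j - 1)))
    idx[[k]] <- as.vector(outer(seq_len(in_ch), cells * in_ch, `+`))
    k <- k + 1
  }
  idx
}

# ---- configuration --------------------------------------------------------

#' Network scale configuration
#'
#' `"small"` is the desk-scale configuration used throughout testing:
#' 28 x 28 input, a 7 x 7 grid of Gabor centers with 6 orientations
#' (294 encoding units), a 3 x 3 x 24 locally connected processing layer
#' (5 x 5-position patches), a fully mixing 48-unit second processing
#' layer, and a 10-way decision layer. `"full"` is the full-scale
#' configuration: 56 x 56 input
#' (3136 pixels), 16 x 16 x 10 = 2560 encoding units, two locally connected
#' processing layers ending in 28 x 28 x 10 = 7840 units, and a 10-way
#' decision layer with 78,410 trainable parameters.
#'
#' @param scale `"small"` or `"full"`.
#' @param ... overrides of individual fields.
#' @return A `network_config` list.
#' @export
network_config <- function(scale = c("small", "full"), ...) {
  scale <- match.arg(scale)
  cfg <- if (scale == "small") {
    list(scale = "small", input_side = 28, grid_n = 7, n_orient = 6,
         gabor_lambda = 6, gabor_sigma = 2.6, gabor_gamma = 0.8,
         encoding_gain = 1.5,
         layers = list(list(out_n = 3, patch = 5, channels = 24),
                       list(out_n = 1, patch = 3, channels = 48)),
         n_classes = 10)
  } else {
    list(scale = "full", input_side = 56, grid_n = 16, n_orient = 10,
         gabor_lambda = 8, gabor_sigma = 3.5, gabor_gamma = 0.8,
         encoding_gain = 1.5,
         layers = list(list(out_n = 14, patch = 5, channels = 16),
                       list(out_n = 28, patch = 3, channels = 10)),
         n_classes = 10)
  }
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "network_config")
}

#' Trainable-parameter counts per component and training regime
#'
#' @param cfg a `network_config`.
#' @return List with per-component counts (`encoding_couplings`,
#'   `processing` per layer, `decision`, `total_weights`) and per-regime
#'   counts (`stochastic_modulator`, `deterministic_modulator`,
#'   `decision_layer_retraining`, `weight_retraining`).
#' @export
network_param_counts <- function(cfg) {
  E <- cfg$grid_n^2 * cfg$n_orient
  in_n <- cfg$grid_n; in_ch <- cfg$n_orient
  proc <- integer(0)
  for (ly in cfg$layers) {
    n_inputs <- ly$patch^2 * in_ch
    n_units <- ly$out_n^2 * ly$channels
    proc <- c(proc, ly$out_n^2 * ly$channels * (n_inputs + 1))
    in_n <- ly$out_n; in_ch <- ly$channels
  }
  H <- in_n^2 * in_ch
  decision <- (H + 1) * cfg$n_classes
  list(encoding_units = E,
       encoding_couplings = E,
       processing = proc,
       final_width = H,
       decision = decision,
       total_weights = sum(proc) + decision,
       regimes = list(stochastic_modulator = E,
                      deterministic_modulator = E,
                      decision_layer_retraining = decision,
                      weight_retraining = sum(proc) + decision))
}

# ---- construction ---------------------------------------------------------

gabor_filter <- function(side, cx, cy, theta, lambda, sigma, gamma) {
  xs <- matrix(rep(seq_len(side), each = side), side) - cx
  ys <- matrix(rep(seq_len(side), side), side) - cy
  xr <- xs * cos(theta) + ys * sin(theta)
  yr <- -xs * sin(theta) + ys * cos(theta)
  g <- exp(-(xr^2 + gamma^2 * yr^2) / (2 * sigma^2)) * cos(2 * pi * xr / lambda)
  g <- g - mean(g) * (abs(g) > 0)          # remove DC
  v <- as.vector(g)
  v / sqrt(sum(v^2))
}

#' Build a modulated hierarchical network
#'
#' Constructs the fixed Gabor filter bank (orientations x a square grid of
#' receptive-field centers), zero couplings, randomly initialized locally
#' connected processing layers and a decision layer. Encoding weights are
#' immutable after construction.
#'
#' @param cfg a [network_config()].
#' @param seed RNG seed for weight initialization.
#' @return A `network_model`.
#' @export
build_network <- function(cfg, seed = 1) {
  set.seed(seed)
  side <- cfg$input_side
  half_pad <- (cfg$grid_n - 1)
  centers <- lc_centers(side, cfg$grid_n, patch = round(side / cfg$grid_n))
  thetas <- (seq_len(cfg$n_orient) - 1) * pi / cfg$n_orient
  E <- cfg$grid_n^2 * cfg$n_orient
  W0 <- matrix(0, E, side^2)
  k <- 1
  for (i in seq_len(cfg$grid_n)) for (j in seq_len(cfg$grid_n)) for (o in seq_len(cfg$n_orient)) {
    W0[k, ] <- gabor_filter(side, centers[i], centers[j], thetas[o],
                            cfg$gabor_lambda, cfg$gabor_sigma, cfg$gabor_gamma)
    k <- k + 1
  }
  W0 <- W0 * cfg$encoding_gain
  layers <- list()
  in_n <- cfg$grid_n; in_ch <- cfg$n_orient
  for (ly in cfg$layers) {
    idx <- lc_patch_indices(in_n, in_ch, ly$out_n, ly$patch)
    n_in <- length(idx[[1]])
    W <- lapply(idx, function(ii)
      matrix(stats::rnorm(ly$channels * n_in, 0, 1 / sqrt(n_in)), ly$channels))
    b <- lapply(idx, function(ii) numeric(ly$channels))
    layers[[length(layers) + 1]] <- list(idx = idx, W = W, b = b,
                                         out_n = ly$out_n, channels = ly$channels)
    in_n <- ly$out_n; in_ch <- ly$channels
  }
  H <- in_n^2 * in_ch
  structure(list(cfg = cfg, W0 = W0, couplings = numeric(E),
                 layers = layers, H = H,
                 W2 = matrix(stats::rnorm(cfg$n_classes * H, 0, 0.01), cfg$n_classes),
                 b2 = numeric(cfg$n_classes),
                 counts = network_param_counts(cfg),
                 stage = "built"),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("<network_model> %s scale: %d px -> %d encoding -> %s -> %d classes (stage: %s)\n",
              x$cfg$scale, x$cfg$input_side^2, nrow(x$W0),
              paste(vapply(x$layers, function(l) l$out_n^2 * l$channels, numeric(1)),
                    collapse = " -> "),
              x$cfg$n_classes, x$stage))
  invisible(x)
}

# ---- forward / backward ---------------------------------------------------

# forward pass on a pixel batch S (npix x B); m is a scalar or length-B
# vector of modulator values; gains (length H) multiply the final
# processing layer before the decision weights
network_forward <- function(net, S, m = 0, gains = NULL, keep = FALSE) {
  u <- net$W0 %*% S
  if (length(m) == 1 && m == 0 && all(net$couplings == 0)) {
    h <- exp(pmin(u, 30))
  } else {
    h <- exp(pmin(u + outer(net$couplings, rep_len(m, ncol(S))), 30))
  }
  acts <- list(h0 = h)
  x <- h
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    nloc <- length(ly$idx)
    Z <- matrix(0, nloc * ly$channels, ncol(S))
    for (k in seq_len(nloc)) {
      rows <- ((k - 1) * ly$channels + 1):(k * ly$channels)
      Z[rows, ] <- ly$W[[k]] %*% x[ly$idx[[k]], , drop = FALSE] + ly$b[[k]]
    }
    if (keep) acts[[paste0("z", l)]] <- Z
    x <- pmax(Z, 0)
    if (keep) acts[[paste0("h", l)]] <- x
  }
  hL <- x
  if (!is.null(gains)) x <- x * gains
  scores <- net$W2 %*% x + net$b2
  if (keep) { acts$hL <- hL; acts$scores <- scores; return(acts) }
  list(hL = hL, scores = scores)
}

#' Forward pass of the modulated network
#'
#' @param net a `network_model`.
#' @param images pixel matrix (npix x batch) or a single image vector.
#' @param m modulator value (scalar or per-image vector).
#' @param gains optional non-negative gain vector on the final processing
#'   layer.
#' @return List with `hL` (final processing-layer activity) and `scores`
#'   (class scores).
#' @export
forward <- function(net, images, m = 0, gains = NULL) {
  if (is.null(dim(images))) images <- matrix(images, ncol = 1)
  network_forward(net, images, m = m, gains = gains)
}

#' Modulator-correlation gain rule
#'
#' `g_n = (1/T) sum_t m_t h_{n,t}` over the fast time steps, rectified at
#' zero.
#'
#' @param activities units x T matrix of final processing-layer activity.
#' @param modulator length-T modulator trace.
#' @return Non-negative gain vector.
#' @export
mg_gain_rule <- function(activities, modulator) {
  Tt <- length(modulator)
  if (Tt == 0) stop("need at least one fast time step")
  stopifnot(ncol(activities) == Tt)
  pmax(drop(activities %*% modulator) / Tt, 0)
}

# gains per stimulus from a fast-phase batch: H (units x B*T), M (T x B)
fast_phase_gains <- function(net, U, M) {
  B <- ncol(M); Tt <- nrow(M)
  h <- exp(pmin(U[, rep(seq_len(B), each = Tt), drop = FALSE] +
                  outer(net$couplings, as.vector(M)), 30))
  x <- h
  for (ly in net$layers) {
    nloc <- length(ly$idx)
    Z <- matrix(0, nloc * ly$channels, ncol(x))
    for (k in seq_len(nloc)) {
      rows <- ((k - 1) * ly$channels + 1):(k * ly$channels)
      Z[rows, ] <- ly$W[[k]] %*% x[ly$idx[[k]], , drop = FALSE] + ly$b[[k]]
    }
    x <- pmax(Z, 0)
  }
  H <- nrow(x)
  G <- matrix(0, H, B)
  for (b in seq_len(B)) {
    cols <- ((b - 1) * Tt + 1):(b * Tt)
    G[, b] <- pmax(x[, cols, drop = FALSE] %*% M[, b] / Tt, 0)
  }
  list(gains = G, hL = x)
}

# ---- synthetic task datasets ----------------------------------------------

# 7-segment style glyph templates on a 12 x 12 stamp (2-px strokes),
# 10 classes
glyph_stamp <- function(class_id) {
  seg <- matrix(0, 12, 12)
  on <- list(a = expand.grid(1:2, 3:10), b = expand.grid(2:6, 9:10),
             c = expand.grid(7:11, 9:10), d = expand.grid(11:12, 3:10),
             e = expand.grid(7:11, 3:4), f = expand.grid(2:6, 3:4),
             g = expand.grid(6:7, 3:10))
  segs <- switch(class_id,
    c("a", "b", "c", "d", "e", "f"),        # 0
    c("b", "c"),                             # 1
    c("a", "b", "g", "e", "d"),              # 2
    c("a", "b", "g", "c", "d"),              # 3
    c("f", "g", "b", "c"),                   # 4
    c("a", "f", "g", "c", "d"),              # 5
    c("a", "f", "g", "e", "c", "d"),         # 6
    c("a", "b", "c"),                        # 7
    c("a", "b", "c", "d", "e", "f", "g"),    # 8
    c("a", "b", "c", "d", "f", "g"))         # 9
  for (s in segs) {
    co <- on[[s]]
    for (r in seq_len(nrow(co))) {
      ii <- co[r, 1]; jj <- co[r, 2]
      seg[ii, jj] <- 1
    }
  }
  seg
}

place_stamp <- function(canvas_side, stamp, top, left) {
  img <- matrix(0, canvas_side, canvas_side)
  rows <- top:(top + nrow(stamp) - 1)
  cols <- left:(left + ncol(stamp) - 1)
  img[rows, cols] <- stamp
  img
}

#' Generate positioned glyph-classification images
#'
#' Ten procedurally generated glyph classes (segment-stroke digit stand-ins)
#' placed at random positions with additive Gaussian pixel noise; the
#' pretraining task of the hierarchical network.
#'
#' @param n number of images.
#' @param cfg a `network_config` (for the canvas size).
#' @param noise_sd pixel noise SD.
#' @param seed RNG seed.
#' @return List with `images` (npix x n) and `labels` (1..10).
#' @export
gen_glyphs <- function(n, cfg, noise_sd = 0.3, seed = 1) {
  set.seed(seed)
  side <- cfg$input_side
  stamps <- lapply(1:10, glyph_stamp)
  labels <- sample.int(10, n, replace = TRUE)
  X <- matrix(0, side^2, n)
  maxoff <- side - 12 + 1
  for (i in seq_len(n)) {
    top <- sample.int(maxoff, 1); left <- sample.int(maxoff, 1)
    img <- place_stamp(side, stamps[[labels[i]]], top, left)
    X[, i] <- as.vector(img) + stats::rnorm(side^2, 0, noise_sd)
  }
  list(images = X, labels = labels)
}

# windowed grating image centered at (cx, cy)
grating_patch <- function(side, cx, cy, theta, lambda, sigma, contrast = 1) {
  xs <- matrix(rep(seq_len(side), each = side), side) - cx
  ys <- matrix(rep(seq_len(side), side), side) - cy
  xr <- xs * cos(theta) + ys * sin(theta)
  env <- exp(-(xs^2 + ys^2) / (2 * sigma^2))
  contrast * env * cos(2 * pi * xr / lambda)
}

#' Generate positioned-orientation grating images
#'
#' Single local oriented gratings at positions of the encoding grid, with
#' `n_classes` orientation categories; the readout-training task.
#'
#' @param n number of images.
#' @param cfg a `network_config`.
#' @param n_classes orientation classes (default 10).
#' @param noise_sd pixel noise SD.
#' @param seed RNG seed.
#' @return List with `images`, `labels` (orientation class 1..n_classes),
#'   `positions` (grid row/col).
#' @export
gen_gratings <- function(n, cfg, n_classes = 10, noise_sd = 0.1, seed = 1) {
  set.seed(seed)
  side <- cfg$input_side
  centers <- lc_centers(side, cfg$grid_n, patch = round(side / cfg$grid_n))
  labels <- sample.int(n_classes, n, replace = TRUE)
  pos <- cbind(sample.int(cfg$grid_n, n, replace = TRUE),
               sample.int(cfg$grid_n, n, replace = TRUE))
  X <- matrix(0, side^2, n)
  for (i in seq_len(n)) {
    th <- (labels[i] - 1) * pi / n_classes
    img <- grating_patch(side, centers[pos[i, 1]], centers[pos[i, 2]], th,
                         cfg$gabor_lambda, cfg$gabor_sigma * 1.3)
    X[, i] <- as.vector(img) + stats::rnorm(side^2, 0, noise_sd)
  }
  list(images = X, labels = labels, positions = pos)
}

#' Generate the binary orientation task with distractors
#'
#' A target grating at a fixed grid location takes one of two orientation
#' classes; distractor gratings with random orientations appear at other
#' locations at the same contrast.
#'
#' @param n number of images.
#' @param cfg a `network_config`.
#' @param task_pos target grid position `c(row, col)` (default center).
#' @param orient_pair the two orientation class labels (of the 10-way
#'   readout) to discriminate.
#' @param n_distractors distractor gratings per image.
#' @param distractor_classes orientation classes the distractors draw from
#'   (default: the task pair itself, the hardest case — only the location
#'   distinguishes target from distractor evidence).
#' @param distractor_contrast contrast of distractor gratings relative to
#'   the target.
#' @param n_classes orientation classes of the readout.
#' @param noise_sd pixel noise SD.
#' @param seed RNG seed.
#' @return List with `images`, `labels` (values in `orient_pair`),
#'   `task_pos`.
#' @export
gen_binary_task <- function(n, cfg, task_pos = NULL, orient_pair = c(3, 8),
                            n_distractors = 6, distractor_classes = orient_pair,
                            distractor_contrast = 1.2,
                            n_classes = 10, noise_sd = 0.1, seed = 1) {
  set.seed(seed)
  side <- cfg$input_side
  g <- cfg$grid_n
  centers <- lc_centers(side, g, patch = round(side / g))
  if (is.null(task_pos)) task_pos <- c(ceiling(g / 2), ceiling(g / 2))
  labels <- sample(orient_pair, n, replace = TRUE)
  X <- matrix(0, side^2, n)
  allpos <- expand.grid(r = seq_len(g), c = seq_len(g))
  far <- abs(allpos$r - task_pos[1]) + abs(allpos$c - task_pos[2]) >= 2
  dist_pool <- which(far)
  for (i in seq_len(n)) {
    th <- (labels[i] - 1) * pi / n_classes
    img <- grating_patch(side, centers[task_pos[1]], centers[task_pos[2]], th,
                         cfg$gabor_lambda, cfg$gabor_sigma * 1.3)
    dp <- sample(dist_pool, n_distractors)
    for (d in dp) {
      thd <- (sample(distractor_classes, 1) - 1) * pi / n_classes
      img <- img + grating_patch(side, centers[allpos$r[d]], centers[allpos$c[d]],
                                 thd, cfg$gabor_lambda, cfg$gabor_sigma * 1.3,
                                 contrast = distractor_contrast)
    }
    X[, i] <- as.vector(img) + stats::rnorm(side^2, 0, noise_sd)
  }
  list(images = X, labels = labels, task_pos = task_pos,
       orient_pair = orient_pair)
}

# ---- training -------------------------------------------------------------

softmax_ce_grad <- function(scores, labels) {
  # scores: classes x B; labels in 1..classes
  mx <- apply(scores, 2, max)
  ex <- exp(sweep(scores, 2, mx))
  prb <- sweep(ex, 2, colSums(ex), `/`)
  Y <- matrix(0, nrow(scores), ncol(scores))
  Y[cbind(labels, seq_len(ncol(scores)))] <- 1
  list(loss = -mean(log(pmax(prb[cbind(labels, seq_len(ncol(scores)))], 1e-12))),
       dscore = (prb - Y) / ncol(scores))
}

# backprop one minibatch through processing + decision layers; returns
# gradients for the requested components
network_backprop <- function(net, S, labels, classes = NULL, gains = NULL,
                             m = 0, want = c("W1", "W2", "c")) {
  acts <- network_forward(net, S, m = m, gains = gains, keep = TRUE)
  scores <- acts$scores
  if (!is.null(classes)) {
    sub <- scores[classes, , drop = FALSE]
    lab <- match(labels, classes)
    sg <- softmax_ce_grad(sub, lab)
    dscore <- matrix(0, nrow(scores), ncol(scores))
    dscore[classes, ] <- sg$dscore
    loss <- sg$loss
  } else {
    sg <- softmax_ce_grad(scores, labels)
    dscore <- sg$dscore
    loss <- sg$loss
  }
  L <- length(net$layers)
  htop <- if (is.null(gains)) acts[[paste0("h", L)]] else acts[[paste0("h", L)]] * gains
  gr <- list(loss = loss)
  if ("W2" %in% want) {
    gr$dW2 <- dscore %*% t(htop)
    gr$db2 <- rowSums(dscore)
  }
  dh <- t(net$W2) %*% dscore
  if (!is.null(gains)) dh <- dh * gains
  need_below <- any(c("W1", "c") %in% want)
  if (need_below) {
    gr$dW1 <- vector("list", L)
    for (l in L:1) {
      ly <- net$layers[[l]]
      Z <- acts[[paste0("z", l)]]
      dz <- dh * (Z > 0)
      xin <- if (l == 1) acts$h0 else acts[[paste0("h", l - 1)]]
      nloc <- length(ly$idx)
      if ("W1" %in% want) {
        dW <- vector("list", nloc); db <- vector("list", nloc)
      }
      dx <- matrix(0, nrow(xin), ncol(xin))
      for (k in seq_len(nloc)) {
        rows <- ((k - 1) * ly$channels + 1):(k * ly$channels)
        dzk <- dz[rows, , drop = FALSE]
        if ("W1" %in% want) {
          dW[[k]] <- dzk %*% t(xin[ly$idx[[k]], , drop = FALSE])
          db[[k]] <- rowSums(dzk)
        }
        dx[ly$idx[[k]], ] <- dx[ly$idx[[k]], ] + t(ly$W[[k]]) %*% dzk
      }
      if ("W1" %in% want) { gr$dW1[[l]] <- dW; gr$db1[[l]] <- db }
      dh <- dx
    }
    if ("c" %in% want) {
      # dh is now the gradient wrt h0; dh0/dc = m * h0
      gr$dc <- rowSums(dh * acts$h0) * (if (length(m) == 1) m else 1)
    }
  }
  gr
}

#' Train one stage of the hierarchical network
#'
#' The three-stage protocol: (1) `"pretrain"` — gradient training of the
#' processing and decision weights on glyph classification with additive
#' pixel noise and an L1 penalty of 0.001 (couplings frozen at 0,
#' modulator off); (2) `"readout"` — a fresh 10-way orientation readout
#' trained on positioned gratings with everything else frozen;
#' (3) `"couplings"` — only the encoding couplings are trained, by gradient
#' descent of the binary-task loss at the slow scale (m = 1), while the
#' decision-layer gains are set each step by [mg_gain_rule()] at the fast
#' scale (`m_t ~ N(0, 0.1)`, 100 steps per stimulus). Stage order is
#' enforced.
#'
#' @param net a `network_model`.
#' @param data dataset from [gen_glyphs()], [gen_gratings()] or
#'   [gen_binary_task()], matching the stage.
#' @param stage `"pretrain"`, `"readout"` or `"couplings"`.
#' @param epochs passes over the data.
#' @param batch minibatch size.
#' @param lr learning rate.
#' @param l1 L1 penalty (pretrain and weight retraining).
#' @param fast_T fast time steps per stimulus (couplings stage).
#' @param fast_var modulator variance at the fast scale (default 0.1).
#' @param seed RNG seed (minibatch order, fast modulator draws).
#' @return The trained network with a `history` attribute (loss per epoch).
#' @export
train_stage <- function(net, data, stage = c("pretrain", "readout", "couplings"),
                        epochs = 3, batch = 32, lr = 0.1, l1 = 0.001,
                        fast_T = 100, fast_var = 0.1, seed = 1) {
  stage <- match.arg(stage)
  order_ok <- switch(stage,
    pretrain = net$stage == "built",
    readout = net$stage == "pretrained",
    couplings = net$stage == "readout")
  if (!order_ok)
    stop(sprintf("stage '%s' cannot follow stage '%s'", stage, net$stage))
  set.seed(seed)
  n <- length(data$labels)
  history <- numeric(0)
  if (stage == "readout") {
    net$W2 <- matrix(stats::rnorm(net$cfg$n_classes * net$H, 0, 0.01),
                     net$cfg$n_classes)
    net$b2 <- numeric(net$cfg$n_classes)
  }
  classes <- if (stage == "couplings") data$orient_pair else NULL
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1, n, by = batch)) {
      ii <- ord[start:min(start + batch - 1, n)]
      S <- data$images[, ii, drop = FALSE]
      lab <- data$labels[ii]
      if (stage == "pretrain") {
        gr <- network_backprop(net, S, lab, want = c("W1", "W2"))
        for (l in seq_along(net$layers)) {
          for (k in seq_along(net$layers[[l]]$W)) {
            W <- net$layers[[l]]$W[[k]]
            net$layers[[l]]$W[[k]] <- W - lr * gr$dW1[[l]][[k]] -
              lr * l1 * sign(W)
            net$layers[[l]]$b[[k]] <- net$layers[[l]]$b[[k]] - lr * gr$db1[[l]][[k]]
          }
        }
        net$W2 <- net$W2 - lr * gr$dW2 - lr * l1 * sign(net$W2)
        net$b2 <- net$b2 - lr * gr$db2
      } else if (stage == "readout") {
        gr <- network_backprop(net, S, lab, want = "W2")
        net$W2 <- net$W2 - lr * gr$dW2
        net$b2 <- net$b2 - lr * gr$db2
      } else {
        if (is.null(net$samples_seen)) net$samples_seen <- 0
        lr_c <- lr / (1 + net$samples_seen / 1000)
        net$samples_seen <- net$samples_seen + length(ii)
        net <- couplings_update(net, S, lab, classes, lr_c,
                                fast_T = fast_T, fast_var = fast_var)
        gr <- list(loss = NA_real_)
      }
      losses <- c(losses, gr$loss)
    }
    history <- c(history, mean(losses))
  }
  net$stage <- switch(stage, pretrain = "pretrained", readout = "readout",
                      couplings = "couplings")
  attr(net, "history") <- history
  net
}

#' Evaluate network accuracy on a labeled set
#'
#' @param net a `network_model`.
#' @param data dataset list with `images`, `labels` and (for binary tasks)
#'   `orient_pair`.
#' @param mode `"plain"` (m = 0, unit gains), `"stochastic"` (fast-phase
#'   modulation with MG gains, scores averaged over fast steps) or
#'   `"deterministic"` (m = 1 constant, unit gains).
#' @param fast_T,fast_var fast-phase parameters for the stochastic mode.
#' @param chunk stimuli per evaluation block.
#' @param seed RNG seed for the fast-phase draws.
#' @return Classification accuracy in [0, 1].
#' @export
evaluate_network <- function(net, data, mode = c("plain", "stochastic",
                                                 "deterministic"),
                             fast_T = 100, fast_var = 0.1, chunk = 64,
                             seed = 1) {
  mode <- match.arg(mode)
  set.seed(seed)
  classes <- if (!is.null(data$orient_pair)) data$orient_pair
             else seq_len(net$cfg$n_classes)
  n <- length(data$labels)
  correct <- 0
  for (start in seq(1, n, by = chunk)) {
    ii <- start:min(start + chunk - 1, n)
    S <- data$images[, ii, drop = FALSE]
    if (mode == "plain") {
      sc <- network_forward(net, S)$scores
    } else if (mode == "deterministic") {
      sc <- network_forward(net, S, m = 1)$scores
    } else {
      # task-engaged operation: slow baseline m = 1 with the task-level
      # gains accumulated by the MG rule during coupling training; without
      # stored gains they are estimated on the fly from the fast phase
      if (!is.null(net$gains_bar)) {
        sc <- network_forward(net, S, m = 1,
                              gains = normalize_gains(net$gains_bar))$scores
      } else {
        B <- ncol(S)
        U <- net$W0 %*% S
        D <- matrix(stats::rnorm(fast_T * B, 0, sqrt(fast_var)), fast_T, B)
        fp <- fast_phase_gains(net, U, 1 + D)
        sc <- matrix(0, net$cfg$n_classes, B)
        for (b in seq_len(B)) {
          cols <- ((b - 1) * fast_T + 1):(b * fast_T)
          g <- normalize_gains(mg_gain_rule(fp$hL[, cols, drop = FALSE], D[, b]))
          hbar <- rowMeans(fp$hL[, cols, drop = FALSE])
          sc[, b] <- net$W2 %*% (g * hbar) + net$b2
        }
      }
    }
    pred <- classes[apply(sc[classes, , drop = FALSE], 2, which.max)]
    correct <- correct + sum(pred == data$labels[ii])
  }
  correct / n
}

#' Compare fine-tuning strategies on the distractor task
#'
#' Starting from one pretrained network per seed, trains each variant
#' online on the binary orientation-with-distractors task and records
#' held-out accuracy at checkpoint training sizes:
#' `"stochastic-modulator"` (couplings by backprop, gains by the MG rule),
#' `"deterministic-modulator"` (m = 1 constant, couplings by backprop),
#' `"weight-retraining"` (all processing + decision weights),
#' `"decision-layer-retraining"` (decision layer only).
#'
#' @param cfg a `network_config`.
#' @param variants subset of the four variant names.
#' @param checkpoints cumulative training-sample counts at which to
#'   evaluate.
#' @param n_eval held-out evaluation set size.
#' @param seeds RNG seeds (one run per seed).
#' @param pretrain_n,readout_n sample sizes for the two preparatory stages.
#' @param criterion accuracy criterion for samples-to-criterion.
#' @param lr_couplings,lr_weights learning rates.
#' @param ... passed to [gen_binary_task()].
#' @return List with `curves` (data frame: variant, seed, samples,
#'   accuracy) and `samples_to_criterion` (data frame: variant, seed,
#'   samples, NA when never reached).
#' @export
run_comparison <- function(cfg,
                           variants = c("stochastic-modulator",
                                        "weight-retraining",
                                        "decision-layer-retraining",
                                        "deterministic-modulator"),
                           checkpoints = c(250, 500, 1000, 2000, 4000),
                           n_eval = 400, seeds = 1:3,
                           pretrain_n = 3000, readout_n = 3000,
                           criterion = 0.8,
                           lr_couplings = 1, lr_weights = 0.01, ...) {
  curves <- list()
  for (sd_i in seeds) {
    base <- build_network(cfg, seed = sd_i)
    glyphs <- gen_glyphs(pretrain_n, cfg, noise_sd = 0.2, seed = 100 + sd_i)
    base <- train_stage(base, glyphs, "pretrain", epochs = 50, lr = 0.05,
                        seed = 200 + sd_i)
    grat <- gen_gratings(readout_n, cfg, seed = 300 + sd_i)
    base <- train_stage(base, grat, "readout", epochs = 6, lr = 0.1,
                        seed = 400 + sd_i)
    task_train <- gen_binary_task(max(checkpoints), cfg, seed = 500 + sd_i, ...)
    task_test <- gen_binary_task(n_eval, cfg, seed = 600 + sd_i, ...)
    for (v in variants) {
      net <- base
      prev <- 0
      for (cp in checkpoints) {
        ii <- (prev + 1):cp
        seg <- list(images = task_train$images[, ii, drop = FALSE],
                    labels = task_train$labels[ii],
                    orient_pair = task_train$orient_pair)
        net <- train_comparison_segment(net, seg, v,
                                        lr_couplings = lr_couplings,
                                        lr_weights = lr_weights,
                                        seed = 700 + sd_i * 13 + cp)
        accu <- evaluate_network(net, task_test,
          mode = switch(v,
            "stochastic-modulator" = "stochastic",
            "deterministic-modulator" = "deterministic",
            "plain"),
          seed = 800 + sd_i)
        curves[[length(curves) + 1]] <- data.frame(
          variant = v, seed = sd_i, samples = cp, accuracy = accu,
          stringsAsFactors = FALSE)
        prev <- cp
      }
    }
  }
  curves <- do.call(rbind, curves)
  stc <- do.call(rbind, lapply(split(curves, curves[c("variant", "seed")]),
    function(d) {
      hit <- d$samples[d$accuracy > criterion]
      data.frame(variant = d$variant[1], seed = d$seed[1],
                 samples = if (length(hit)) min(hit) else NA_integer_,
                 stringsAsFactors = FALSE)
    }))
  rownames(stc) <- NULL
  list(curves = curves, samples_to_criterion = stc)
}

# One coupling-training step of the stochastic-modulator regime. The fast
# phase runs 100 modulator steps per stimulus, m_t = 1 + delta_t with
# delta_t ~ N(0, 0.1), riding on the task-engaged slow baseline m = 1. Gains
# are estimated from the delta-activity correlations (the MG rule) and
# smoothed across stimuli into a running task-level gain vector, which
# gates the decision layer in the slow pass where the couplings' gradient
# is computed.
couplings_update <- function(net, S, lab, classes, lr, fast_T = 100,
                             fast_var = 0.1, ema = 0.05) {
  if (is.null(net$gains_bar)) net$gains_bar <- rep(1, net$H)
  U <- net$W0 %*% S
  D <- matrix(stats::rnorm(fast_T * ncol(S), 0, sqrt(fast_var)), fast_T, ncol(S))
  fp <- fast_phase_gains(net, U, 1 + D)
  G <- vapply(seq_len(ncol(S)), function(b)
    mg_gain_rule(fp$hL[, ((b - 1) * fast_T + 1):(b * fast_T), drop = FALSE],
                 D[, b]),
    numeric(net$H))
  net$gains_bar <- (1 - ema) * net$gains_bar + ema * rowMeans(matrix(G, net$H))
  gn <- normalize_gains(net$gains_bar)
  gr <- network_backprop(net, S, lab, classes = classes, gains = gn,
                         m = 1, want = "c")
  net$couplings <- clamp_couplings(net$couplings - lr * clip_grad(gr$dc))
  net
}

normalize_gains <- function(g) {
  if (mean(g) > 0) g / mean(g) else rep(1, length(g))
}

# couplings are gain exponents around the task-engaged baseline: kept in a
# bounded range with a bounded gradient step (the exponential link
# otherwise allows runaway). Negative values act as suppression of
# task-irrelevant channels.
clamp_couplings <- function(cc, cmax = 8) pmin(pmax(cc, -cmax), cmax)
clip_grad <- function(g, gmax = 5) {
  nrm <- sqrt(sum(g^2))
  if (is.finite(nrm) && nrm > gmax) g * gmax / nrm else g
}

# one online training segment for a comparison variant; coupling learning
# uses a 1/(1 + t) step decay over cumulative samples for stability
train_comparison_segment <- function(net, seg, variant, lr_couplings, lr_weights,
                                     seed = 1, batch = 10) {
  set.seed(seed)
  n <- length(seg$labels)
  classes <- seg$orient_pair
  if (is.null(net$samples_seen)) net$samples_seen <- 0
  for (start in seq(1, n, by = batch)) {
    ii <- start:min(start + batch - 1, n)
    S <- seg$images[, ii, drop = FALSE]
    lab <- seg$labels[ii]
    lr_c <- lr_couplings / (1 + net$samples_seen / 1000)
    net$samples_seen <- net$samples_seen + length(ii)
    if (variant == "stochastic-modulator") {
      net <- couplings_update(net, S, lab, classes, lr_c)
    } else if (variant == "deterministic-modulator") {
      gr <- network_backprop(net, S, lab, classes = classes, m = 1, want = "c")
      net$couplings <- clamp_couplings(net$couplings - lr_c * clip_grad(gr$dc))
    } else if (variant == "weight-retraining") {
      gr <- network_backprop(net, S, lab, classes = classes,
                             want = c("W1", "W2"))
      for (l in seq_along(net$layers)) for (k in seq_along(net$layers[[l]]$W)) {
        W <- net$layers[[l]]$W[[k]]
        net$layers[[l]]$W[[k]] <- W - lr_weights * clip_grad(gr$dW1[[l]][[k]], 1) -
          lr_weights * 0.001 * sign(W)
        net$layers[[l]]$b[[k]] <- net$layers[[l]]$b[[k]] -
          lr_weights * clip_grad(gr$db1[[l]][[k]], 1)
      }
      net$W2 <- net$W2 - lr_weights * clip_grad(gr$dW2, 1) -
        lr_weights * 0.001 * sign(net$W2)
      net$b2 <- net$b2 - lr_weights * clip_grad(gr$db2, 1)
    } else if (variant == "decision-layer-retraining") {
      gr <- network_backprop(net, S, lab, classes = classes, want = "W2")
      net$W2 <- net$W2 - lr_weights * clip_grad(gr$dW2, 1) -
        lr_weights * 0.001 * sign(net$W2)
      net$b2 <- net$b2 - lr_weights * clip_grad(gr$db2, 1)
    } else stop("unknown variant: ", variant)
  }
  net
}
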