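# Stimulus-response design construction.
#
# The SR design parametrizes the within-presentation stimulus transient with
# contrast-specific one-hot time windows (4 windows over the 200 ms
# presentation at 50 ms bins), an after-stimulus dimension for the
# inter-stimulus bins, and a constant offset. The downstream (MT-like)
# variant adds a drift-direction indicator; an external modulator covariate
# can be appended as a normalized column.

v1_design_names <- function(n_win) {
  c(paste0("hc_w", seq_len(n_win)), paste0("lc_w", seq_len(n_win)),
    "after_stim", "offset")
}

# design rows for a sequence of presentations; rows are presentation-major,
# bin-minor, matching flatten_counts()
block_design_rows <- function(contrast, Tb, bins_on, drift_dir = NULL) {
  n_win <- bins_on
  P <- length(contrast)
  k <- 2 * n_win + 2 + (!is.null(drift_dir))
  X <- matrix(0, P * Tb, k)
  nm <- v1_design_names(n_win)
  if (!is.null(drift_dir)) nm <- c(nm, "drift_right")
  colnames(X) <- nm
  bin_in_pres <- rep(seq_len(Tb), P)
  pres_of_bin <- rep(seq_len(P), each = Tb)
  on <- bin_in_pres <= bins_on
  win <- bin_in_pres
  hc <- contrast[pres_of_bin] == "high"
  for (w in seq_len(n_win)) {
    X[on & win == w & hc, w] <- 1
    X[on & win == w & !hc, n_win + w] <- 1
  }
  X[!on, "after_stim"] <- 1
  X[, "offset"] <- 1
  if (!is.null(drift_dir))
    X[on & (drift_dir[pres_of_bin] == "right"), "drift_right"] <- 1
  X
}

# units x (P*Tb) count matrix, time-ordered to match design rows
flatten_counts <- function(rec) {
  d <- dim(rec$counts)
  matrix(aperm(rec$counts, c(1, 3, 2)), d[1], d[2] * d[3])
}

#' Build the stimulus-response design matrix for a recording
#'
#' Maps every bin of every presentation to a design row: stimulus-on bins
#' get a contrast-specific one-hot time-window indicator, inter-stimulus
#' bins get the after-stimulus indicator, and the offset is always 1. For
#' downstream recordings (or `drift = TRUE`) a drift-direction indicator is
#' added; a modulator trace can be appended as a z-scored covariate.
#'
#' @param rec a `population_recording`.
#' @param drift include the drift-direction column (default: TRUE for
#'   downstream recordings with a `drift_dir` metadata column).
#' @param modulator optional P x T_b modulator matrix appended as a
#'   normalized (z-scored) covariate column.
#' @return A list of class `sr_design`: `X` (rows = P*Tb, presentation-major
#'   bin-minor), `n_win`, `names`, and logical row masks `on_bin`,
#'   `target_bin`.
#' @export
build_design_matrix <- function(rec, drift = NULL, modulator = NULL) {
  stopifnot(inherits(rec, "population_recording"))
  Tb <- dim(rec$counts)[3]
  P <- dim(rec$counts)[2]
  if (!all(rec$meta$contrast %in% c("high", "low")))
    stop("unknown contrast level in metadata")
  if (is.null(drift))
    drift <- rec$area == "downstream" && !is.null(rec$meta$drift_dir)
  drift_dir <- if (drift) {
    if (is.null(rec$meta$drift_dir))
      stop("drift = TRUE but metadata has no drift_dir column")
    rec$meta$drift_dir
  } else NULL
  X <- block_design_rows(rec$meta$contrast, Tb, rec$bins_on, drift_dir)
  if (!is.null(modulator)) {
    if (!all(dim(modulator) == c(P, Tb)))
      stop("modulator length does not match the recording's bin grid")
    mvec <- as.vector(t(modulator))
    mvec <- (mvec - mean(mvec)) / stats::sd(mvec)
    X <- cbind(X, modulator = mvec)
  }
  bin_in_pres <- rep(seq_len(Tb), P)
  on_bin <- bin_in_pres <= rec$bins_on
  target_bin <- rep(rec$meta$stimulus == 1L, each = Tb)
  structure(list(X = X, n_win = rec$bins_on, names = colnames(X),
                 on_bin = on_bin, target_bin = target_bin,
                 P = P, Tb = Tb),
            class = "sr_design")
}

# default bins used for model fitting: all bins of non-target presentations
# (target responses are reserved for informativeness and decoding)
fitting_bins <- function(design, include_target = FALSE) {
  if (include_target) rep(TRUE, nrow(design$X)) else !design$target_bin
}
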