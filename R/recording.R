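#' Binned population recording
#'
#' Construct a `population_recording`, the common currency of all analysis
#' stages: a 3-d array of non-negative integer spike counts
#' (units x presentations x time bins) together with per-presentation
#' metadata describing the task structure.
#'
#' Each presentation is a 200 ms stimulus flash followed (optionally) by
#' inter-stimulus "off" bins; `bins_on` bins at the start of each
#' presentation are stimulus-on, the remaining `n_bins - bins_on` are off.
#' Trials consist of repeated presentations of stimulus 0 ending in at most
#' one target (stimulus 1), which must be the final presentation of its
#' trial.
#'
#' @param counts integer array `U x P x T_b` of spike counts.
#' @param meta data frame with one row per presentation and columns
#'   `block`, `trial`, `repeat_index`, `contrast` ("high"/"low"),
#'   `stimulus` (0 or 1), `outcome` ("hit", "miss" or "excluded") and
#'   optionally `drift_dir`.
#' @param unit_ids character or integer identifiers, length `U`.
#' @param bin_ms bin width in milliseconds (default 50).
#' @param bins_on number of stimulus-on bins per presentation (default
#'   `min(4, T_b)`, i.e. a 200 ms window at 50 ms bins).
#' @param area `"primary"` (V1-like) or `"downstream"` (MT-like).
#' @return An object of class `population_recording`.
#' @export
population_recording <- function(counts, meta, unit_ids = NULL,
                                 bin_ms = 50, bins_on = NULL,
                                 area = c("primary", "downstream")) {
  area <- match.arg(area)
  if (length(dim(counts)) != 3L)
    stop("`counts` must be a 3-d array (units x presentations x bins)")
  storage.mode(counts) <- "integer"
  if (any(is.na(counts)) || any(counts < 0L))
    stop("`counts` must be non-negative integers")
  U <- dim(counts)[1]; P <- dim(counts)[2]; Tb <- dim(counts)[3]
  if (is.null(bins_on)) bins_on <- min(4L, Tb)
  if (is.null(unit_ids)) unit_ids <- paste0("u", seq_len(U))
  if (length(unit_ids) != U) stop("`unit_ids` length must equal dim(counts)[1]")
  if (!is.data.frame(meta)) stop("`meta` must be a data frame")
  required <- c("block", "trial", "repeat_index", "contrast", "stimulus", "outcome")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0)
    stop(sprintf("presentation metadata is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (nrow(meta) != P)
    stop(sprintf("dimension mismatch: counts have %d presentations, metadata has %d rows",
                 P, nrow(meta)), call. = FALSE)
  if (!all(meta$contrast %in% c("high", "low")))
    stop("contrast must be 'high' or 'low'")
  if (!all(meta$stimulus %in% c(0L, 1L))) stop("stimulus must be 0 or 1")
  if (!all(meta$outcome %in% c("hit", "miss", "excluded")))
    stop("outcome must be 'hit', 'miss' or 'excluded'")
  # target occurs at most once per trial and only as the final presentation
  key <- paste(meta$block, meta$trial)
  is_tgt <- meta$stimulus == 1L
  if (any(is_tgt)) {
    n_tgt <- tapply(is_tgt, key, sum)
    if (any(n_tgt > 1L))
      stop(sprintf("trial %s has more than one target presentation",
                   names(n_tgt)[which(n_tgt > 1L)[1]]))
    last_of_trial <- !duplicated(key, fromLast = TRUE)
    bad <- is_tgt & !last_of_trial
    if (any(bad))
      stop(sprintf("target presentation of trial %s is not its final presentation",
                   key[which(bad)[1]]))
  }
  structure(list(counts = counts,
                 meta = as.data.frame(meta, stringsAsFactors = FALSE),
                 unit_ids = as.character(unit_ids),
                 bin_ms = as.numeric(bin_ms),
                 bins_on = as.integer(bins_on),
                 area = area,
                 first_removed = FALSE),
            class = "population_recording")
}

#' @export
print.population_recording <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<population_recording> %s area: %d units, %d presentations, %d bins of %g ms (%d on)\n",
              x$area, d[1], d[2], d[3], x$bin_ms, x$bins_on))
  cat(sprintf("  blocks: %d, trials: %d, targets: %d\n",
              length(unique(x$meta$block)),
              length(unique(paste(x$meta$block, x$meta$trial))),
              sum(x$meta$stimulus == 1L)))
  invisible(x)
}

#' Write a population recording to a JSON container
#'
#' One self-describing text file per block set: counts are stored as a flat
#' integer vector plus dimensions, metadata as named columns. The format
#' round-trips bit-exactly through [read_recording()].
#'
#' @param rec a `population_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "population_recording"))
  payload <- list(
    format = "modlabel-recording",
    version = 1L,
    bin_ms = rec$bin_ms,
    bins_on = rec$bins_on,
    area = rec$area,
    first_removed = isTRUE(rec$first_removed),
    unit_ids = rec$unit_ids,
    dims = dim(rec$counts),
    counts = as.integer(rec$counts),
    meta = as.list(rec$meta)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a population recording from a JSON container
#'
#' @param path file written by [write_recording()].
#' @return A validated `population_recording`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$format) || x$format != "modlabel-recording")
    stop("not a modlabel recording container (missing field 'format')")
  for (f in c("counts", "dims", "meta", "unit_ids"))
    if (is.null(x[[f]]))
      stop(sprintf("recording container is missing field '%s'", f))
  required <- c("block", "trial", "repeat_index", "contrast", "stimulus", "outcome")
  missing_cols <- setdiff(required, names(x$meta))
  if (length(missing_cols) > 0)
    stop(sprintf("recording container metadata is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  counts <- array(as.integer(x$counts), dim = x$dims)
  meta <- as.data.frame(x$meta, stringsAsFactors = FALSE)
  meta$stimulus <- as.integer(meta$stimulus)
  meta$repeat_index <- as.integer(meta$repeat_index)
  rec <- population_recording(counts, meta, unit_ids = x$unit_ids,
                              bin_ms = x$bin_ms, bins_on = x$bins_on,
                              area = x$area)
  rec$first_removed <- isTRUE(x$first_removed)
  rec
}

#' Export presentation metadata as CSV
#'
#' @param rec a `population_recording`.
#' @param path output CSV path.
#' @export
write_meta_csv <- function(rec, path) {
  utils::write.csv(rec$meta, path, row.names = FALSE)
  invisible(path)
}

# per-unit firing rate (Hz) over a bin subset
unit_rate_hz <- function(rec, bins) {
  mean_per_bin <- apply(rec$counts[, , bins, drop = FALSE], 1, mean)
  mean_per_bin / (rec$bin_ms / 1000)
}

#' Apply unit and trial inclusion criteria
#'
#' Filters a recording the way blocks are screened before model fitting:
#' \itemize{
#'   \item drop units whose largest per-stimulus mean response is less than
#'     10\% above baseline (reason `low-response`);
#'   \item drop units whose Fano factor lies more than 5 population standard
#'     deviations above the population mean Fano (reason `outlier-fano`);
#'   \item drop units with mean firing below `rate_min_hz` (reason `low-rate`);
#'   \item drop trials without a hit/miss outcome (`incomplete-outcome`);
#'   \item remove the first presentation of every trial to avoid adaptation
#'     transients (`first-presentation-drop`);
#'   \item declare the whole block excluded if fewer than `min_trials`
#'     valid trials remain.
#' }
#'
#' Baseline firing is the mean rate in inter-stimulus (off) bins when the
#' recording has them, otherwise `baseline_hz` must be supplied.
#'
#' @param rec a `population_recording`.
#' @param baseline_hz scalar baseline rate in Hz, used only when the
#'   recording has no off bins.
#' @param min_trials minimum number of valid trials per block (default 20).
#' @param rate_min_hz minimum mean firing rate in Hz (default 1).
#' @param response_factor required response relative to baseline (default 1.10).
#' @param fano_sd_max Fano outlier cut in population SDs (default 5).
#' @return A list with elements `recording` (filtered, or `NULL` if the
#'   block is excluded), `report` (an `inclusion_report`) and
#'   `block_excluded` (logical).
#' @export
apply_inclusion_criteria <- function(rec, baseline_hz = NULL,
                                     min_trials = 20, rate_min_hz = 1,
                                     response_factor = 1.10, fano_sd_max = 5) {
  stopifnot(inherits(rec, "population_recording"))
  Tb <- dim(rec$counts)[3]
  on_bins <- seq_len(rec$bins_on)
  off_bins <- setdiff(seq_len(Tb), on_bins)

  if (length(off_bins) > 0) {
    baseline <- unit_rate_hz(rec, off_bins)
  } else {
    if (is.null(baseline_hz))
      stop("recording has no inter-stimulus bins; supply `baseline_hz`")
    baseline <- rep(baseline_hz, dim(rec$counts)[1])
  }

  # mean stimulus-window rate for each stimulus identity
  stim_rate <- function(s) {
    idx <- which(rec$meta$stimulus == s)
    if (length(idx) == 0) return(rep(NA_real_, dim(rec$counts)[1]))
    apply(rec$counts[, idx, on_bins, drop = FALSE], 1, mean) / (rec$bin_ms / 1000)
  }
  r0 <- stim_rate(0L); r1 <- stim_rate(1L)
  best <- pmax(r0, r1, na.rm = TRUE)

  mean_rate <- unit_rate_hz(rec, seq_len(Tb))

  # per-unit Fano over presentation-summed counts of the repeated stimulus
  idx0 <- which(rec$meta$stimulus == 0L)
  sums0 <- apply(rec$counts[, idx0, on_bins, drop = FALSE], c(1, 2), sum)
  fano <- apply(sums0, 1, function(x) {
    if (mean(x) == 0) return(NA_real_)
    stats::var(x) / mean(x)
  })
  fano_mu <- mean(fano, na.rm = TRUE)
  fano_sd <- stats::sd(fano, na.rm = TRUE)
  fano_hi <- !is.na(fano) & !is.na(fano_sd) & fano_sd > 0 &
    fano > fano_mu + fano_sd_max * fano_sd

  reason <- rep(NA_character_, length(best))
  reason[best < response_factor * baseline] <- "low-response"
  reason[is.na(reason) & fano_hi] <- "outlier-fano"
  reason[is.na(reason) & mean_rate < rate_min_hz] <- "low-rate"
  keep_units <- is.na(reason)

  # trial screening
  meta <- rec$meta
  key <- paste(meta$block, meta$trial)
  trial_outcome <- tapply(meta$outcome, key, function(o) o[1])
  bad_trials <- names(trial_outcome)[!(trial_outcome %in% c("hit", "miss"))]
  keep_pres <- !(key %in% bad_trials)
  trial_reason <- stats::setNames(rep("incomplete-outcome", length(bad_trials)), bad_trials)

  # first presentation of each remaining trial removed (once only, so the
  # whole screening is idempotent)
  if (!isTRUE(rec$first_removed)) {
    first_of_trial <- !duplicated(key)
    keep_pres <- keep_pres & !first_of_trial
  }

  valid_trials <- unique(key[keep_pres])
  report <- structure(list(
    kept_units = rec$unit_ids[keep_units],
    dropped_units = data.frame(unit_id = rec$unit_ids[!keep_units],
                               reason = reason[!keep_units],
                               stringsAsFactors = FALSE),
    kept_trials = valid_trials,
    dropped_trials = data.frame(trial = names(trial_reason),
                                reason = unname(trial_reason),
                                stringsAsFactors = FALSE),
    n_valid_trials = length(valid_trials)
  ), class = "inclusion_report")

  if (length(valid_trials) < min_trials) {
    report$dropped_trials <- rbind(
      report$dropped_trials,
      data.frame(trial = valid_trials, reason = "too-few-trials",
                 stringsAsFactors = FALSE))
    return(list(recording = NULL, report = report, block_excluded = TRUE))
  }
  if (!any(keep_units)) {
    return(list(recording = NULL, report = report, block_excluded = TRUE))
  }

  out <- rec
  out$counts <- rec$counts[keep_units, keep_pres, , drop = FALSE]
  out$meta <- rec$meta[keep_pres, , drop = FALSE]
  rownames(out$meta) <- NULL
  out$unit_ids <- rec$unit_ids[keep_units]
  out$first_removed <- TRUE
  list(recording = out, report = report, block_excluded = FALSE)
}

#' @export
print.inclusion_report <- function(x, ...) {
  cat(sprintf("<inclusion_report> kept %d units (dropped %d), %d valid trials (dropped %d)\n",
              length(x$kept_units), nrow(x$dropped_units),
              x$n_valid_trials, nrow(x$dropped_trials)))
  invisible(x)
}
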