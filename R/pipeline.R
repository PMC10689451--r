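# Config-driven orchestration of the synthetic experiments.

#' Build an experiment configuration
#'
#' @param experiment one of `"fig-sweep"` (decoder accuracy vs modulator
#'   strength), `"block-pipeline"` (block simulation, inclusion, SR/PLDS
#'   fits, dimensionality selection, decoding, task statistics),
#'   `"downstream-pipeline"` (adds a modulator-inheriting downstream
#'   population, SR+modulator fits, grouped tests and the two-area
#'   cross-correlogram), `"network-comparison"` (hierarchical-network
#'   fine-tuning comparison).
#' @param seed global seed; every stochastic stage derives its own seed
#'   from it deterministically.
#' @param out_dir output directory (created if missing); `NULL` disables
#'   file output.
#' @param params named list of stage parameter overrides.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(experiment = c("fig-sweep", "block-pipeline",
                                             "downstream-pipeline",
                                             "network-comparison"),
                              seed = 1, out_dir = NULL, params = list()) {
  experiment <- match.arg(experiment)
  structure(list(experiment = experiment, seed = seed, out_dir = out_dir,
                 params = params),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' @param path YAML file with fields `experiment`, `seed`, `out_dir`,
#'   `params`.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  experiment_config(experiment = y$experiment,
                    seed = if (is.null(y$seed)) 1 else y$seed,
                    out_dir = y$out_dir,
                    params = if (is.null(y$params)) list() else y$params)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(cfg)), tmp)
  unname(tools::md5sum(tmp))
}

write_stage_csv <- function(out_dir, name, df) {
  if (!is.null(out_dir)) {
    utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  invisible(df)
}

#' Run a configured experiment end-to-end
#'
#' Executes one of the four experiment types with deterministic per-stage
#' seeds derived from the global seed, persisting tidy CSV tables and a
#' JSON summary (with config hash, seed, and per-stage timings) to the
#' output directory when one is configured.
#'
#' @param cfg an [experiment_config()].
#' @return A report list; contents depend on the experiment type. Always
#'   includes `config_hash`, `seed`, and `timings` (seconds per stage).
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (!is.null(cfg$out_dir) && !dir.exists(cfg$out_dir))
    dir.create(cfg$out_dir, recursive = TRUE)
  p <- cfg$params
  seed <- cfg$seed
  timings <- c()
  tic <- function() Sys.time()
  toc <- function(t0, name) {
    timings[[name]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
  }
  report <- list(experiment = cfg$experiment, seed = seed,
                 config_hash = config_hash(cfg))

  if (cfg$experiment == "fig-sweep") {
    t0 <- tic()
    base_cfg <- population_sim_config(
      n_informative = p$n_informative %||% 10,
      n_uninformative = p$n_uninformative %||% 40,
      n_inactive = p$n_inactive %||% 150,
      seed = seed)
    sweep <- modulator_strength_sweep(
      base_cfg,
      strength_grid = p$strength_grid %||% c(0, 0.25, 0.5, 1, 1.5, 2),
      n_train = p$n_train %||% 1000, n_test = p$n_test %||% 500,
      n_seeds = p$n_seeds %||% 5, seed = seed)
    toc(t0, "sweep")
    report$sweep <- sweep
    report$summary <- summarize_sweep(sweep)
    write_stage_csv(cfg$out_dir, "sweep", sweep)
    write_stage_csv(cfg$out_dir, "sweep_summary", report$summary)
  } else if (cfg$experiment %in% c("block-pipeline", "downstream-pipeline")) {
    t0 <- tic()
    pop_cfg <- population_sim_config(
      n_informative = p$n_informative %||% 8,
      n_uninformative = p$n_uninformative %||% 14,
      n_inactive = p$n_inactive %||% 2,
      sigma_m = p$sigma_m %||% 0.6,
      modulator_law = "ar1", ar_coef = p$ar_coef %||% 0.5,
      bins_off = 4, uninformative_ratio = c(1, 1.25), seed = seed)
    blk <- simulate_ar1_block(pop_cfg,
                              block_sim_config(n_trials = p$n_trials %||% 40),
                              seed = seed + 1)
    inc <- apply_inclusion_criteria(blk$recording)
    toc(t0, "simulate")
    if (inc$block_excluded) {
      report$error <- "block-excluded"
      return(report)
    }
    rec <- blk$recording   # keep generator-aligned grid for fitting
    t0 <- tic()
    design <- build_design_matrix(rec)
    srfit <- fit_sr(rec, design)
    pfit <- suppressWarnings(fit_plds_em(rec, design, D = 1))
    toc(t0, "fits")
    t0 <- tic()
    sel <- select_dimensionality(rec, design, D_range = 0:(p$max_D %||% 2),
                                 folds = p$folds %||% 3, seed = seed + 2,
                                 n_samples = p$n_samples %||% 30,
                                 max_iter = 25)
    toc(t0, "selection")
    t0 <- tic()
    stats <- unit_statistics(rec, pfit, n_perm = p$n_perm %||% 500,
                             seed = seed + 3)
    pc <- partial_correlation(stats$dprime, stats$coupling,
                              covariates = stats$mean_rate_hz)
    toc(t0, "stats")
    summaries <- modulator_summaries(pfit)
    report$inclusion <- inc$report
    report$selected_D <- sel$selected_D
    report$selection_scores <- sel$scores
    report$modulator <- summaries
    report$unit_statistics <- stats
    report$coupling_dprime_partial <- pc
    write_stage_csv(cfg$out_dir, "unit_statistics", stats)
    if (cfg$experiment == "downstream-pipeline") {
      t0 <- tic()
      U2 <- p$n_downstream %||% 20
      set.seed(seed + 4)
      base_hz <- stats::runif(U2, 10, 30)
      dp_order <- stats::runif(U2)
      informative_ds <- dp_order > 0.5
      target_delta <- ifelse(informative_ds, log(2), 0)
      inherited <- ifelse(informative_ds, 0.6, 0.05)
      lag <- p$lag_bins %||% 1
      ds <- simulate_downstream_units(rec, blk$modulator,
        tuning = list(base_hz = base_hz, target_delta = target_delta,
                      drift_gain = stats::runif(U2, 0, 0.4)),
        couplings = inherited, lag_bins = lag, seed = seed + 5)
      mtrace <- plds_modulator_trace(pfit, rec)
      dfit <- fit_sr_plus_modulator(ds, mtrace)
      grp <- compare_groups(dfit$improvement[informative_ds],
                            dfit$improvement[!informative_ds], test = "t")
      dsdesign <- build_design_matrix(ds)
      dpfit <- suppressWarnings(fit_plds_em(ds, dsdesign, D = 1))
      ds_trace <- plds_modulator_trace(dpfit, ds)
      Tb <- dim(rec$counts)[3]
      trial <- rep(paste(rec$meta$block, rec$meta$trial), each = Tb)
      xc <- cross_correlogram(as.vector(t(mtrace)), as.vector(t(ds_trace)),
                              trial, max_lag = p$max_lag %||% 4)
      toc(t0, "downstream")
      report$downstream <- list(improvement = dfit$improvement,
                                informative = informative_ds,
                                group_test = grp,
                                crosscorr = xc, lag_bins = lag)
      write_stage_csv(cfg$out_dir, "downstream_improvement",
                      data.frame(unit = seq_len(U2),
                                 informative = informative_ds,
                                 improvement = dfit$improvement))
    }
  } else if (cfg$experiment == "network-comparison") {
    t0 <- tic()
    net_cfg <- network_config(p$scale %||% "small")
    res <- run_comparison(net_cfg,
                          checkpoints = p$checkpoints %||% c(250, 500, 1000, 2000, 4000),
                          n_eval = p$n_eval %||% 400,
                          seeds = seq_len(p$n_seeds %||% 3) + seed - 1)
    toc(t0, "comparison")
    report$curves <- res$curves
    report$samples_to_criterion <- res$samples_to_criterion
    write_stage_csv(cfg$out_dir, "curves", res$curves)
    write_stage_csv(cfg$out_dir, "samples_to_criterion", res$samples_to_criterion)
  }
  report$timings <- timings
  if (!is.null(cfg$out_dir)) {
    jsonlite::write_json(list(experiment = cfg$experiment, seed = seed,
                              config_hash = report$config_hash,
                              timings = timings),
                         file.path(cfg$out_dir, "run.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
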