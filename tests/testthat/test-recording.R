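test_that("recording container round-trips bit-exactly", {
  x <- make_iid_recording(n_per_stim = 10)
  path <- withr::local_tempfile(fileext = ".json")
  write_recording(x$rec, path)
  back <- read_recording(path)
  expect_identical(back$counts, x$rec$counts)
  expect_identical(back$meta, x$rec$meta)
  expect_identical(back$unit_ids, x$rec$unit_ids)
  expect_identical(back$bin_ms, x$rec$bin_ms)
  expect_identical(back$area, x$rec$area)

  # generator output survives a second round trip unchanged
  blk <- make_targeted_block(n_trials = 5, seed = 1)
  p2 <- withr::local_tempfile(fileext = ".json")
  write_recording(blk$rec, p2)
  expect_identical(read_recording(p2)$counts, blk$rec$counts)
})

test_that("malformed containers fail with the offending field named", {
  x <- make_iid_recording(n_per_stim = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_recording(x$rec, path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$meta$contrast <- NULL
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(raw, path2, auto_unbox = TRUE, digits = NA)
  expect_error(read_recording(path2), "contrast")
  expect_error(read_recording(tempfile()), "not found")
})

test_that("recording invariants are enforced", {
  counts <- array(1L, dim = c(2, 4, 2))
  meta <- data.frame(block = 1L, trial = c(1L, 1L, 1L, 1L),
                     repeat_index = 1:4, contrast = "high",
                     stimulus = c(0L, 1L, 0L, 0L), outcome = "hit",
                     stringsAsFactors = FALSE)
  expect_error(population_recording(counts, meta), "final presentation")
  meta$stimulus <- c(0L, 1L, 0L, 1L)
  expect_error(population_recording(counts, meta), "more than one target")
  counts[1] <- -1L
  meta$stimulus <- c(0L, 0L, 0L, 1L)
  expect_error(population_recording(counts, meta), "non-negative")
})

test_that("inclusion criteria drop the right units and trials", {
  blk <- make_targeted_block(n_trials = 30, seed = 11)
  res <- apply_inclusion_criteria(blk$rec)
  expect_false(res$block_excluded)
  # inactive units (1 Hz, no stimulus response above baseline) are dropped
  inactive_ids <- blk$rec$unit_ids[blk$pop$kind == "inactive"]
  expect_true(all(inactive_ids %in% res$report$dropped_units$unit_id))
  # first presentation of every trial removed exactly once
  reps <- tapply(res$recording$meta$repeat_index,
                 res$recording$meta$trial, min)
  expect_true(all(reps == 2))
  # idempotence
  res2 <- apply_inclusion_criteria(res$recording)
  expect_identical(res2$recording$counts, res$recording$counts)
  expect_identical(res2$recording$meta, res$recording$meta)
})

test_that("a block with fewer than 20 valid trials is excluded, not an error", {
  blk <- make_targeted_block(n_trials = 19, seed = 5)
  res <- apply_inclusion_criteria(blk$rec)
  expect_true(res$block_excluded)
  expect_null(res$recording)
  expect_true("too-few-trials" %in% res$report$dropped_trials$reason)
})

test_that("homogeneous Poisson population has no Fano outliers; baseline-level units are low-response", {
  set.seed(42)
  U <- 50; P <- 800; Tb <- 8
  n_tr <- P / 2
  counts <- array(rpois(U * P * Tb, 2), dim = c(U, P, Tb))
  meta <- data.frame(block = 1L, trial = rep(seq_len(n_tr), each = 2),
                     repeat_index = rep(1:2, n_tr), contrast = "high",
                     stimulus = rep(c(0L, 1L), n_tr), outcome = "hit",
                     stringsAsFactors = FALSE)
  rec <- population_recording(counts, meta, bins_on = 4)
  res <- apply_inclusion_criteria(rec)
  # Poisson responses: no Fano outliers; flat units sit exactly at their
  # own baseline (well inside the 10% margin at this sample size), so every
  # unit is dropped as low-response and the block is excluded
  expect_false("outlier-fano" %in% res$report$dropped_units$reason)
  expect_true(all(res$report$dropped_units$reason == "low-response"))
  expect_true(res$block_excluded)
})
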