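small_cfg <- function(seed = 1L, n_events = 2L, ...)
  synth_config(n_channels = 2L, duration_s = 120L, n_events = n_events,
               event_duration_range = c(8L, 12L), seed = seed, ...)

test_that("generation is deterministic under the seed", {
  s1 <- synth_eeg(small_cfg(4L))
  s2 <- synth_eeg(small_cfg(4L))
  expect_identical(s1$recording$signals, s2$recording$signals)
  expect_identical(s1$annotations$events, s2$annotations$events)
  s3 <- synth_eeg(small_cfg(5L))
  expect_false(identical(s1$recording$signals, s3$recording$signals))
  # generation does not disturb the caller's RNG stream
  set.seed(2); before <- stats::runif(1)
  set.seed(2); invisible(synth_eeg(small_cfg(4L))); after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("planted events respect rarity, duration and overlap invariants", {
  for (seed in 1:5) {
    s <- synth_eeg(small_cfg(seed))
    ev <- s$annotations$events
    expect_equal(nrow(ev), 2L)
    durs <- ev$end - ev$start
    expect_true(all(durs >= 8 & durs <= 12))
    expect_lte(sum(durs), 0.2 * 120)
    o <- order(ev$start)
    expect_true(all(utils::head(ev$end[o], -1L) <= ev$start[o][-1L]))
    expect_true(all(ev$start >= 0 & ev$end <= 120))
  }
  s0 <- synth_eeg(small_cfg(1L, n_events = 0L))
  expect_equal(nrow(s0$annotations$events), 0L)
  expect_error(synth_eeg(synth_config(duration_s = 60L, n_events = 5L,
                                      event_duration_range = c(50L, 60L))),
               "cannot")
})

test_that("event frames shift spectral energy into the 2-4 Hz band", {
  cfg <- synth_config(n_channels = 2L, duration_s = 300L, n_events = 2L,
                      event_duration_range = c(20L, 30L), seed = 8L)
  s <- synth_eeg(cfg)
  sf <- featurize(s$recording)
  truth <- frame_truth(events_for(s$annotations, s$recording$file_id),
                       sf$frame_times, sf$cfg, 256L)
  # interior event frames (fully covered, past the onset ramp)
  interior <- truth & c(FALSE, utils::head(truth, -1L)) &
    c(utils::tail(truth, -1L), FALSE)
  bins_2_4 <- 3:5  # 1-based bins for 2, 3, 4 Hz at 1 Hz resolution
  for (ch in 1:2) {
    M <- sf$frames[[ch]]^2
    e_evt <- mean(rowSums(M[interior, bins_2_4, drop = FALSE]))
    e_bg <- mean(rowSums(M[!truth, bins_2_4, drop = FALSE]))
    expect_gte(e_evt / e_bg, cfg$amplitude_ratio^2 / 2)
  }
})

test_that("fixtures round-trip through EDF and the annotation parser", {
  s <- synth_eeg(small_cfg(6L))
  dir <- withr::local_tempdir()
  paths <- write_fixture(s$recording, s$annotations, dir)
  expect_true(all(file.exists(paths)))
  rec2 <- read_edf(paths[["edf"]])
  expect_identical(rec2$channel_labels, s$recording$channel_labels)
  step <- max(vapply(seq_len(2L), function(j)
    edf_quantization_step(max(abs(s$recording$signals[, j]))), numeric(1)))
  expect_lte(max(abs(rec2$signals - s$recording$signals)), step)
  ann2 <- parse_annotation_summary(paths[["summary"]])
  expect_equal(ann2$events$start, s$annotations$events$start)
  expect_equal(ann2$events$end, s$annotations$events$end)
  expect_true(any(grepl("Number of Seizures in File: 2",
                        readLines(paths[["summary"]]))))
})
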