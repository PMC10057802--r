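test_that("write/read round trip stays within one quantization step", {
  rec <- make_sine_rec(n_channels = 3L, seconds = 2L, amp = 80)
  p <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, p)
  r2 <- read_edf(p)
  expect_identical(r2$channel_labels, rec$channel_labels)
  expect_identical(r2$sample_rate, rec$sample_rate)
  expect_equal(dim(r2$signals), dim(rec$signals))
  for (j in 1:3) {
    step <- edf_quantization_step(max(abs(rec$signals[, j])))
    expect_lte(max(abs(r2$signals[, j] - rec$signals[, j])), step)
  }
})

test_that("a single all-zero channel round-trips exactly", {
  rec <- recording(matrix(0, 256, 1), 256, "FLAT", file_id = "flat")
  p <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, p)
  r2 <- read_edf(p)
  expect_equal(n_samples(r2), 256L)
  expect_true(all(abs(r2$signals) <= edf_quantization_step(0)))
})

test_that("truncated and malformed files raise parse errors", {
  rec <- make_sine_rec(1L, seconds = 1L)
  p <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, p)
  raw <- readBin(p, "raw", n = file.size(p))

  p_trunc <- withr::local_tempfile(fileext = ".edf")
  writeBin(raw[1:100], p_trunc)
  expect_error(read_edf(p_trunc), "truncated")

  p_hdr <- withr::local_tempfile(fileext = ".edf")
  writeBin(raw[1:512], p_hdr)  # header only, no data
  expect_error(read_edf(p_hdr), "truncated")

  # corrupt the 'number of signals' field (bytes 253-256)
  p_bad <- withr::local_tempfile(fileext = ".edf")
  raw_bad <- raw
  raw_bad[253:256] <- charToRaw("abcd")
  writeBin(raw_bad, p_bad)
  expect_error(read_edf(p_bad), "number of signals")

  expect_error(read_edf(withr::local_tempfile()), "does not exist")
})

test_that("channels with differing sampling rates are rejected with rates listed", {
  rec <- make_sine_rec(2L, seconds = 1L)
  p <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, p)
  raw <- readBin(p, "raw", n = file.size(p))
  # samples-per-record block starts at 256 + 216 * ns; patch signal 2
  off <- 256L + 216L * 2L + 8L
  raw[(off + 1L):(off + 8L)] <- charToRaw(formatC("128", width = -8))
  p2 <- withr::local_tempfile(fileext = ".edf")
  writeBin(raw, p2)
  expect_error(read_edf(p2), "differing sampling rates.*256.*128")
})

test_that("writer validates inputs", {
  rec <- make_sine_rec(2L, seconds = 1L)
  bad <- rec
  bad$signals[5, 2] <- NaN
  p <- withr::local_tempfile(fileext = ".edf")
  expect_error(write_edf(bad, p), "non-finite.*CH2")
  expect_error(write_edf(rec, p, physical_max = 10), "exceeds.*CH1")
  odd <- recording(matrix(1, 300, 1), 256)  # not a whole second
  expect_error(write_edf(odd, p), "whole number")
})

test_that("millivolt channels are converted to microvolts on read", {
  rec <- make_sine_rec(1L, seconds = 1L, amp = 0.05)
  p <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, p, physical_dim = "mV")
  r2 <- read_edf(p)
  expect_equal(max(abs(r2$signals)) / max(abs(rec$signals)), 1000,
               tolerance = 1e-3)
})
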