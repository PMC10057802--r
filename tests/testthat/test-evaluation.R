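test_that("frame truth follows the one-sample-overlap rule", {
  cfg <- frame_config()
  ft <- (0:19) * 192L  # 20 frames
  sr <- 256L
  # event exactly covering frames 10..12 (0-based samples)
  ev <- data.frame(start = ft[11L] / sr, end = (ft[13L] + 256) / sr)
  truth <- frame_truth(ev, ft, cfg, sr)
  expect_true(all(truth[11:13]))
  # frames 9 and 10 (1-based) share samples with frame 11's window start?
  # overlap rule: any frame whose window intersects the event is positive
  manual <- vapply(seq_along(ft), function(i) {
    fs <- ft[i]; fe <- ft[i] + 256L
    (fs < ev$end * sr) && (fe > ev$start * sr)
  }, logical(1))
  expect_equal(truth, manual)

  # 1-sample event inside frame 5 only (offset past frame 4's window end,
  # before frame 6's start, since adjacent windows overlap by 64 samples)
  s5 <- ft[5L] + 100L
  ev1 <- data.frame(start = s5 / sr, end = (s5 + 1L) / sr)
  truth1 <- frame_truth(ev1, ft, cfg, sr)
  expect_equal(which(truth1), 5L)

  # event straddling a frame boundary marks both frames
  evb <- data.frame(start = (ft[7L] + 250L) / sr, end = (ft[7L] + 260L) / sr)
  truthb <- frame_truth(evb, ft, cfg, sr)
  expect_true(truthb[7L] && truthb[8L])

  expect_equal(frame_truth(NULL, ft, cfg, sr), rep(FALSE, 20L))
})

test_that("confusion counts match an element-wise tally", {
  set.seed(21)
  flags <- stats::runif(1000) < 0.3
  truth <- stats::runif(1000) < 0.1
  cc <- confusion(flags, truth)
  expect_equal(cc$tp, sum(flags & truth))
  expect_equal(cc$fp, sum(flags & !truth))
  expect_equal(cc$tn, sum(!flags & !truth))
  expect_equal(cc$fn, sum(!flags & truth))
  expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, 1000L)
  agree <- confusion(truth, truth)
  expect_equal(agree$fp + agree$fn, 0L)
  flip <- confusion(!truth, truth)
  expect_equal(flip$tp + flip$tn, 0L)
  expect_error(confusion(flags, truth[1:10]), "lengths differ")
})

test_that("metric formulas match hand evaluation and handle zero denominators", {
  m <- compute_metrics(structure(list(tp = 40L, fn = 10L, tn = 80L,
                                      fp = 20L),
                                 class = "confusion_counts"))
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$ppv, 2 / 3)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$f1, 2 * 40 / (2 * 40 + 20 + 10))

  perfect <- compute_metrics(confusion(c(TRUE, FALSE, TRUE),
                                       c(TRUE, FALSE, TRUE)))
  for (nm in c("sensitivity", "specificity", "accuracy", "f1", "mcc"))
    expect_equal(perfect[[nm]], 1)
  for (nm in c("fpr", "fnr", "fdr", "fomr"))
    expect_equal(perfect[[nm]], 0)

  none <- compute_metrics(confusion(rep(FALSE, 5), rep(FALSE, 5)))
  expect_true(is.na(none$sensitivity))
  expect_true("sensitivity" %in% attr(none, "undefined"))
  expect_true("ppv" %in% attr(none, "undefined"))
  expect_equal(none$specificity, 1)
})

test_that("metrics agree with independent formulas on random tables", {
  set.seed(31)
  for (i in 1:200) {
    cc <- structure(as.list(stats::setNames(
      sample(0:50, 4L, replace = TRUE), c("tp", "fp", "tn", "fn"))),
      class = "confusion_counts")
    got <- compute_metrics(cc)
    want <- oracle_metrics(cc$tp, cc$fp, cc$tn, cc$fn)
    for (nm in names(want))
      expect_equal(got[[nm]], want[[nm]], info = nm)
    # complementarity identities, exact whenever defined
    if (!is.na(got$specificity)) expect_identical(got$fpr, 1 - got$specificity)
    if (!is.na(got$sensitivity)) expect_identical(got$fnr, 1 - got$sensitivity)
    if (!is.na(got$ppv)) expect_identical(got$fdr, 1 - got$ppv)
    if (!is.na(got$npv)) expect_identical(got$fomr, 1 - got$npv)
    if (!is.na(got$mcc)) expect_gte(got$mcc, -1)
    if (!is.na(got$mcc)) expect_lte(got$mcc, 1)
  }
})

test_that("MCC equals the Pearson correlation of the boolean vectors", {
  set.seed(41)
  for (i in 1:20) {
    flags <- stats::runif(300) < stats::runif(1, 0.2, 0.8)
    truth <- stats::runif(300) < stats::runif(1, 0.2, 0.8)
    m <- compute_metrics(confusion(flags, truth))
    if (!is.na(m$mcc))
      expect_equal(m$mcc, stats::cor(as.numeric(flags), as.numeric(truth)),
                   tolerance = 1e-12)
  }
})

test_that("event capture counts events and channel coincidence correctly", {
  cfg <- frame_config()
  ft <- (0:49) * 192L
  sr <- 256L
  events <- data.frame(
    start = c(ft[5L], ft[20L], ft[35L]) / sr,
    end = c(ft[8L] + 256, ft[23L] + 256, ft[38L] + 256) / sr)
  N <- 4L
  flags <- matrix(FALSE, 50L, N)
  flags[5:8, ] <- TRUE          # event 1: all channels
  flags[20, 1:2] <- TRUE        # event 2: half the channels
  cap <- event_capture(flags, events, ft, cfg, sr)
  expect_equal(cap$total, 3L)
  expect_equal(cap$captured, 2L)
  expect_equal(cap$coincidence, c(1, 0.5, 0))
  # monotone: adding flags never reduces capture or coincidence
  flags2 <- flags
  flags2[36, 4] <- TRUE
  cap2 <- event_capture(flags2, events, ft, cfg, sr)
  expect_gte(cap2$captured, cap$captured)
  expect_true(all(cap2$coincidence >= cap$coincidence))
  # no events
  cap0 <- event_capture(flags, NULL, ft, cfg, sr)
  expect_equal(cap0$total, 0L)
  # coincidence histogram sums to the event count
  tab <- coincidence_table(cap$coincidence)
  expect_equal(sum(tab$n_events), 3L)
})

test_that("micro-aggregation sums confusion counts", {
  c1 <- confusion(c(TRUE, FALSE, TRUE), c(TRUE, TRUE, FALSE))
  c2 <- confusion(c(FALSE, FALSE), c(FALSE, TRUE))
  s <- sum_confusion(c1, c2)
  expect_equal(s$tp, c1$tp + c2$tp)
  expect_equal(s$fn, c1$fn + c2$fn)
  s2 <- sum_confusion(list(c1, c2))
  expect_equal(unclass(s2), unclass(s))
})
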