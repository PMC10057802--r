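# Frame-level and event-level evaluation of anomaly flags against expert
# annotations: 2x2 confusion counts, the standard battery of eleven binary
# classification metrics, event capture, and per-event channel coincidence.

#' Frame-level ground truth from annotated events
#'
#' A frame is positive iff its sample interval
#' `[start_sample, start_sample + window_len)` overlaps an annotated event
#' interval by at least one sample — the most permissive overlap rule, since
#' events only partially overlap fixed frames and per-frame sensitivity is
#' then a lower bound for practical purposes.
#'
#' @param events data.frame of events for this recording (columns `start`,
#'   `end`, in seconds), e.g. from [events_for()].
#' @param frame_times 0-based frame start samples (from [featurize()]).
#' @param cfg a [frame_config()].
#' @param sample_rate samples per second of the recording.
#' @return logical vector, one element per frame.
#' @export
frame_truth <- function(events, frame_times, cfg, sample_rate) {
  truth <- rep(FALSE, length(frame_times))
  if (is.null(events) || nrow(events) == 0L) return(truth)
  wl <- cfg$window_len
  for (i in seq_len(nrow(events))) {
    s <- round(events$start[i] * sample_rate)
    e <- round(events$end[i] * sample_rate)
    truth <- truth | (frame_times < e & (frame_times + wl) > s)
  }
  truth
}

#' Confusion counts over frames
#'
#' @param flags logical vector of per-frame anomaly calls.
#' @param truth logical vector of per-frame ground truth (same length).
#' @return object of class `confusion_counts` with fields `tp`, `fp`, `tn`,
#'   `fn` (which sum to the number of frames).
#' @export
confusion <- function(flags, truth) {
  if (length(flags) != length(truth))
    stop("flags (", length(flags), ") and truth (", length(truth),
         ") lengths differ")
  flags <- as.logical(flags); truth <- as.logical(truth)
  structure(list(tp = sum(flags & truth), fp = sum(flags & !truth),
                 tn = sum(!flags & !truth), fn = sum(!flags & truth)),
            class = "confusion_counts")
}

#' Sum confusion counts (micro-aggregation)
#' @param ... `confusion_counts` objects (or a single list of them).
#' @return a `confusion_counts` with summed fields.
#' @export
sum_confusion <- function(...) {
  cs <- list(...)
  if (length(cs) == 1L && !inherits(cs[[1L]], "confusion_counts"))
    cs <- cs[[1L]]
  structure(list(tp = sum(vapply(cs, `[[`, 0, "tp")),
                 fp = sum(vapply(cs, `[[`, 0, "fp")),
                 tn = sum(vapply(cs, `[[`, 0, "tn")),
                 fn = sum(vapply(cs, `[[`, 0, "fn"))),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion: tp=%d fp=%d tn=%d fn=%d>\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' The eleven frame-level classification metrics
#'
#' Computes sensitivity, specificity, accuracy, F1 score, positive and
#' negative predictive value, false positive / negative rate, false
#' discovery / omission rate, and the Matthews correlation coefficient from
#' a 2x2 confusion table. Any metric whose denominator is zero is reported
#' as `NA` and listed in the `undefined` attribute rather than silently
#' propagated or coerced to 0.
#'
#' @param cc a [confusion()] object.
#' @return object of class `metrics_report`: named list of the 11 metrics
#'   plus the counts, with attribute `undefined` naming any metric with a
#'   zero denominator.
#' @export
compute_metrics <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  tp <- as.numeric(cc$tp); fp <- as.numeric(cc$fp)
  tn <- as.numeric(cc$tn); fn <- as.numeric(cc$fn)
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- frac(tp, tp + fn)
  spec <- frac(tn, tn + fp)
  ppv  <- frac(tp, tp + fp)
  npv  <- frac(tn, tn + fn)
  acc  <- frac(tp + tn, tp + fp + tn + fn)
  f1   <- frac(2 * tp, 2 * tp + fp + fn)
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else NA_real_
  m <- list(sensitivity = sens, specificity = spec, accuracy = acc,
            f1 = f1, ppv = ppv, npv = npv,
            fpr = if (is.na(spec)) NA_real_ else 1 - spec,
            fnr = if (is.na(sens)) NA_real_ else 1 - sens,
            fdr = if (is.na(ppv)) NA_real_ else 1 - ppv,
            fomr = if (is.na(npv)) NA_real_ else 1 - npv,
            mcc = mcc,
            counts = list(tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn))
  undef <- names(m)[vapply(m[1:11], function(v) is.na(v), logical(1))]
  structure(m, undefined = undef, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat("<metrics_report>\n")
  for (nm in setdiff(names(x), "counts"))
    cat(sprintf("  %-12s %s\n", nm,
                if (is.na(x[[nm]])) "undefined"
                else formatC(x[[nm]], digits = digits, format = "f")))
  cat(sprintf("  counts       tp=%d fp=%d tn=%d fn=%d\n",
              x$counts$tp, x$counts$fp, x$counts$tn, x$counts$fn))
  invisible(x)
}

#' Event-level capture and channel coincidence
#'
#' An annotated event is captured iff at least one of its truth-positive
#' frames is flagged in at least one channel. Per-event channel coincidence
#' is the fraction of channels with at least one flagged frame inside the
#' event (the quantity behind "seizure prediction as a percentage of total
#' channels").
#'
#' @param flag_matrix logical matrix `F x N` of per-frame, per-channel
#'   flags.
#' @param events data.frame of events (columns `start`, `end`, seconds).
#' @param frame_times 0-based frame start samples.
#' @param cfg a [frame_config()].
#' @param sample_rate samples per second.
#' @return list with `captured`, `total`, and `coincidence` (numeric vector,
#'   one fraction per event).
#' @export
event_capture <- function(flag_matrix, events, frame_times, cfg,
                          sample_rate) {
  flag_matrix <- as.matrix(flag_matrix)
  N <- ncol(flag_matrix)
  if (N < 1L) stop("need at least one channel")
  n_ev <- if (is.null(events)) 0L else nrow(events)
  if (n_ev == 0L)
    return(list(captured = 0L, total = 0L, coincidence = numeric(0)))
  coinc <- numeric(n_ev)
  for (i in seq_len(n_ev)) {
    tr <- frame_truth(events[i, , drop = FALSE], frame_times, cfg,
                      sample_rate)
    hit <- colSums(flag_matrix[tr, , drop = FALSE]) > 0L
    coinc[i] <- mean(hit)
  }
  list(captured = sum(coinc > 0), total = n_ev, coincidence = coinc)
}

#' Channel-coincidence histogram table
#'
#' Tabulates per-event coincidence fractions into bins for export (the
#' machine-readable form of the coincidence barplot).
#'
#' @param coincidence numeric vector of per-event channel fractions.
#' @param breaks histogram breaks on \[0, 1\] (default deciles).
#' @return data.frame with columns `bin_low`, `bin_high`, `n_events`.
#' @export
coincidence_table <- function(coincidence, breaks = seq(0, 1, by = 0.1)) {
  cuts <- cut(coincidence, breaks = breaks, include.lowest = TRUE,
              right = TRUE)
  data.frame(bin_low = utils::head(breaks, -1L),
             bin_high = breaks[-1L],
             n_events = as.integer(table(cuts)))
}
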