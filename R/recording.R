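#' Multichannel EEG recording container
#'
#' An `eeg_recording` holds a multichannel biosignal: one numeric vector of
#' `T` samples per channel (in microvolts by convention), the shared sampling
#' rate, channel labels, and a file identifier. All channels must have the
#' same length.
#'
#' @param signals numeric matrix (`T` samples x `N` channels) or a list of
#'   equal-length numeric vectors, in microvolts.
#' @param sample_rate sampling rate in samples per second (positive integer;
#'   scalp EEG reference value 256).
#' @param channel_labels character vector of `N` labels, e.g. bipolar montage
#'   names such as `"FP1-F7"`. Defaults to `"CH1"`, `"CH2"`, ...
#' @param start_time optional `POSIXct` acquisition start.
#' @param file_id identifier used to match annotations (defaults to "record").
#'
#' @return An object of class `eeg_recording` with elements `signals`
#'   (T x N matrix), `sample_rate`, `channel_labels`, `start_time`, `file_id`.
#' @examples
#' rec <- recording(matrix(sin(seq_len(512) / 10), ncol = 2), 256)
#' n_samples(rec)
#' @export
recording <- function(signals, sample_rate, channel_labels = NULL,
                      start_time = NULL, file_id = "record") {
  if (is.list(signals) && !is.data.frame(signals)) {
    lens <- lengths(signals)
    if (length(unique(lens)) > 1L)
      stop("all channels must have the same length; got lengths ",
           paste(unique(lens), collapse = ", "))
    signals <- do.call(cbind, lapply(signals, as.numeric))
  }
  signals <- as.matrix(signals)
  storage.mode(signals) <- "double"
  if (nrow(signals) < 1L || ncol(signals) < 1L)
    stop("recording needs at least one channel with at least one sample")
  sample_rate <- as.integer(sample_rate)
  if (is.na(sample_rate) || sample_rate <= 0L)
    stop("sample_rate must be a positive integer")
  if (is.null(channel_labels))
    channel_labels <- if (!is.null(colnames(signals))) colnames(signals)
                      else paste0("CH", seq_len(ncol(signals)))
  if (length(channel_labels) != ncol(signals))
    stop("channel_labels length (", length(channel_labels),
         ") does not match channel count (", ncol(signals), ")")
  colnames(signals) <- channel_labels
  structure(
    list(signals = signals, sample_rate = sample_rate,
         channel_labels = as.character(channel_labels),
         start_time = start_time, file_id = as.character(file_id)),
    class = "eeg_recording")
}

#' @rdname recording
#' @param rec an `eeg_recording`.
#' @export
n_samples <- function(rec) nrow(rec$signals)

#' @rdname recording
#' @export
n_channels <- function(rec) ncol(rec$signals)

#' @export
print.eeg_recording <- function(x, ...) {
  dur <- n_samples(x) / x$sample_rate
  cat(sprintf("<eeg_recording '%s': %d channel(s), %d samples @ %d Hz (%.1f s)>\n",
              x$file_id, n_channels(x), n_samples(x), x$sample_rate, dur))
  cat("  channels:", paste(utils::head(x$channel_labels, 8), collapse = ", "),
      if (n_channels(x) > 8) "..." else "", "\n")
  invisible(x)
}

#' Seizure annotation set
#'
#' Holds expert event annotations for one or more recordings: each event is a
#' `(file_id, start_seconds, end_seconds)` interval with `0 <= start < end`.
#'
#' @param events data.frame with columns `file_id`, `start`, `end` (seconds),
#'   or NULL for an empty set.
#' @param file_durations named numeric vector mapping file_id to recording
#'   duration in seconds (NA allowed when unknown). Events are clipped to the
#'   duration when it is known.
#' @return object of class `annotation_set` with elements `events`
#'   (data.frame), `total_files`, `file_durations`.
#' @export
annotation_set <- function(events = NULL, file_durations = numeric(0)) {
  if (is.null(events) || nrow(as.data.frame(events)) == 0L) {
    events <- data.frame(file_id = character(0), start = numeric(0),
                         end = numeric(0), stringsAsFactors = FALSE)
  } else {
    events <- as.data.frame(events, stringsAsFactors = FALSE)
    stopifnot(all(c("file_id", "start", "end") %in% names(events)))
    if (any(events$start < 0)) stop("event start times must be non-negative")
    if (any(events$end <= events$start))
      stop("event end must be strictly greater than start")
    dur <- file_durations[events$file_id]
    clip <- !is.na(dur) & events$end > dur
    events$end[clip] <- dur[clip]
    events <- events[events$end > events$start, , drop = FALSE]
    rownames(events) <- NULL
  }
  structure(list(events = events,
                 total_files = length(file_durations),
                 file_durations = file_durations),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set: %d event(s) across %d file(s)>\n",
              nrow(x$events), x$total_files))
  invisible(x)
}

#' Events annotated for one recording
#'
#' Selects the events of an [annotation_set] whose `file_id` matches a
#' recording, by case-insensitive file-stem match (extension ignored).
#'
#' @param ann an `annotation_set`.
#' @param file_id recording identifier or file name.
#' @return data.frame of events (columns `file_id`, `start`, `end`).
#' @export
events_for <- function(ann, file_id) {
  stem <- function(s) tolower(sub("\\.[A-Za-z0-9]+$", "", basename(s)))
  ev <- ann$events
  ev[stem(ev$file_id) == stem(file_id), , drop = FALSE]
}
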