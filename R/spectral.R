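# Short-time Fourier featurization: overlapping fixed-length windows per
# channel, each mapped to its full-length DFT magnitude vector.

#' Windowing configuration for spectral featurization
#'
#' Frames are `window_len` samples long; adjacent frames share `overlap`
#' samples, so the hop between frame starts is `window_len - overlap`
#' (default 256/64, i.e. a 192-sample hop: 1-second frames stepping 0.75 s
#' at 256 Hz). The frame count for a `T`-sample channel is
#' `floor((T - window_len) / hop) + 1`; trailing samples that do not fill a
#' window are dropped.
#'
#' @param window_len window length in samples (default 256).
#' @param overlap samples shared by adjacent windows (default 64). The
#'   alternative reading "step by 64 samples" is obtained with
#'   `overlap = window_len - 64`.
#' @param taper `"none"` (rectangular, default) or `"hann"`.
#' @return object of class `frame_config` with fields `window_len`,
#'   `overlap`, `hop`, `taper`.
#' @export
frame_config <- function(window_len = 256L, overlap = 64L,
                         taper = c("none", "hann")) {
  window_len <- as.integer(window_len); overlap <- as.integer(overlap)
  if (window_len < 1L) stop("window_len must be >= 1")
  if (overlap < 0L || overlap >= window_len)
    stop("overlap must satisfy 0 <= overlap < window_len")
  structure(list(window_len = window_len, overlap = overlap,
                 hop = window_len - overlap, taper = match.arg(taper)),
            class = "frame_config")
}

#' Number of frames for a signal length
#' @param T_ signal length in samples.
#' @param cfg a [frame_config()].
#' @return integer frame count (0 when `T_ < window_len`).
#' @export
n_frames <- function(T_, cfg) {
  if (T_ < cfg$window_len) return(0L)
  as.integer((T_ - cfg$window_len) %/% cfg$hop + 1L)
}

#' Cut one channel into overlapping windows
#'
#' @param signal numeric vector of samples.
#' @param cfg a [frame_config()].
#' @return numeric matrix with one window per row (`F x window_len`); frame
#'   `i` (1-based) starts at sample index `(i-1) * hop`. A signal shorter
#'   than one window yields a 0-row matrix with a warning.
#' @export
window_signal <- function(signal, cfg) {
  F_ <- n_frames(length(signal), cfg)
  if (F_ == 0L) {
    warning("signal shorter than one window (", length(signal), " < ",
            cfg$window_len, " samples); no frames produced")
    return(matrix(numeric(0), nrow = 0L, ncol = cfg$window_len))
  }
  idx <- outer((seq_len(F_) - 1L) * cfg$hop, seq_len(cfg$window_len), `+`)
  matrix(signal[idx], nrow = F_, ncol = cfg$window_len)
}

#' Full DFT magnitude of one window
#'
#' Element `k` (0-based) is the modulus of the `k`-th discrete Fourier
#' coefficient of the raw (mean-preserved, untapered) samples; the output has
#' the same length as the input, i.e. the full conjugate-symmetric spectrum.
#' Parseval's identity `sum(mag^2) / n == sum(x^2)` holds exactly up to
#' floating-point rounding.
#'
#' @param window numeric vector of samples.
#' @return non-negative numeric vector of the same length.
#' @export
fft_magnitude <- function(window) {
  if (!all(is.finite(window))) stop("non-finite sample in window")
  Mod(stats::fft(window))
}

#' Spectral featurization of a recording
#'
#' Applies [window_signal()] then [fft_magnitude()] independently to every
#' channel. All channels share the same frame grid, so `frame_times` (the
#' 0-based start sample of each frame) is common.
#'
#' @param rec an [recording()] object.
#' @param cfg a [frame_config()].
#' @return object of class `spectral_frames`: list with `frames` (named list
#'   of `F x window_len` magnitude matrices, one per channel),
#'   `frame_times` (integer vector of frame start samples),
#'   `channel_labels`, `sample_rate`, `cfg`.
#' @export
featurize <- function(rec, cfg = frame_config()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(cfg, "frame_config"))
  if (!all(is.finite(rec$signals))) stop("non-finite sample in recording")
  F_ <- n_frames(n_samples(rec), cfg)
  tap <- if (cfg$taper == "hann") {
    n <- cfg$window_len
    0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n)
  } else NULL
  frames <- lapply(seq_len(n_channels(rec)), function(j) {
    W <- window_signal(rec$signals[, j], cfg)
    if (nrow(W) == 0L)
      return(matrix(numeric(0), nrow = 0L, ncol = cfg$window_len))
    if (!is.null(tap)) W <- sweep(W, 2L, tap, `*`)
    t(Mod(stats::mvfft(t(W))))  # DFT of each row
  })
  names(frames) <- rec$channel_labels
  structure(list(frames = frames,
                 frame_times = (seq_len(F_) - 1L) * cfg$hop,
                 channel_labels = rec$channel_labels,
                 sample_rate = rec$sample_rate, cfg = cfg),
            class = "spectral_frames")
}

#' @export
print.spectral_frames <- function(x, ...) {
  cat(sprintf("<spectral_frames: %d channel(s) x %d frame(s) x %d bins>\n",
              length(x$frames), length(x$frame_times), x$cfg$window_len))
  invisible(x)
}

#' Export spectral frames as TSV
#'
#' One long-format table (channel, frame_index, start_sample, bin, magnitude)
#' for external inspection.
#'
#' @param sf a `spectral_frames` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frames_tsv <- function(sf, path) {
  rows <- lapply(names(sf$frames), function(ch) {
    M <- sf$frames[[ch]]
    if (nrow(M) == 0L) return(NULL)
    data.frame(channel = ch,
               frame_index = rep(seq_len(nrow(M)), each = ncol(M)),
               start_sample = rep(sf$frame_times, each = ncol(M)),
               bin = rep(seq_len(ncol(M)) - 1L, times = nrow(M)),
               magnitude = as.vector(t(M)))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
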