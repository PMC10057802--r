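# Synthetic multichannel EEG with planted rare discharge events, plus a
# matching CHB-MIT-style annotation summary, so the full pipeline is
# testable without downloading clinical data. Background is a mixture of
# alpha- and theta-band sinusoids with Gaussian noise; events superimpose a
# ~3 Hz spike-wave discharge (sharp transient + slow wave per cycle) whose
# RMS amplitude is a configurable multiple of the background RMS.

#' Synthetic EEG generator configuration
#'
#' Defaults emulate a desk-scale version of a long-term scalp EEG
#' monitoring file: 8 bipolar-labelled channels, 10 minutes at 256 Hz, and
#' 3 rare seizure-like events of 10-60 s (planted event time is capped at
#' 20% of the recording; clinical rarity is far lower, and a longer
#' recording with `event_fraction_cap` left at default approaches it).
#'
#' @param n_channels number of channels (default 8).
#' @param duration_s recording length in seconds (default 600; must be a
#'   whole number of seconds).
#' @param sample_rate samples per second (default 256).
#' @param n_events number of planted discharge events (default 3).
#' @param event_duration_range min/max event duration in whole seconds
#'   (default `c(10, 60)`, a scaled-down version of clinically observed
#'   6-752 s seizure durations).
#' @param amplitude_ratio RMS amplitude of the discharge relative to the
#'   background RMS (default 4; ictal rhythms typically run several-fold
#'   above background).
#' @param channel_subset fraction of channels expressing each event
#'   (default 1.0, i.e. a generalized discharge).
#' @param alpha_amp,theta_amp amplitudes (microvolts) of the alpha (8-12 Hz)
#'   and theta (4-7 Hz) background components (defaults 30 and 20).
#' @param noise_sd Gaussian noise standard deviation in microvolts
#'   (default 10).
#' @param spike_hz discharge repetition rate (default 3 Hz spike-wave).
#' @param event_fraction_cap maximum fraction of the recording covered by
#'   events (default 0.2).
#' @param seed integer seed; generation is fully deterministic given it.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_channels = 8L, duration_s = 600L,
                         sample_rate = 256L, n_events = 3L,
                         event_duration_range = c(10L, 60L),
                         amplitude_ratio = 4, channel_subset = 1,
                         alpha_amp = 30, theta_amp = 20, noise_sd = 10,
                         spike_hz = 3, event_fraction_cap = 0.2,
                         seed = 1L) {
  if (duration_s != round(duration_s)) stop("duration_s must be whole seconds")
  if (amplitude_ratio < 0) stop("amplitude_ratio must be non-negative")
  if (channel_subset <= 0 || channel_subset > 1)
    stop("channel_subset must be in (0, 1]")
  structure(list(n_channels = as.integer(n_channels),
                 duration_s = as.integer(duration_s),
                 sample_rate = as.integer(sample_rate),
                 n_events = as.integer(n_events),
                 event_duration_range = as.integer(event_duration_range),
                 amplitude_ratio = amplitude_ratio,
                 channel_subset = channel_subset,
                 alpha_amp = alpha_amp, theta_amp = theta_amp,
                 noise_sd = noise_sd, spike_hz = spike_hz,
                 event_fraction_cap = event_fraction_cap,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# bipolar-style labels cycling over a standard 10-20 longitudinal chain
.synth_labels <- function(n) {
  chain <- c("FP1-F7", "F7-T7", "T7-P7", "P7-O1", "FP1-F3", "F3-C3",
             "C3-P3", "P3-O1", "FP2-F4", "F4-C4", "C4-P4", "P4-O2",
             "FP2-F8", "F8-T8", "T8-P8", "P8-O2")
  rep_len(chain, n)
}

# one spike-wave cycle train: slow wave + sharp Gaussian transient per cycle
.spike_wave <- function(t, hz) {
  phase <- (t * hz) %% 1
  slow <- sin(2 * pi * t * hz)
  spike <- 2 * exp(-((phase - 0.25) / 0.04)^2)
  slow + spike
}

#' Generate a synthetic EEG recording with planted discharges
#'
#' @param cfg a [synth_config()].
#' @return list with `recording` (an [recording()]) and `annotations` (an
#'   [annotation_set()] whose events exactly match the planted intervals).
#' @details Event start times and durations are whole seconds, placed
#'   without overlap and with a 2-second guard gap (an error is raised if
#'   placement fails after bounded retries). Discharge frames concentrate
#'   energy in the 2-4 Hz band and its harmonics, in contrast to the
#'   alpha/theta background.
#' @export
synth_eeg <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  sr <- cfg$sample_rate
  T_ <- cfg$duration_s * sr
  with_seed(cfg$seed, {
    # --- plant events (whole-second grid) ---
    ev <- NULL
    if (cfg$n_events > 0L) {
      cap <- cfg$event_fraction_cap * cfg$duration_s
      durs <- NULL
      for (try in 1:200) {
        d <- sample(seq(cfg$event_duration_range[1L],
                        cfg$event_duration_range[2L]), cfg$n_events,
                    replace = TRUE)
        if (sum(d) <= cap) { durs <- d; break }
      }
      if (is.null(durs))
        stop("cannot satisfy event-time cap of ", cfg$event_fraction_cap,
             " with ", cfg$n_events, " events of ",
             cfg$event_duration_range[1L], "-",
             cfg$event_duration_range[2L], " s")
      gap <- 2L
      placed <- NULL
      for (try in 1:1000) {
        starts <- sort(sample(seq(gap, cfg$duration_s - max(durs) - gap),
                              cfg$n_events))
        ends <- starts + durs
        if (all(diff(starts) >= utils::head(durs, -1L) + gap) &&
            max(ends) <= cfg$duration_s - gap) {
          placed <- data.frame(start = starts, end = ends)
          break
        }
      }
      if (is.null(placed))
        stop("cannot place ", cfg$n_events,
             " non-overlapping events in ", cfg$duration_s, " s")
      ev <- placed
    }
    # --- background + events per channel ---
    t <- (seq_len(T_) - 1L) / sr
    bg_rms <- sqrt(cfg$alpha_amp^2 / 2 + cfg$theta_amp^2 / 2 +
                   cfg$noise_sd^2)
    sw_unit <- .spike_wave(t, cfg$spike_hz)
    sw_gain <- cfg$amplitude_ratio * bg_rms /
      sqrt(mean(.spike_wave(seq(0, 1, by = 1 / sr), cfg$spike_hz)^2))
    signals <- matrix(0, T_, cfg$n_channels)
    ev_channels <- vector("list", if (is.null(ev)) 0L else nrow(ev))
    if (!is.null(ev)) {
      n_expr <- max(1L, ceiling(cfg$channel_subset * cfg$n_channels))
      for (i in seq_len(nrow(ev)))
        ev_channels[[i]] <- sort(sample(cfg$n_channels, n_expr))
    }
    for (j in seq_len(cfg$n_channels)) {
      fa <- stats::runif(1, 8, 12); ft <- stats::runif(1, 4, 7)
      pa <- stats::runif(1, 0, 2 * pi); pt <- stats::runif(1, 0, 2 * pi)
      x <- cfg$alpha_amp * sin(2 * pi * fa * t + pa) +
        cfg$theta_amp * sin(2 * pi * ft * t + pt) +
        stats::rnorm(T_, 0, cfg$noise_sd)
      if (!is.null(ev)) for (i in seq_len(nrow(ev))) {
        if (!(j %in% ev_channels[[i]])) next
        idx <- (ev$start[i] * sr + 1L):(ev$end[i] * sr)
        ramp <- pmin(1, pmin(seq_along(idx), rev(seq_along(idx))) / sr)
        x[idx] <- x[idx] + sw_gain * sw_unit[idx] * ramp
      }
      signals[, j] <- x
    }
    file_id <- sprintf("synth%02d", cfg$seed %% 100L)
    rec <- recording(signals, sr, .synth_labels(cfg$n_channels),
                     file_id = file_id)
    ann <- annotation_set(
      if (is.null(ev)) NULL
      else data.frame(file_id = paste0(file_id, ".edf"),
                      start = as.numeric(ev$start),
                      end = as.numeric(ev$end)),
      stats::setNames(as.numeric(cfg$duration_s), paste0(file_id, ".edf")))
    list(recording = rec, annotations = ann)
  })
}

#' Write a synthetic recording and its annotations to disk
#'
#' Produces an EDF file via [write_edf()] and a CHB-MIT-dialect summary via
#' [write_annotation_summary()]; the pair round-trips through [read_edf()]
#' and [parse_annotation_summary()].
#'
#' @param rec an [recording()].
#' @param ann an [annotation_set()].
#' @param dir output directory (created if missing).
#' @return named character vector with elements `edf` and `summary`.
#' @export
write_fixture <- function(rec, ann, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  edf_path <- file.path(dir, paste0(rec$file_id, ".edf"))
  sum_path <- file.path(dir, paste0(rec$file_id, "-summary.txt"))
  write_edf(rec, edf_path)
  write_annotation_summary(ann, sum_path, rec$sample_rate)
  c(edf = edf_path, summary = sum_path)
}
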