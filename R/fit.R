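# The core fit: per-channel unsupervised segmentation of a recording.
# Featurize -> train autoencoder -> reconstruction error -> hypothesize HMM
# states -> label track, independently for every channel.

#' Unsupervised per-channel segmentation of an EEG recording
#'
#' Fits the full unsupervised pipeline to one recording: each channel is cut
#' into overlapping windows, transformed to DFT magnitudes, modelled by a
#' per-channel bottleneck autoencoder, and the per-frame reconstruction-error
#' vectors are segmented into discrete states by a penalized-Viterbi HMM with
#' a generative state-hypothesis loop. Frames in non-background states are
#' flagged as candidate anomalies for expert review. Every channel is
#' processed independently (results do not depend on channel order or on the
#' presence of other channels), and the whole fit is deterministic given
#' `ae$seed`.
#'
#' @param rec an [recording()] object.
#' @param frame a [frame_config()].
#' @param ae an [ae_config()]; channel `j` trains under seed
#'   `ae$seed + j - 1` so channels are independent yet reproducible.
#' @param hmm an [hmm_config()].
#' @param channels optional integer indices or label regular expression
#'   selecting channels to process (default: all).
#' @param exclude optional label regular expression of channels to drop
#'   (applied after `channels`).
#' @param hmm_input what the segmenter sees per frame: the reconstruction
#'   error vector (default), the scalar error, or the raw magnitude
#'   spectrum.
#' @param flag_policy,theta anomaly binarization, see [label_track()].
#' @param pool_channels train a single autoencoder on all selected channels'
#'   frames pooled (default FALSE: one autoencoder per channel).
#' @param workers number of parallel workers for the per-channel loop
#'   (results are identical for any value; default 1).
#' @return object of class `eeg_segmentation`: per-channel autoencoder
#'   models, HMM models and state tracks, plus the shared frame grid and all
#'   configurations.
#' @examples
#' synth <- synth_eeg(synth_config(n_channels = 2, duration_s = 60,
#'                                 n_events = 1, seed = 7))
#' fit <- eeg_segment(synth$recording)
#' summary(fit)
#' @export
eeg_segment <- function(rec, frame = frame_config(), ae = ae_config(),
                        hmm = hmm_config(), channels = NULL, exclude = NULL,
                        hmm_input = c("error_vec", "error_scalar",
                                      "spectrum"),
                        flag_policy = c("non_background", "error_ratio"),
                        theta = 2, pool_channels = FALSE, workers = 1L) {
  stopifnot(inherits(rec, "eeg_recording"))
  hmm_input <- match.arg(hmm_input)
  flag_policy <- match.arg(flag_policy)
  sel <- seq_len(n_channels(rec))
  if (!is.null(channels)) {
    sel <- if (is.numeric(channels)) as.integer(channels)
           else which(grepl(channels, rec$channel_labels))
  }
  if (!is.null(exclude))
    sel <- sel[!grepl(exclude, rec$channel_labels[sel])]
  if (length(sel) == 0L) stop("no channels selected")

  sf <- featurize(rec, frame)
  if (length(sf$frame_times) == 0L)
    stop("recording too short for one analysis window")

  pooled_model <- NULL
  if (pool_channels) {
    pooled <- do.call(rbind, sf$frames[sel])
    cfg_p <- ae; cfg_p$seed <- ae$seed
    pooled_model <- ae_train(ae_init(cfg_p), pooled)
  }

  fit_channel <- function(j) {
    frames_j <- sf$frames[[j]]
    model <- if (pool_channels) pooled_model else {
      cfg_j <- ae
      cfg_j$seed <- ae$seed + j - 1L
      ae_train(ae_init(cfg_j), frames_j)
    }
    ef <- ae_error(model, frames_j)
    Xh <- switch(hmm_input,
                 error_vec = ef$errors,
                 error_scalar = matrix(ef$scalar, ncol = 1L),
                 spectrum = frames_j)
    hs <- hypothesize_states(Xh, hmm)
    track <- label_track(hs$path, hs$model, ef$scalar,
                         policy = flag_policy, theta = theta)
    list(ae = model, hmm = hs$model, track = track, scalar = ef$scalar)
  }
  per_ch <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(sel, fit_channel, mc.cores = workers)
  } else lapply(sel, fit_channel)
  names(per_ch) <- rec$channel_labels[sel]

  structure(list(channels = per_ch,
                 channel_labels = rec$channel_labels[sel],
                 frame_times = sf$frame_times,
                 sample_rate = rec$sample_rate,
                 file_id = rec$file_id,
                 frame = frame, ae = ae, hmm = hmm,
                 hmm_input = hmm_input, flag_policy = flag_policy,
                 theta = theta, pool_channels = pool_channels,
                 call = match.call()),
            class = "eeg_segmentation")
}

#' Per-frame, per-channel anomaly flags of a fit
#' @param fit an `eeg_segmentation`.
#' @return logical matrix `F x N`.
#' @export
flag_matrix <- function(fit) {
  stopifnot(inherits(fit, "eeg_segmentation"))
  sapply(fit$channels, function(ch) ch$track$flags)
}

#' @export
print.eeg_segmentation <- function(x, ...) {
  cat(sprintf("<eeg_segmentation '%s': %d channel(s), %d frame(s)>\n",
              x$file_id, length(x$channels), length(x$frame_times)))
  cat(sprintf("  states per channel: %s\n",
              paste(vapply(x$channels,
                           function(ch) length(ch$track$state_mean_error),
                           integer(1)), collapse = " ")))
  cat(sprintf("  flagged frames: %d of %d channel-frames\n",
              sum(flag_matrix(x)),
              length(x$frame_times) * length(x$channels)))
  invisible(x)
}

#' @export
summary.eeg_segmentation <- function(object, ...) {
  tab <- data.frame(
    channel = object$channel_labels,
    n_states = vapply(object$channels,
                      function(ch) length(ch$track$state_mean_error),
                      integer(1)),
    background = vapply(object$channels,
                        function(ch) ch$track$background_id, integer(1)),
    flagged = vapply(object$channels,
                     function(ch) sum(ch$track$flags), integer(1)),
    mean_error = vapply(object$channels,
                        function(ch) mean(ch$scalar), numeric(1)),
    row.names = NULL)
  structure(list(file_id = object$file_id, table = tab,
                 n_frames = length(object$frame_times)),
            class = "summary.eeg_segmentation")
}

#' @export
print.summary.eeg_segmentation <- function(x, ...) {
  cat(sprintf("Segmentation of '%s' (%d frames per channel)\n",
              x$file_id, x$n_frames))
  print(x$table, digits = 4)
  invisible(x)
}

#' @export
residuals.eeg_segmentation <- function(object, ...) {
  sapply(object$channels, function(ch) ch$scalar)
}

#' State heatmap of a segmentation
#'
#' Channels on the y axis, frames on the x axis, colored by state id
#' (background state in grey, other states in warm colors) — the raw-data
#' form of the usual segmentation heatmap.
#'
#' @param x an `eeg_segmentation`.
#' @param ... passed to [graphics::image()].
#' @export
plot.eeg_segmentation <- function(x, ...) {
  M <- sapply(x$channels, function(ch) {
    s <- ch$track$states
    # 0 = background, >0 = anomaly states in order
    match(s, setdiff(sort(unique(s)), ch$track$background_id),
          nomatch = 0L)
  })
  K <- max(M) + 1L
  cols <- c("grey85", grDevices::hcl.colors(max(K - 1L, 1L), "YlOrRd",
                                            rev = TRUE))
  graphics::image(x = x$frame_times / x$sample_rate,
                  y = seq_len(ncol(M)), z = M, zlim = c(0, K - 1L),
                  col = cols[seq_len(K)], xlab = "time (s)",
                  ylab = "channel", yaxt = "n", ...)
  graphics::axis(2, at = seq_len(ncol(M)), labels = x$channel_labels,
                 las = 2, cex.axis = 0.6)
  invisible(x)
}

#' Apply a fitted segmentation model to a new recording
#'
#' Reuses the trained per-channel autoencoders and HMM state models to label
#' a new recording with the same channel layout: no retraining, only error
#' computation and Viterbi decoding.
#'
#' @param object an `eeg_segmentation`.
#' @param newdata an [recording()] with the same channels.
#' @param ... unused.
#' @return list of [label_track()] objects, one per channel.
#' @export
predict.eeg_segmentation <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "eeg_recording"))
  sf <- featurize(newdata, object$frame)
  lapply(seq_along(object$channels), function(i) {
    ch <- object$channels[[i]]
    lab <- object$channel_labels[i]
    j <- match(lab, newdata$channel_labels)
    if (is.na(j)) stop("channel '", lab, "' absent from newdata")
    ef <- ae_error(ch$ae, sf$frames[[j]])
    Xh <- switch(object$hmm_input,
                 error_vec = ef$errors,
                 error_scalar = matrix(ef$scalar, ncol = 1L),
                 spectrum = sf$frames[[j]])
    path <- viterbi_segment(Xh, ch$hmm, object$hmm)
    label_track(path, ch$hmm, ef$scalar, policy = object$flag_policy,
                theta = object$theta)
  })
}
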