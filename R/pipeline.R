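# Orchestration: run the full pipeline on one EDF file or a directory of
# them, writing reproducible plain-text outputs (state-track TSV, model
# JSON, run manifest, metrics JSON when annotations are available).

#' Write a segmentation's state track as TSV
#'
#' Columns: `channel`, `frame_index` (1-based), `start_sample` (0-based),
#' `state_id`, `scalar_error`, `flag` — the machine-readable form of the
#' per-channel state heatmap. Output is byte-deterministic for a fixed fit.
#'
#' @param fit an [eeg_segment()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_state_track <- function(fit, path) {
  stopifnot(inherits(fit, "eeg_segmentation"))
  F_ <- length(fit$frame_times)
  rows <- do.call(rbind, lapply(seq_along(fit$channels), function(i) {
    ch <- fit$channels[[i]]
    data.frame(channel = fit$channel_labels[i],
               frame_index = seq_len(F_),
               start_sample = fit$frame_times,
               state_id = ch$track$states,
               scalar_error = sprintf("%.10g", ch$scalar),
               flag = as.integer(ch$track$flags))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Evaluate a fitted segmentation against annotations
#'
#' Computes the frame-level confusion and eleven metrics (a frame is
#' globally flagged when flagged in at least `min_channels` channels),
#' event-level capture and per-event channel coincidence.
#'
#' @param fit an [eeg_segment()] result.
#' @param ann an [annotation_set()].
#' @param min_channels channels that must flag a frame for a global call
#'   (default 1).
#' @return list with `metrics` (a [compute_metrics()] report), `confusion`,
#'   `event_capture`, `coincidence`, and `per_channel` confusion counts.
#' @export
evaluate_segmentation <- function(fit, ann, min_channels = 1L) {
  stopifnot(inherits(fit, "eeg_segmentation"),
            inherits(ann, "annotation_set"))
  ev <- events_for(ann, fit$file_id)
  truth <- frame_truth(ev, fit$frame_times, fit$frame, fit$sample_rate)
  fm <- flag_matrix(fit)
  fm <- matrix(fm, nrow = length(fit$frame_times))
  global <- rowSums(fm) >= min_channels
  cc <- confusion(global, truth)
  cap <- event_capture(fm, ev, fit$frame_times, fit$frame,
                       fit$sample_rate)
  per_channel <- lapply(seq_len(ncol(fm)),
                        function(j) confusion(fm[, j], truth))
  names(per_channel) <- fit$channel_labels
  list(metrics = compute_metrics(cc), confusion = cc,
       event_capture = cap, coincidence = cap$coincidence,
       per_channel = per_channel)
}

#' Run the full pipeline on one EDF recording
#'
#' Reads the EDF, fits [eeg_segment()], and writes to `output_dir`: the
#' state-track TSV, one autoencoder model JSON per channel, a run manifest
#' (all parameters, seed, package version), and — when an annotation summary
#' is supplied — a metrics JSON. Outputs are byte-identical across runs with
#' the same inputs and seed, and independent of `workers`.
#'
#' @param input path to an EDF file.
#' @param output_dir directory for the output bundle (created if needed).
#' @param frame,ae,hmm configurations, see [eeg_segment()].
#' @param annotations optional path to a CHB-MIT-style summary file.
#' @param channels,exclude channel selection, see [eeg_segment()].
#' @param hmm_input,flag_policy,theta,pool_channels,workers see
#'   [eeg_segment()].
#' @param min_channels global frame call threshold, see
#'   [evaluate_segmentation()].
#' @param save_models write per-channel autoencoder JSON files
#'   (default TRUE).
#' @return invisibly, a list with the fit, the evaluation (or NULL) and the
#'   written paths.
#' @export
run_recording <- function(input, output_dir, frame = frame_config(),
                          ae = ae_config(), hmm = hmm_config(),
                          annotations = NULL, channels = NULL,
                          exclude = NULL, hmm_input = "error_vec",
                          flag_policy = "non_background", theta = 2,
                          pool_channels = FALSE, workers = 1L,
                          min_channels = 1L, save_models = TRUE) {
  rec <- read_edf(input)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- eeg_segment(rec, frame = frame, ae = ae, hmm = hmm,
                     channels = channels, exclude = exclude,
                     hmm_input = hmm_input, flag_policy = flag_policy,
                     theta = theta, pool_channels = pool_channels,
                     workers = workers)
  stem <- rec$file_id
  paths <- c(track = file.path(output_dir,
                               paste0(stem, "_states.tsv")))
  write_state_track(fit, paths[["track"]])
  if (save_models) {
    mdir <- file.path(output_dir, paste0(stem, "_models"))
    dir.create(mdir, showWarnings = FALSE)
    for (i in seq_along(fit$channels)) {
      safe <- gsub("[^A-Za-z0-9]+", "_", fit$channel_labels[i])
      ae_save(fit$channels[[i]]$ae,
              file.path(mdir, paste0(sprintf("%02d_", i), safe, ".json")))
    }
    paths[["models"]] <- mdir
  }
  manifest <- list(
    input = basename(input), file_id = stem,
    package_version = as.character(utils::packageVersion("eegseg")),
    n_channels = length(fit$channels), n_frames = length(fit$frame_times),
    frame = unclass(frame), ae = unclass(ae), hmm = unclass(hmm),
    hmm_input = hmm_input, flag_policy = flag_policy, theta = theta,
    pool_channels = pool_channels, min_channels = min_channels)
  paths[["manifest"]] <- file.path(output_dir,
                                   paste0(stem, "_manifest.json"))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  eval_out <- NULL
  if (!is.null(annotations)) {
    ann <- if (inherits(annotations, "annotation_set")) annotations
           else parse_annotation_summary(annotations)
    eval_out <- evaluate_segmentation(fit, ann, min_channels)
    paths[["metrics"]] <- file.path(output_dir,
                                    paste0(stem, "_metrics.json"))
    rep <- eval_out$metrics
    jsonlite::write_json(
      list(metrics = unclass(rep)[setdiff(names(rep), "counts")],
           counts = rep$counts,
           undefined = attr(rep, "undefined"),
           event_capture = list(captured = eval_out$event_capture$captured,
                                total = eval_out$event_capture$total),
           coincidence = eval_out$coincidence),
      paths[["metrics"]], auto_unbox = TRUE, digits = NA, pretty = TRUE,
      na = "null")
  }
  invisible(list(fit = fit, evaluation = eval_out, paths = paths))
}

#' Run the pipeline over a directory of EDF files
#'
#' Processes every `*.edf` file in `dir` independently (streaming: one file
#' in memory at a time), writing one output bundle per file plus a
#' micro-aggregated metrics JSON when annotations are given. Per-file
#' failures are caught, reported in the aggregate, and do not stop the
#' batch.
#'
#' @param dir directory containing EDF files.
#' @param output_dir output root (one subdirectory per file).
#' @param annotations optional path to a summary file covering the batch.
#' @param ... passed to [run_recording()].
#' @return invisibly, a list with `results` (per-file), `failures` (named
#'   error messages), `aggregate` (micro-summed confusion + metrics + event
#'   capture, or NULL), and `status` (0 = all ok, 1 = all failed,
#'   2 = partial).
#' @export
run_batch <- function(dir, output_dir, annotations = NULL, ...) {
  files <- sort(list.files(dir, pattern = "\\.edf$", ignore.case = TRUE,
                           full.names = TRUE))
  if (length(files) == 0L) stop("no EDF files in ", dir)
  ann <- if (is.null(annotations)) NULL
         else if (inherits(annotations, "annotation_set")) annotations
         else parse_annotation_summary(annotations)
  results <- list(); failures <- character(0)
  for (f in files) {
    stem <- sub("\\.[Ee][Dd][Ff]$", "", basename(f))
    res <- tryCatch(
      run_recording(f, file.path(output_dir, stem), annotations = ann, ...),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[stem] <- conditionMessage(res)
    } else {
      res$fit <- NULL  # keep memory bounded across files
      results[[stem]] <- res
    }
  }
  aggregate <- NULL
  evals <- Filter(Negate(is.null), lapply(results, `[[`, "evaluation"))
  if (length(evals)) {
    cc <- sum_confusion(lapply(evals, `[[`, "confusion"))
    cap <- lapply(evals, `[[`, "event_capture")
    aggregate <- list(
      confusion = cc, metrics = compute_metrics(cc),
      event_capture = list(
        captured = sum(vapply(cap, `[[`, 0L, "captured")),
        total = sum(vapply(cap, `[[`, 0L, "total"))),
      coincidence = unlist(lapply(evals, `[[`, "coincidence"),
                           use.names = FALSE))
    rep <- aggregate$metrics
    jsonlite::write_json(
      list(files = length(results), failures = as.list(failures),
           metrics = unclass(rep)[setdiff(names(rep), "counts")],
           counts = rep$counts,
           event_capture = aggregate$event_capture,
           coincidence = aggregate$coincidence),
      file.path(output_dir, "aggregate_metrics.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  }
  status <- if (length(failures) == 0L) 0L
            else if (length(results) == 0L) 1L else 2L
  invisible(list(results = results, failures = failures,
                 aggregate = aggregate, status = status))
}
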