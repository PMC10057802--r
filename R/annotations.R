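# CHB-MIT-style plain-text annotation summaries: per EDF file, a block
# declaring "File Name:", optional start/end clock times, a seizure count,
# and one start/end pair per seizure. Two dialects exist: "Seizure Start
# Time:" (single-seizure files) and the numbered "Seizure 1 Start Time:".

#' Parse a CHB-MIT-style seizure annotation summary
#'
#' Reads a plain-text summary in the dialect used by the CHB-MIT scalp EEG
#' corpus (`chbXX-summary.txt`) and returns the declared seizure intervals.
#' Both the plain (`Seizure Start Time:`) and numbered
#' (`Seizure 1 Start Time:`) variants are accepted; the count of parsed
#' events per file must equal the declared `Number of Seizures in File:`.
#'
#' @param path path to the summary text file.
#' @return an [annotation_set()] whose `events` rows are
#'   `(file_id, start, end)` in seconds and whose `file_durations` are
#'   derived from the declared file start/end clock times where present
#'   (`NA` otherwise; midnight wrap handled).
#' @export
parse_annotation_summary <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  grab <- function(line, pattern) trimws(sub(pattern, "\\1", line))

  cur_file <- NULL; cur_start <- NULL; cur_end <- NULL
  declared <- integer(0); durations <- numeric(0)
  starts <- list(); ends <- list()
  flush_file <- function() {
    if (is.null(cur_file)) return()
    if (is.na(declared[[cur_file]]))
      stop("missing 'Number of Seizures in File:' line for '", cur_file, "'")
    s <- unlist(starts[[cur_file]]); e <- unlist(ends[[cur_file]])
    if (length(s) != declared[[cur_file]] || length(e) != declared[[cur_file]])
      stop("seizure count mismatch in '", cur_file, "': declared ",
           declared[[cur_file]], ", parsed ", length(s), " start / ",
           length(e), " end time(s)")
  }
  clock <- function(s) {
    p <- as.numeric(strsplit(s, ":", fixed = TRUE)[[1L]])
    if (length(p) != 3L || anyNA(p)) return(NA_real_)
    p[1L] * 3600 + p[2L] * 60 + p[3L]
  }
  file_start <- NA_real_

  for (ln in lines) {
    if (grepl("^\\s*File Name:", ln)) {
      flush_file()
      cur_file <- grab(ln, "^\\s*File Name:\\s*(.*)$")
      declared[cur_file] <- NA_integer_
      durations[cur_file] <- NA_real_
      starts[[cur_file]] <- list(); ends[[cur_file]] <- list()
      file_start <- NA_real_
    } else if (grepl("^\\s*File Start Time:", ln)) {
      file_start <- clock(grab(ln, "^\\s*File Start Time:\\s*(.*)$"))
    } else if (grepl("^\\s*File End Time:", ln)) {
      fe <- clock(grab(ln, "^\\s*File End Time:\\s*(.*)$"))
      if (!is.na(file_start) && !is.na(fe)) {
        d <- fe - file_start
        if (d <= 0) d <- d + 86400  # midnight wrap
        durations[cur_file] <- d
      }
    } else if (grepl("^\\s*Number of Seizures in File:", ln)) {
      declared[cur_file] <-
        as.integer(grab(ln, "^\\s*Number of Seizures in File:\\s*(\\d+).*$"))
    } else if (grepl("^\\s*Seizure( \\d+)? Start Time:", ln)) {
      if (is.null(cur_file))
        stop("seizure time declared before any 'File Name:' line")
      v <- as.numeric(grab(ln,
        "^\\s*Seizure(?: \\d+)? Start Time:\\s*([0-9.]+).*$"))
      starts[[cur_file]] <- c(starts[[cur_file]], v)
    } else if (grepl("^\\s*Seizure( \\d+)? End Time:", ln)) {
      v <- as.numeric(grab(ln,
        "^\\s*Seizure(?: \\d+)? End Time:\\s*([0-9.]+).*$"))
      ends[[cur_file]] <- c(ends[[cur_file]], v)
    }
  }
  flush_file()

  ev <- do.call(rbind, lapply(names(starts), function(f) {
    s <- unlist(starts[[f]]); e <- unlist(ends[[f]])
    if (length(s) == 0L) return(NULL)
    data.frame(file_id = f, start = s, end = e, stringsAsFactors = FALSE)
  }))
  if (!is.null(ev) && any(ev$end <= ev$start)) {
    bad <- ev[ev$end <= ev$start, ][1L, ]
    stop("seizure end time (", bad$end, ") not after start time (",
         bad$start, ") in '", bad$file_id, "'")
  }
  annotation_set(ev, durations)
}

#' Write an annotation set as a CHB-MIT-style summary file
#'
#' Emits the numbered dialect (`Seizure 1 Start Time: ... seconds`) parseable
#' by [parse_annotation_summary()]; used by the synthetic-fixture writer.
#'
#' @param ann an [annotation_set()].
#' @param path output path.
#' @param sample_rate sampling rate declared in the file header line.
#' @return `path`, invisibly.
#' @export
write_annotation_summary <- function(ann, path, sample_rate = 256L) {
  out <- c(sprintf("Data Sampling Rate: %d Hz", as.integer(sample_rate)), "")
  files <- names(ann$file_durations)
  if (length(files) == 0L) files <- unique(ann$events$file_id)
  for (f in files) {
    ev <- ann$events[ann$events$file_id == f, , drop = FALSE]
    dur <- ann$file_durations[f]
    out <- c(out, paste0("File Name: ", f))
    if (!is.na(dur)) {
      out <- c(out, "File Start Time: 00:00:00",
               sprintf("File End Time: %02d:%02d:%02d",
                       dur %/% 3600, (dur %% 3600) %/% 60,
                       round(dur %% 60)))
    }
    out <- c(out, sprintf("Number of Seizures in File: %d", nrow(ev)))
    if (nrow(ev)) for (k in seq_len(nrow(ev))) {
      out <- c(out,
        sprintf("Seizure %d Start Time: %s seconds", k,
                format(ev$start[k], scientific = FALSE, trim = TRUE)),
        sprintf("Seizure %d End Time: %s seconds", k,
                format(ev$end[k], scientific = FALSE, trim = TRUE)))
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}
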