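# European Data Format (EDF) I/O. EDF stores a 256-byte fixed ASCII header,
# one 256-byte ASCII header block per signal, then data records of 2-byte
# little-endian integers, channel-sequential within each record. Physical
# values are recovered by the linear map declared per channel via the
# physical/digital min/max header fields.

.edf_field <- function(raw, from, len, name, numeric = FALSE) {
  txt <- rawToChar(raw[from:(from + len - 1L)])
  val <- trimws(txt)
  if (numeric) {
    num <- suppressWarnings(as.numeric(val))
    if (is.na(num))
      stop("malformed EDF header: field '", name, "' is not numeric (got '",
           val, "')")
    return(num)
  }
  val
}

.edf_pad <- function(x, width, name) {
  x <- as.character(x)
  if (nchar(x, type = "bytes") > width)
    stop("EDF header field '", name, "' exceeds ", width, " bytes: '", x, "'")
  formatC(x, width = -width, flag = " ")
}

# Format a physical bound in <= 8 ASCII chars and return the exactly
# representable value actually written, so digitization uses the same number
# the reader will parse.
.edf_phys <- function(x) {
  s <- formatC(x, format = "g", digits = 6, width = 1)
  if (nchar(s) > 8) s <- formatC(x, format = "g", digits = 4, width = 1)
  list(text = s, value = as.numeric(s))
}

#' Read a European Data Format (EDF) file
#'
#' Parses the EDF header and data records and returns the signals with the
#' declared physical calibration applied. Channels recorded in millivolts or
#' volts are converted to microvolts; channel labels are preserved verbatim.
#'
#' @param path path to an EDF file.
#' @return an [recording()] object (`eeg_recording`).
#' @details All signals must share one sampling rate (the per-channel method
#'   downstream is rate-agnostic, but a single recording container carries one
#'   rate); files mixing rates are rejected with the offending rates listed.
#'   EDF+ annotation channels are not interpreted (they are returned as
#'   ordinary channels if present).
#' @seealso [write_edf()]
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 256L)
  if (length(hdr) < 256L)
    stop("malformed EDF header: file truncated before fixed header (",
         length(hdr), " bytes)")
  version <- .edf_field(hdr, 1L, 8L, "version")
  if (version != "0")
    stop("malformed EDF header: field 'version' must be '0', got '",
         version, "'")
  startdate  <- .edf_field(hdr, 169L, 8L, "startdate")
  starttime  <- .edf_field(hdr, 177L, 8L, "starttime")
  hdr_bytes  <- .edf_field(hdr, 185L, 8L, "header bytes", numeric = TRUE)
  n_records  <- .edf_field(hdr, 237L, 8L, "number of data records",
                           numeric = TRUE)
  rec_dur    <- .edf_field(hdr, 245L, 8L, "data record duration",
                           numeric = TRUE)
  ns         <- .edf_field(hdr, 253L, 4L, "number of signals",
                           numeric = TRUE)
  if (ns < 1) stop("malformed EDF header: field 'number of signals' is ", ns)
  ns <- as.integer(ns)

  sig_hdr <- readBin(con, "raw", n = 256L * ns)
  if (length(sig_hdr) < 256L * ns)
    stop("malformed EDF header: file truncated inside signal headers")
  fld <- function(offset, width, name, numeric = FALSE)
    vapply(seq_len(ns), function(i)
      .edf_field(sig_hdr, offset * ns + (i - 1L) * width + 1L, width,
                 paste0(name, "[", i, "]"), numeric = numeric),
      if (numeric) numeric(1) else character(1))
  labels    <- fld(0L,  16L, "label")
  phys_dim  <- fld(96L, 8L, "physical dimension")
  phys_min  <- fld(104L, 8L, "physical minimum", numeric = TRUE)
  phys_max  <- fld(112L, 8L, "physical maximum", numeric = TRUE)
  dig_min   <- fld(120L, 8L, "digital minimum", numeric = TRUE)
  dig_max   <- fld(128L, 8L, "digital maximum", numeric = TRUE)
  spr       <- fld(216L, 8L, "samples per record", numeric = TRUE)
  if (any(dig_max <= dig_min))
    stop("malformed EDF header: digital maximum must exceed digital minimum")
  if (rec_dur <= 0)
    stop("malformed EDF header: field 'data record duration' is ", rec_dur)
  rates <- spr / rec_dur
  if (length(unique(rates)) > 1L)
    stop("channels have differing sampling rates: ",
         paste(unique(rates), collapse = ", "), " Hz")

  spr <- as.integer(spr)
  n_records <- as.integer(n_records)
  if (n_records < 0L) {  # -1 = unknown; infer from file size
    data_bytes <- file.size(path) - hdr_bytes
    n_records <- as.integer(data_bytes %/% (2L * sum(spr)))
  }
  n_int <- sum(spr) * n_records
  dat <- readBin(con, "integer", n = n_int, size = 2L, endian = "little")
  if (length(dat) < n_int)
    stop("malformed EDF file: data section truncated (expected ", n_int,
         " samples, found ", length(dat), ")")
  # record layout: per record, all samples of signal 1, then signal 2, ...
  arr <- array(dat, dim = c(spr[1L], ns, n_records))
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  signals <- vapply(seq_len(ns), function(j) {
    x <- as.numeric(arr[, j, ])
    x <- (x - dig_min[j]) * gain[j] + phys_min[j]
    u <- tolower(phys_dim[j])
    if (u == "mv") x * 1e3 else if (u == "v") x * 1e6 else x
  }, numeric(spr[1L] * n_records))
  signals <- matrix(signals, ncol = ns)

  start_time <- tryCatch(
    as.POSIXct(paste(startdate, starttime), format = "%d.%m.%y %H.%M.%S",
               tz = "UTC"),
    error = function(e) NULL)
  recording(signals, sample_rate = as.integer(round(rates[1L])),
            channel_labels = labels, start_time = start_time,
            file_id = sub("\\.[Ee][Dd][Ff]$", "", basename(path)))
}

#' Write a recording to a European Data Format (EDF) file
#'
#' Writes a standard-conformant 16-bit EDF file (one-second data records)
#' readable by [read_edf()] and by standard EDF tooling. Each channel is
#' digitized against a symmetric physical range covering its amplitude; the
#' round-trip error is at most one digital quantization step.
#'
#' @param rec an [recording()] object; all samples must be finite and the
#'   signal length a whole number of seconds.
#' @param path output path.
#' @param physical_dim unit string written per channel (default `"uV"`).
#' @param physical_max optional declared physical range (scalar or one value
#'   per channel); samples exceeding it are an error naming the channel. By
#'   default the range is fitted to each channel's peak amplitude.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, physical_dim = "uV", physical_max = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (n_channels(rec) < 1L) stop("recording has an empty channel list")
  if (!all(is.finite(rec$signals))) {
    bad <- which(colSums(!is.finite(rec$signals)) > 0L)
    stop("non-finite samples in channel(s): ",
         paste(rec$channel_labels[bad], collapse = ", "))
  }
  T_ <- n_samples(rec); N <- n_channels(rec); spr <- rec$sample_rate
  if (T_ %% spr != 0L)
    stop("signal length (", T_, ") must be a whole number of 1-second data ",
         "records (multiple of ", spr, ")")
  n_rec <- T_ %/% spr
  dmin <- -32768; dmax <- 32767

  if (is.null(physical_max)) {
    pm <- vapply(seq_len(N), function(j) {
      amax <- max(abs(rec$signals[, j]))
      if (amax == 0) amax <- 1
      .edf_phys(amax * 1.0001)$value  # headroom so rounding never clips
    }, numeric(1))
  } else {
    pm <- vapply(rep_len(as.numeric(physical_max), N),
                 function(p) .edf_phys(p)$value, numeric(1))
  }
  over <- which(sweep(abs(rec$signals), 2L, pm, ">"))
  if (length(over))
    stop("amplitude exceeds declared physical range in channel ",
         rec$channel_labels[(over[1L] - 1L) %/% T_ + 1L])
  gain <- (2 * pm) / (dmax - dmin)
  dig <- vapply(seq_len(N), function(j)
    as.integer(pmin(dmax, pmax(dmin,
      round((rec$signals[, j] + pm[j]) / gain[j]) + dmin))),
    integer(T_))
  dig <- matrix(dig, ncol = N)

  st <- rec$start_time
  if (is.null(st)) st <- as.POSIXct("2000-01-01 00:00:00", tz = "UTC")
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(x, w, nm) writeChar(.edf_pad(x, w, nm), con, eos = NULL)
  put("0", 8, "version")
  put("X X X X", 80, "patient")
  put(paste("Startdate X", rec$file_id), 80, "recording")
  put(format(st, "%d.%m.%y"), 8, "startdate")
  put(format(st, "%H.%M.%S"), 8, "starttime")
  put(256L * (1L + N), 8, "header bytes")
  put("", 44, "reserved")
  put(n_rec, 8, "number of data records")
  put("1", 8, "data record duration")
  put(N, 4, "number of signals")
  for (lab in rec$channel_labels) put(lab, 16, "label")
  for (j in seq_len(N)) put("", 80, "transducer")
  for (j in seq_len(N)) put(physical_dim, 8, "physical dimension")
  for (j in seq_len(N)) put(.edf_phys(-pm[j])$text, 8, "physical minimum")
  for (j in seq_len(N)) put(.edf_phys(pm[j])$text, 8, "physical maximum")
  for (j in seq_len(N)) put(dmin, 8, "digital minimum")
  for (j in seq_len(N)) put(dmax, 8, "digital maximum")
  for (j in seq_len(N)) put("", 80, "prefiltering")
  for (j in seq_len(N)) put(spr, 8, "samples per record")
  for (j in seq_len(N)) put("", 32, "reserved")
  # interleave: (samples within record) x (channel) x (record)
  arr <- aperm(array(dig, dim = c(spr, n_rec, N)), c(1L, 3L, 2L))
  writeBin(as.integer(arr), con, size = 2L, endian = "little")
  invisible(path)
}

#' Digital quantization step of a written EDF channel
#'
#' The physical value of one digital unit for a signal of the given peak
#' amplitude, as digitized by [write_edf()]. Round-trip deviations are
#' bounded by one such step.
#'
#' @param peak peak absolute amplitude of the channel (microvolts).
#' @return quantization step in microvolts.
#' @export
edf_quantization_step <- function(peak) {
  if (peak == 0) peak <- 1
  2 * .edf_phys(peak * 1.0001)$value / 65535
}
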