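# Readers and writers for the plain formats the pipeline touches:
# temperature and hypnogram CSV, EEG as EDF or CSV + JSON sidecar.

#' Write a temperature trace to CSV
#'
#' Columns `time_s`, `temp_c`, values rounded to 6 decimals (lossless for
#' millikelvin-resolution data).
#'
#' @param trace a [temperature_trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_temperature_csv <- function(trace, path) {
  stopifnot(inherits(trace, "temperature_trace"))
  df <- data.frame(time_s = round(trace_times(trace), 6),
                   temp_c = round(trace$values, 6))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a temperature trace from CSV
#'
#' Expects columns `time_s` and `temp_c` with a uniform, monotone time axis
#' (tolerance 1% of the sampling interval).
#'
#' @param path input file path.
#' @return a [temperature_trace()].
#' @export
read_temperature_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "temp_c") %in% names(df)))
    stop("temperature CSV must have columns time_s and temp_c")
  tt <- df$time_s
  if (length(tt) < 2L) stop("temperature CSV needs at least two samples")
  dt <- diff(tt)
  step <- stats::median(dt)
  if (step <= 0) stop("time axis must be strictly increasing")
  bad <- which(abs(dt - step) > 0.01 * step)
  if (length(bad) > 0L)
    stop(sprintf("non-uniform timestamps at line %d (data row %d)",
                 bad[1] + 2L, bad[1] + 1L))
  temperature_trace(df$temp_c, rate = 1 / step, start_time = tt[1])
}

#' Write a hypnogram to CSV
#'
#' Columns `epoch_start_s`, `state`, `phase`.
#'
#' @param hyp a [hypnogram()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hypnogram_csv <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  df <- data.frame(epoch_start_s = trace_times(hyp),
                   state = hyp$labels, phase = hyp$phase)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a hypnogram from CSV
#'
#' Validates state tokens against [SLEEP_STATES] and the fixed 4 s epoch
#' grid; an unknown token raises an error naming it and its line.
#'
#' @param path input file path.
#' @param epoch_len expected epoch length in seconds.
#' @return a [hypnogram()].
#' @export
read_hypnogram_csv <- function(path, epoch_len = 4) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("epoch_start_s", "state") %in% names(df)))
    stop("hypnogram CSV must have columns epoch_start_s and state")
  bad <- which(!(df$state %in% SLEEP_STATES))
  if (length(bad) > 0L)
    stop(sprintf("unknown state token '%s' at line %d",
                 df$state[bad[1]], bad[1] + 1L))
  if (nrow(df) > 1L) {
    dt <- diff(df$epoch_start_s)
    if (any(abs(dt - epoch_len) > 1e-6))
      stop(sprintf("epoch grid is not uniform %g s at line %d", epoch_len,
                   which(abs(dt - epoch_len) > 1e-6)[1] + 2L))
  }
  phase <- if ("phase" %in% names(df)) df$phase else NULL
  hypnogram(df$state, epoch_len = epoch_len, phase = phase)
}

#' Write an EEG trace to CSV with a JSON sidecar
#'
#' Single column `eeg_uv`; the sidecar (`<path>.json`) carries the sampling
#' rate, filters and an optional generator seed.
#'
#' @param eeg an [eeg_trace()].
#' @param path output file path.
#' @param seed optional integer recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_eeg_csv <- function(eeg, path, seed = NULL) {
  stopifnot(inherits(eeg, "eeg_trace"))
  utils::write.csv(data.frame(eeg_uv = eeg$values), path,
                   row.names = FALSE, quote = FALSE)
  meta <- list(rate_hz = eeg$rate, filters = eeg$filters)
  if (!is.null(seed)) meta$seed <- seed
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an EEG trace from CSV + JSON sidecar
#'
#' @param path CSV path written by [write_eeg_csv()].
#' @return an [eeg_trace()].
#' @export
read_eeg_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!"eeg_uv" %in% names(df)) stop("EEG CSV must have column eeg_uv")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  eeg_trace(df$eeg_uv, rate = meta$rate_hz,
            filters = as.list(meta$filters))
}

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a single-channel EEG trace as EDF
#'
#' Minimal European Data Format writer: 1 s data records, 16-bit samples,
#' physical range taken from the data.  The trace is zero-padded to a whole
#' number of records.
#'
#' @param eeg an [eeg_trace()]; the sampling rate must be a whole number.
#' @param path output file path.
#' @param label channel label stored in the header.
#' @return `path`, invisibly.
#' @export
write_edf <- function(eeg, path, label = "EEG FpFc") {
  stopifnot(inherits(eeg, "eeg_trace"))
  fs <- eeg$rate
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  x <- eeg$values
  n_rec <- as.integer(ceiling(length(x) / fs))
  x <- c(x, numeric(n_rec * fs - length(x)))
  pmin_ <- min(x) - 1e-9
  pmax_ <- max(x) + 1e-9
  dmin <- -32768L
  dmax <- 32767L
  dig <- as.integer(round((x - pmin_) / (pmax_ - pmin_) *
                            (dmax - dmin) + dmin))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256L * 2L, 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad("1", 8), edf_pad(1L, 4),
    edf_pad(label, 16), edf_pad("AgAgCl electrode", 80), edf_pad("uV", 8),
    edf_pad(sprintf("%.3f", pmin_), 8), edf_pad(sprintf("%.3f", pmax_), 8),
    edf_pad(dmin, 8), edf_pad(dmax, 8),
    edf_pad(sprintf("HP:%gHz N:%gHz",
                    eeg$filters$highpass_hz %||% 0,
                    eeg$filters$notch_hz %||% 0), 80),
    edf_pad(fs, 8), edf_pad("", 32))
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)
  writeBin(dig, con, size = 2L, endian = "little")
  invisible(path)
}

#' Read a single-channel EDF file
#'
#' Recovers the sampling rate from the header (samples per record divided by
#' the record duration) and converts the 16-bit samples back to physical
#' units.
#'
#' @param path EDF file path.
#' @return an [eeg_trace()].
#' @export
read_eeg_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256L, useBytes = TRUE)
  if (nchar(hdr) < 256L) stop("malformed EDF header: file too short")
  field <- function(s, from, len) trimws(substr(s, from, from + len - 1L))
  n_rec <- suppressWarnings(as.integer(field(hdr, 237, 8)))
  rec_dur <- suppressWarnings(as.numeric(field(hdr, 245, 8)))
  ns <- suppressWarnings(as.integer(field(hdr, 253, 4)))
  if (is.na(n_rec) || is.na(rec_dur) || is.na(ns) || rec_dur <= 0)
    stop("malformed EDF header: bad record fields")
  if (ns != 1L) stop("only single-channel EDF files are supported")
  sh <- readChar(con, 256L * ns, useBytes = TRUE)
  pmin_ <- as.numeric(field(sh, 16 + 80 + 8 + 1, 8))
  pmax_ <- as.numeric(field(sh, 16 + 80 + 8 + 8 + 1, 8))
  dmin <- as.numeric(field(sh, 16 + 80 + 8 + 16 + 1, 8))
  dmax <- as.numeric(field(sh, 16 + 80 + 8 + 24 + 1, 8))
  prefilter <- field(sh, 16 + 80 + 8 + 32 + 80 + 1 - 80, 80)
  spr <- as.integer(field(sh, 16 + 80 + 8 + 32 + 80 + 1, 8))
  if (anyNA(c(pmin_, pmax_, dmin, dmax, spr)))
    stop("malformed EDF header: bad signal fields")
  dig <- readBin(con, "integer", n = n_rec * spr, size = 2L,
                 endian = "little")
  x <- (dig - dmin) / (dmax - dmin) * (pmax_ - pmin_) + pmin_
  hp <- sub(".*HP:([0-9.]+)Hz.*", "\\1", prefilter)
  nt <- sub(".*N:([0-9.]+)Hz.*", "\\1", prefilter)
  filters <- list(
    highpass_hz = suppressWarnings(as.numeric(hp)),
    notch_hz = suppressWarnings(as.numeric(nt)))
  eeg_trace(x, rate = spr / rec_dur, filters = filters)
}

#' Write the ground-truth record of a synthetic recording as JSON
#'
#' @param truth the `truth` element of a [simulate_recording()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
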