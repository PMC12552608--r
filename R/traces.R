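#' @keywords internal
"_PACKAGE"

#' Sleep-wake state alphabet
#'
#' Ordered set of state labels used throughout the package: wakefulness,
#' theta-dominated wakefulness (TDW), NREM sleep, REM sleep, the
#' cataplexy-associated state (CAS) and the REM-sleep-like state closing
#' cataplexy bouts, plus an `Artifact` label for epochs excluded from EEG
#' spectral analyses.
#'
#' @export
SLEEP_STATES <- c("Wake", "TDW", "NREM", "REM", "CAS", "REMlike", "Artifact")

#' Uniformly sampled cortical temperature trace
#'
#' @param values numeric vector of temperature samples in degrees Celsius.
#' @param rate sampling rate in Hz (nominally 10 Hz).
#' @param start_time time of the first sample in seconds from recording start.
#' @return An object of class `temperature_trace`.
#' @export
temperature_trace <- function(values, rate = 10, start_time = 0) {
  stopifnot(is.numeric(values), length(rate) == 1L, rate > 0)
  if (any(!is.finite(values)))
    stop("temperature values must be finite")
  structure(list(values = as.numeric(values), rate = rate,
                 start_time = start_time),
            class = "temperature_trace")
}

#' Raw EEG trace
#'
#' @param values numeric vector of EEG samples in microvolts.
#' @param rate sampling rate in Hz; must be at least twice the highest
#'   analyzed frequency (100 Hz), i.e. >= 200 Hz for the full spectral grid.
#' @param filters record of acquisition filters (high-pass and notch, Hz).
#' @return An object of class `eeg_trace`.
#' @export
eeg_trace <- function(values, rate = 200,
                      filters = list(highpass_hz = 0.0625, notch_hz = 50)) {
  stopifnot(is.numeric(values), length(rate) == 1L, rate > 0)
  structure(list(values = as.numeric(values), rate = rate, filters = filters),
            class = "eeg_trace")
}

#' Hypnogram of 4 s epochs
#'
#' @param labels character vector of state labels from [SLEEP_STATES].
#' @param epoch_len epoch length in seconds (fixed at 4 s).
#' @param phase optional per-epoch `"light"`/`"dark"` annotation.  When `NULL`
#'   a 12:12 h schedule starting in the light phase is assumed.
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(labels, epoch_len = 4, phase = NULL) {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("hypnogram needs at least one epoch")
  bad <- setdiff(unique(labels), SLEEP_STATES)
  if (length(bad) > 0L)
    stop("unknown state token(s): ", paste(bad, collapse = ", "))
  if (is.null(phase)) {
    start_s <- (seq_along(labels) - 1L) * epoch_len
    phase <- ifelse(start_s %% 86400 < 43200, "light", "dark")
  }
  stopifnot(length(phase) == length(labels), all(phase %in% c("light", "dark")))
  structure(list(labels = labels, epoch_len = epoch_len, phase = phase),
            class = "hypnogram")
}

#' Time axis of a trace
#'
#' @param x a `temperature_trace`, `eeg_trace` or `hypnogram`.
#' @return numeric vector of sample times (epoch start times for hypnograms)
#'   in seconds.
#' @export
trace_times <- function(x) {
  if (inherits(x, "hypnogram"))
    return((seq_along(x$labels) - 1L) * x$epoch_len)
  x$start_time %||% 0 + (seq_along(x$values) - 1L) / x$rate
}

#' Contiguous state episodes of a hypnogram
#'
#' Run-length encodes the epoch labels into an episode table.
#'
#' @param hyp a [hypnogram()].
#' @return data.frame with columns `state`, `start_epoch`, `end_epoch`
#'   (1-based, inclusive), `start_s`, `end_s`, `duration_s`.
#' @export
hyp_episodes <- function(hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  r <- rle(hyp$labels)
  end_epoch <- cumsum(r$lengths)
  start_epoch <- end_epoch - r$lengths + 1L
  data.frame(state = r$values,
             start_epoch = start_epoch, end_epoch = end_epoch,
             start_s = (start_epoch - 1L) * hyp$epoch_len,
             end_s = end_epoch * hyp$epoch_len,
             duration_s = r$lengths * hyp$epoch_len,
             stringsAsFactors = FALSE)
}

#' Collapse hypnogram labels onto the three physiological states
#'
#' Temperature-only scoring distinguishes only Wake, NREM and REM sleep; for
#' comparisons the richer alphabet is collapsed: TDW and CAS count as
#' wakefulness (both are behaviorally wake states) and the REM-sleep-like
#' state as REM sleep.  `Artifact` epochs are left unchanged.
#'
#' @param hyp a [hypnogram()].
#' @param map named character vector giving the collapse mapping.
#' @return a [hypnogram()] over the collapsed alphabet.
#' @export
collapse_states <- function(hyp, map = c(TDW = "Wake", CAS = "Wake",
                                         REMlike = "REM")) {
  stopifnot(inherits(hyp, "hypnogram"))
  lab <- hyp$labels
  hit <- lab %in% names(map)
  lab[hit] <- unname(map[lab[hit]])
  hypnogram(lab, epoch_len = hyp$epoch_len, phase = hyp$phase)
}

#' Epochwise agreement between two hypnograms
#'
#' @param a,b hypnograms of equal length.
#' @param collapse collapse both onto the Wake/NREM/REM alphabet first.
#' @return fraction of epochs with identical labels.
#' @export
state_agreement <- function(a, b, collapse = TRUE) {
  stopifnot(length(a$labels) == length(b$labels))
  if (collapse) {
    a <- collapse_states(a)
    b <- collapse_states(b)
  }
  mean(a$labels == b$labels)
}

#' @export
print.temperature_trace <- function(x, ...) {
  cat(sprintf("<temperature_trace> %d samples at %g Hz (%.1f s), %.3f-%.3f degC\n",
              length(x$values), x$rate, length(x$values) / x$rate,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.eeg_trace <- function(x, ...) {
  cat(sprintf("<eeg_trace> %d samples at %g Hz (%.1f s)\n",
              length(x$values), x$rate, length(x$values) / x$rate))
  invisible(x)
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$labels, levels = SLEEP_STATES))
  cat(sprintf("<hypnogram> %d x %g s epochs (%.1f min)\n",
              length(x$labels), x$epoch_len,
              length(x$labels) * x$epoch_len / 60))
  print(tab[tab > 0])
  invisible(x)
}

#' NTC thermistor calibration constants
#'
#' The epidural thermistor is driven by a constant measuring current
#' `I_const` (default 100 microampere); the measured voltage V gives the
#' resistance `R_t = V / I_const`, converted to temperature with the NTC beta
#' model.  The manufacturer's constants for the probe used in the study are
#' not public; the defaults here are representative of its 10 kOhm NTC class.
#'
#' @param I_const measuring current in amperes (default 100e-6).
#' @param R_ref reference resistance in ohms at `T_ref`.
#' @param T_ref reference temperature in degrees Celsius.
#' @param beta NTC beta coefficient in kelvin.
#' @return An object of class `thermistor_calibration`.
#' @export
thermistor_calibration <- function(I_const = 100e-6, R_ref = 10e3,
                                   T_ref = 25, beta = 3435) {
  stopifnot(I_const > 0, R_ref > 0, beta > 0, T_ref > -273.15)
  structure(list(I_const = I_const, R_ref = R_ref, T_ref = T_ref, beta = beta),
            class = "thermistor_calibration")
}

#' Convert thermistor voltage to temperature
#'
#' Computes `R_t = V / I_const` and inverts the NTC beta model
#' `1/T = 1/T_ref + (1/beta) log(R_t / R_ref)` (temperatures in kelvin),
#' returning degrees Celsius.
#'
#' @param V measured voltage(s) in volts; must be positive.
#' @param cal a [thermistor_calibration()].
#' @return temperature(s) in degrees Celsius.
#' @export
resistance_to_temperature <- function(V, cal = thermistor_calibration()) {
  stopifnot(inherits(cal, "thermistor_calibration"))
  if (any(V <= 0)) stop("voltage must be positive")
  R_t <- V / cal$I_const
  invT <- 1 / (cal$T_ref + 273.15) + log(R_t / cal$R_ref) / cal$beta
  1 / invT - 273.15
}

#' Convert temperature back to thermistor resistance
#'
#' Algebraic inverse of the beta model used by [resistance_to_temperature()].
#'
#' @param temp_c temperature(s) in degrees Celsius.
#' @param cal a [thermistor_calibration()].
#' @return resistance(s) in ohms.
#' @export
temperature_to_resistance <- function(temp_c, cal = thermistor_calibration()) {
  stopifnot(inherits(cal, "thermistor_calibration"))
  TK <- temp_c + 273.15
  cal$R_ref * exp(cal$beta * (1 / TK - 1 / (cal$T_ref + 273.15)))
}
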