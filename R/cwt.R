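# Continuous wavelet transform and epoch spectra.
#
# The CWT uses an analytic (single-sided) wavelet family with Gaussian
# frequency response and constant relative bandwidth, evaluated by FFT
# filtering.  Rows are normalized so that the band-integrated power of a
# pure tone is independent of its frequency, which is the contract the
# downstream band-power analyses rely on (validated by the two-tone test).

#' Continuous wavelet transform spectrogram
#'
#' Complex analytic wavelet transform of an EEG trace on the standard
#' 0-100 Hz, 0.25 Hz grid, returned as magnitude-squared power.  Power
#' scales with the square of the input amplitude.  With `out_rate` the
#' power is mean-binned in time (e.g. to 10 Hz to match the temperature
#' sampling), which also bounds memory for long recordings.
#'
#' @param eeg an [eeg_trace()]; the sampling rate must be at least twice the
#'   highest requested frequency.
#' @param freqs frequency grid in Hz (default 0-100 Hz, 0.25 Hz step).
#' @param out_rate output sampling rate of the power time axis, Hz;
#'   `NULL` keeps the EEG rate.
#' @param rel_bw relative bandwidth of the wavelet (Gaussian sigma as a
#'   fraction of the center frequency).
#' @return An object of class `cwt_spectrogram`: list with `times`, `freqs`,
#'   `power` (frequency x time matrix, arbitrary microvolt-squared scale)
#'   and `rate`.
#' @export
compute_cwt <- function(eeg, freqs = seq(0, 100, by = 0.25),
                        out_rate = NULL, rel_bw = 0.07) {
  stopifnot(inherits(eeg, "eeg_trace"))
  fs <- eeg$rate
  if (fs < 2 * max(freqs))
    stop(sprintf("sampling rate %g Hz is below Nyquist for %g Hz",
                 fs, max(freqs)))
  x <- eeg$values
  n <- length(x)
  dec <- 1L
  if (!is.null(out_rate)) {
    dec <- as.integer(round(fs / out_rate))
    if (dec < 1L) dec <- 1L
  }
  nt <- n %/% dec
  X <- stats::fft(x)
  fgrid <- (seq_len(n) - 1L) / n * fs
  pos <- fgrid > 0 & fgrid <= fs / 2
  P <- matrix(0, nrow = length(freqs), ncol = nt)
  G <- numeric(n)
  for (i in seq_along(freqs)) {
    f0 <- freqs[i]
    if (f0 <= 0) next
    sig <- rel_bw * f0
    G[] <- 0
    G[pos] <- exp(-(fgrid[pos] - f0)^2 / (2 * sig^2))
    w <- stats::fft(X * G, inverse = TRUE) / n
    p <- (Re(w)^2 + Im(w)^2) / f0
    if (dec > 1L) p <- bin_mean(p, dec)
    P[i, ] <- p
  }
  structure(list(times = (seq_len(nt) - 0.5) * dec / fs,
                 freqs = freqs, power = P, rate = fs / dec),
            class = "cwt_spectrogram")
}

#' @export
print.cwt_spectrogram <- function(x, ...) {
  cat(sprintf("<cwt_spectrogram> %d freqs (%g-%g Hz) x %d samples at %g Hz\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              ncol(x$power), x$rate))
  invisible(x)
}

#' Band-integrated power series
#'
#' Integrates spectrogram power over a frequency band, mean-bins the result
#' to the target rate (10 Hz, matching the temperature recordings) and
#' smooths it with a centered moving window (truncated at the edges).
#'
#' @param spect a `cwt_spectrogram`.
#' @param band numeric length-2 frequency band in Hz (inclusive grid rows).
#' @param rate_out output rate, Hz.
#' @param smooth_s moving-window width in seconds (0 disables smoothing).
#' @return An object of class `band_power`: list with `times`, `values`,
#'   `band`, `rate`.
#' @export
band_power_series <- function(spect, band, rate_out = 10, smooth_s = 20) {
  stopifnot(inherits(spect, "cwt_spectrogram"), length(band) == 2L)
  rows <- which(spect$freqs >= band[1] & spect$freqs <= band[2])
  if (length(rows) == 0L)
    stop(sprintf("band %g-%g Hz contains no grid frequencies",
                 band[1], band[2]))
  df <- if (length(spect$freqs) > 1L) diff(spect$freqs[1:2]) else 1
  p <- colSums(spect$power[rows, , drop = FALSE]) * df
  dec <- as.integer(round(spect$rate / rate_out))
  if (dec > 1L) p <- bin_mean(p, dec)
  rate <- spect$rate / max(dec, 1L)
  if (smooth_s > 0) p <- moving_average(p, smooth_s, rate = rate)
  structure(list(times = (seq_along(p) - 0.5) / rate, values = p,
                 band = band, rate = rate),
            class = "band_power")
}

#' Per-epoch discrete Fourier power spectra
#'
#' Power spectrum of every 4 s epoch at 0.25 Hz resolution (the DFT bin
#' spacing of a 4 s window) from 0 to 100 Hz, with a Hamming taper and the
#' 49-51 Hz notch region masked as `NA`.
#'
#' @param eeg an [eeg_trace()] with rate >= 200 Hz.
#' @param epoch_len epoch length in seconds.
#' @param notch frequency interval in Hz to mask (`NULL` disables).
#' @param f_max highest frequency retained, Hz.
#' @return matrix (epochs x frequencies) with a `freqs` attribute.
#' @export
epoch_spectra <- function(eeg, epoch_len = 4, notch = c(49, 51),
                          f_max = 100) {
  stopifnot(inherits(eeg, "eeg_trace"))
  fs <- eeg$rate
  if (fs < 2 * f_max)
    stop("sampling rate below Nyquist for requested spectrum")
  spe <- as.integer(round(epoch_len * fs))
  n_ep <- length(eeg$values) %/% spe
  if (n_ep == 0L) stop("trace shorter than one epoch")
  df <- 1 / epoch_len
  freqs <- seq(0, f_max, by = df)
  k <- seq_along(freqs)            # DFT bins 0 .. f_max
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(spe) - 1L) / (spe - 1L))
  u <- sum(w^2)
  M <- matrix(eeg$values[seq_len(n_ep * spe)], nrow = spe)
  M <- M * w
  S <- stats::mvfft(M)
  P <- t(Mod(S[k, , drop = FALSE])^2) * (2 / (u * fs))
  P[, 1] <- P[, 1] / 2             # DC is not doubled
  if (!is.null(notch)) P[, freqs >= notch[1] & freqs <= notch[2]] <- NA
  attr(P, "freqs") <- freqs
  P
}
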