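# Theta-dominated wakefulness (TDW) detection from CWT relative theta power
# with a REM-calibrated threshold.

#' Parameters of the TDW detector
#'
#' @param peak_search frequency interval searched for the highest spectral
#'   peak, Hz.
#' @param theta_window interval within which that peak counts as a theta
#'   peak, Hz.
#' @param theta_halfwidth half width of the dynamic theta band around the
#'   observed peak, Hz.
#' @param denom_band band over which total power is integrated for the
#'   relative theta ratio, Hz.
#' @param percentile level on the inverse cumulative distribution (1-CDF) of
#'   REM relative theta power at which the threshold is read off; 0.95
#'   retains 95% of REM time points above threshold (i.e. the 5th percentile
#'   of the REM distribution).
#' @param epoch_frac fraction of high-theta time points above which a 4 s
#'   wake epoch is provisionally labeled TDW.
#' @return An object of class `tdw_params`.
#' @export
tdw_params <- function(peak_search = c(3.5, 15), theta_window = c(6.5, 12),
                       theta_halfwidth = 1, denom_band = c(3.5, 45),
                       percentile = 0.95, epoch_frac = 0.25) {
  stopifnot(percentile > 0, percentile < 1,
            peak_search[1] < peak_search[2],
            theta_window[1] >= peak_search[1],
            theta_window[2] <= peak_search[2],
            denom_band[1] < denom_band[2])
  structure(list(peak_search = peak_search, theta_window = theta_window,
                 theta_halfwidth = theta_halfwidth, denom_band = denom_band,
                 percentile = percentile, epoch_frac = epoch_frac),
            class = "tdw_params")
}

#' Relative theta power series from a CWT spectrogram
#'
#' For every time sample the highest spectral peak between 3.5 and 15 Hz is
#' located (ties broken toward the lower frequency).  If the peak lies in
#' the 6.5-12 Hz theta window, relative theta power is the ratio of the
#' power integrated over the observed peak +/- 1 Hz to the total power
#' between 3.5 and 45 Hz; otherwise it is undefined (`NA`).
#'
#' @param spect a `cwt_spectrogram` covering at least the denominator band.
#' @param params a [tdw_params()].
#' @return An object of class `theta_power`: list with `times`,
#'   `theta_peak_hz`, `rel_theta` and `rate`.
#' @export
relative_theta_power <- function(spect, params = tdw_params()) {
  stopifnot(inherits(spect, "cwt_spectrogram"))
  fr <- spect$freqs
  search <- which(fr >= params$peak_search[1] & fr <= params$peak_search[2])
  denom_rows <- which(fr >= params$denom_band[1] & fr <= params$denom_band[2])
  if (length(search) < 3L || length(denom_rows) == 0L)
    stop("spectrogram grid does not cover the search/denominator bands")
  P <- spect$power
  df <- diff(fr[1:2])
  nt <- ncol(P)
  S <- P[search, , drop = FALSE]
  ns <- nrow(S)
  # local maxima within the search band (edges count, ties -> lower freq)
  up <- rbind(TRUE, S[-1L, , drop = FALSE] > S[-ns, , drop = FALSE])
  dn <- rbind(S[-ns, , drop = FALSE] >= S[-1L, , drop = FALSE], TRUE)
  is_peak <- up & dn
  Sm <- S
  Sm[!is_peak] <- -Inf
  pk_row <- max.col(t(Sm), ties.method = "first")
  peak_hz <- fr[search][pk_row]
  denom <- colSums(P[denom_rows, , drop = FALSE]) * df
  in_theta <- peak_hz >= params$theta_window[1] &
    peak_hz <= params$theta_window[2] & denom > 0
  rel <- rep(NA_real_, nt)
  hw <- params$theta_halfwidth
  if (any(in_theta)) {
    cum <- apply(P, 2L, cumsum) * df
    lo_row <- findInterval(peak_hz - hw, fr + 1e-9) # last row < lo
    hi_row <- findInterval(peak_hz + hw + 1e-9, fr)
    hi_row <- pmin(hi_row, length(fr))
    num <- numeric(nt)
    ii <- which(in_theta)
    num[ii] <- cum[cbind(hi_row[ii], ii)] -
      ifelse(lo_row[ii] >= 1L, cum[cbind(pmax(lo_row[ii], 1L), ii)], 0)
    rel[ii] <- pmin(num[ii] / denom[ii], 1)
  }
  peak_hz[!in_theta & is.na(peak_hz)] <- NA_real_
  structure(list(times = spect$times, theta_peak_hz = peak_hz,
                 rel_theta = rel, rate = spect$rate),
            class = "theta_power")
}

#' High-theta threshold calibrated on REM sleep
#'
#' The threshold is the relative theta power at which the empirical inverse
#' cumulative distribution (1-CDF) of REM-sleep relative theta power equals
#' `params$percentile` - i.e. the (1 - percentile) quantile of the REM
#' distribution - computed separately for the light and dark phases.
#'
#' @param series a `theta_power` series covering the hypnogram span.
#' @param hypnogram the reference [hypnogram()].
#' @param phase `"light"` or `"dark"`.
#' @param params a [tdw_params()].
#' @return the threshold (dimensionless relative theta power).
#' @export
theta_threshold_from_rem <- function(series, hypnogram, phase = "light",
                                     params = tdw_params()) {
  stopifnot(inherits(series, "theta_power"), inherits(hypnogram, "hypnogram"),
            phase %in% c("light", "dark"))
  ep_idx <- epoch_index(series$times, hypnogram)
  ok <- !is.na(ep_idx)
  rem <- ok & hypnogram$labels[ep_idx] == "REM" &
    hypnogram$phase[ep_idx] == phase
  v <- series$rel_theta[rem]
  v <- v[!is.na(v)]
  if (length(v) == 0L)
    stop(sprintf(
      "no REM relative theta power in the %s phase; pool phases or supply a threshold",
      phase))
  unname(stats::quantile(v, probs = 1 - params$percentile))
}

# map sample times onto hypnogram epoch indices (NA outside the span)
epoch_index <- function(times, hypnogram) {
  idx <- floor(times / hypnogram$epoch_len) + 1L
  idx[idx < 1L | idx > length(hypnogram$labels)] <- NA_integer_
  idx
}

#' Label theta-dominated wakefulness epochs
#'
#' Wake epochs containing more than `epoch_frac` (default 25%) of high-theta
#' time points (defined relative theta power above the threshold) are
#' provisionally labeled TDW, then filtered once, in order: (1) the
#' preceding epoch must be Wake or TDW; (2) the following epoch must not be
#' NREM sleep; (3) isolated TDW epochs (neither neighbor TDW) are removed.
#' Epochs failing a filter revert to Wake; all non-wake states are preserved
#' verbatim.
#'
#' @param series a `theta_power` series covering the hypnogram span.
#' @param threshold high-theta threshold (from [theta_threshold_from_rem()]),
#'   either a single value or a named list/vector with `light` and `dark`
#'   entries applied per epoch phase.
#' @param hypnogram the reference [hypnogram()].
#' @param params a [tdw_params()].
#' @return a [hypnogram()] with TDW labels inserted.
#' @export
label_tdw <- function(series, threshold, hypnogram, params = tdw_params()) {
  stopifnot(inherits(series, "theta_power"), inherits(hypnogram, "hypnogram"))
  ep_idx <- epoch_index(series$times, hypnogram)
  n_ep <- length(hypnogram$labels)
  thr <- if (length(threshold) > 1L)
    unlist(threshold)[hypnogram$phase] else rep(threshold, n_ep)
  high <- !is.na(series$rel_theta) &
    series$rel_theta > thr[pmax(ep_idx, 1L)]
  frac <- tapply(high, factor(ep_idx, levels = seq_len(n_ep)), mean)
  frac[is.na(frac)] <- 0
  provisional <- hypnogram$labels == "Wake" & frac > params$epoch_frac
  lab <- hypnogram$labels
  lab[provisional] <- "TDW"
  lab <- apply_tdw_filters(lab)
  hypnogram(lab, epoch_len = hypnogram$epoch_len, phase = hypnogram$phase)
}

# The three exclusion filters, each applied once over the whole sequence in
# the order (1) -> (2) -> (3); filter n sees the output of filter n-1.
apply_tdw_filters <- function(lab) {
  n <- length(lab)
  prev <- c(NA_character_, lab[-n])
  f1 <- lab == "TDW" & !(prev %in% c("Wake", "TDW"))
  lab[f1] <- "Wake"
  nxt <- c(lab[-1L], NA_character_)
  f2 <- lab == "TDW" & !is.na(nxt) & nxt == "NREM"
  lab[f2] <- "Wake"
  prev <- c(NA_character_, lab[-n])
  nxt <- c(lab[-1L], NA_character_)
  f3 <- lab == "TDW" &
    !(!is.na(prev) & prev == "TDW") & !(!is.na(nxt) & nxt == "TDW")
  lab[f3] <- "Wake"
  lab
}
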