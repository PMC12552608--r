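# Infraslow rhythm detection, detrending, band-power cross-correlation and
# the thermal-diffusion worked example.

#' Detrend a series
#'
#' Subtracts the least-squares fit of the named model: a second-order
#' polynomial (used for NREM/wake temperature), the mean (used for EEG
#' sigma power), or a sigmoid (a 4-parameter logistic plus a linear drift
#' term, used for REM temperature whose within-episode course is a fast
#' sigmoidal rise on a slow drift).  A failed sigmoid fit falls back to the
#' polynomial with a warning.
#'
#' @param x numeric series.
#' @param method one of `"polynomial2"`, `"mean"`, `"sigmoid"`.
#' @param rate sampling rate, Hz (used to build the time axis).
#' @return the residual series.
#' @export
detrend_series <- function(x, method = c("polynomial2", "mean", "sigmoid"),
                           rate = 10) {
  method <- match.arg(method)
  n <- length(x)
  if (method == "mean") return(x - mean(x))
  if (n < 10L) stop("need at least 10 samples for model detrending")
  tt <- (seq_len(n) - 1L) / rate
  if (method == "polynomial2") {
    fit <- stats::lm.fit(cbind(1, tt, tt^2), x)
    return(fit$residuals)
  }
  # sigmoid with drift
  rng <- max(x) - min(x)
  t_end <- tt[n]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ L + b * t + A / (1 + exp(-k * (t - t0))),
      data = data.frame(t = tt, y = x),
      start = list(L = min(x), b = 0, A = rng, k = 10 / t_end,
                   t0 = t_end / 3),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("sigmoid detrend failed; falling back to polynomial2")
    return(detrend_series(x, "polynomial2", rate))
  }
  as.numeric(stats::resid(fit))
}

# Horne & Baliunas (1986) estimate of the number of independent frequencies
# scanned by an oversampled periodogram, used for the analytic false-alarm
# level.
horne_baliunas <- function(n) {
  max(2, round(-6.362 + 1.193 * n + 0.00098 * n^2))
}

#' Lomb-Scargle periodogram with analytic false-alarm level
#'
#' Classic variance-normalized Scargle periodogram on a frequency grid
#' oversampled by `oversample`, from periods of half the series duration
#' down to the Nyquist period.  The significance cutoff is the power level
#' at false-alarm probability `fap` (default p = 0.05) using the
#' Horne-Baliunas estimate of independent frequencies; significant peaks
#' are local maxima above the cutoff.
#'
#' @param x numeric series (uniformly sampled).
#' @param rate sampling rate, Hz.
#' @param oversample frequency oversampling factor.
#' @param fap false-alarm probability of the significance cutoff.
#' @param period_range optional period interval of interest, seconds; the
#'   series must be longer than twice the longest period.
#' @return An object of class `ls_periodogram`: `periods` (s), `power`,
#'   `significance_level`, `significant_periods` (peak periods ordered by
#'   decreasing power), `peak_period`, `n`.
#' @export
lomb_scargle <- function(x, rate = 1, oversample = 4, fap = 0.05,
                         period_range = NULL) {
  n <- length(x)
  if (n < 8L) stop("series too short for a periodogram")
  T_tot <- n / rate
  if (!is.null(period_range) && T_tot <= 2 * max(period_range))
    stop(sprintf(
      "series of %.1f s is too short: need more than %.1f s (twice the longest period of interest)",
      T_tot, 2 * max(period_range)))
  tt <- (seq_len(n) - 1L) / rate
  y <- x - mean(x)
  vr <- stats::var(y)
  f_lo <- 2 / T_tot
  f_hi <- rate / 2
  if (!is.null(period_range)) {
    f_lo <- max(f_lo, 1 / max(period_range))
    f_hi <- min(f_hi, 1 / min(period_range))
  }
  df <- 1 / (T_tot * oversample)
  freqs <- seq(f_lo, f_hi, by = df)
  power <- numeric(length(freqs))
  if (vr > 0) {
    for (i in seq_along(freqs)) {
      w <- 2 * pi * freqs[i]
      s2 <- sum(sin(2 * w * tt))
      c2 <- sum(cos(2 * w * tt))
      tau <- atan2(s2, c2) / (2 * w)
      arg <- w * (tt - tau)
      ca <- cos(arg)
      sa <- sin(arg)
      power[i] <- ((sum(y * ca)^2 / sum(ca^2)) +
                     (sum(y * sa)^2 / sum(sa^2))) / (2 * vr)
    }
  }
  M <- horne_baliunas(n)
  level <- -log(1 - (1 - fap)^(1 / M))
  np <- length(power)
  is_pk <- power > level
  if (np > 2L) {
    loc <- c(power[1] > power[2],
             power[-c(1, np)] > power[-c(np - 1, np)] &
               power[-c(1, np)] >= power[-c(1, 2)],
             power[np] > power[np - 1])
    is_pk <- is_pk & loc
  }
  sig_p <- (1 / freqs)[is_pk]
  sig_pow <- power[is_pk]
  ord <- order(sig_pow, decreasing = TRUE)
  structure(list(periods = 1 / freqs, power = power,
                 significance_level = level,
                 significant_periods = sig_p[ord],
                 peak_period = if (length(sig_p)) sig_p[ord][1] else NA_real_,
                 n = n),
            class = "ls_periodogram")
}

#' @export
print.ls_periodogram <- function(x, ...) {
  cat(sprintf("<ls_periodogram> %d freqs, cutoff %.2f, %d significant peak(s)",
              length(x$power), x$significance_level,
              length(x$significant_periods)))
  if (!is.na(x$peak_period)) cat(sprintf(", top period %.1f s", x$peak_period))
  cat("\n")
  invisible(x)
}

#' Infraslow periodicity of NREM episodes
#'
#' For every NREM episode longer than `min_episode` (200 s, long enough to
#' resolve a ~50 s rhythm) the band power series (mean-subtracted, binned to
#' `ls_rate`) and the temperature (second-order-polynomial detrended) are
#' subjected to the Lomb-Scargle periodogram; episodes with a significant
#' peak contribute their top period.
#'
#' @param recording a `synthetic_recording`, or a list with elements `eeg`,
#'   `temperature`, `hypnogram`.
#' @param band sigma band, Hz.
#' @param min_episode minimum episode duration, seconds (strictly longer).
#' @param state state whose episodes are analyzed.
#' @param period_range period interval of interest, seconds.
#' @param ls_rate sampling rate of the band-power series handed to the
#'   periodogram, Hz (1 Hz bins keep neighbouring samples approximately
#'   independent, which the analytic false-alarm level assumes).
#' @param spect optional precomputed `cwt_spectrogram` of the whole EEG.
#' @return list with `episodes` (data.frame: start_s, duration_s,
#'   power_period_s, power_significant, temp_period_s, temp_significant)
#'   and `summary` (mean/sd of significant periods and significant fraction,
#'   separately for band power and temperature).
#' @export
infraslow_period_histogram <- function(recording, band = c(11, 15),
                                       min_episode = 200, state = "NREM",
                                       period_range = c(20, 120),
                                       ls_rate = 1, spect = NULL) {
  hyp <- recording$hypnogram
  eps <- hyp_episodes(hyp)
  eps <- eps[eps$state == state & eps$duration_s > min_episode, ,
             drop = FALSE]
  cols <- c("start_s", "duration_s", "power_period_s", "power_significant",
            "temp_period_s", "temp_significant")
  if (nrow(eps) == 0L) {
    empty <- as.data.frame(stats::setNames(rep(list(numeric(0)), 6), cols))
    return(list(episodes = empty,
                summary = list(power = list(mean = NA_real_, sd = NA_real_,
                                            frac_significant = NA_real_),
                               temp = list(mean = NA_real_, sd = NA_real_,
                                           frac_significant = NA_real_))))
  }
  fs_e <- recording$eeg$rate
  rate_t <- recording$temperature$rate
  rows <- vector("list", nrow(eps))
  for (i in seq_len(nrow(eps))) {
    i0 <- as.integer(eps$start_s[i] * fs_e) + 1L
    i1 <- as.integer(eps$end_s[i] * fs_e)
    seg <- eeg_trace(recording$eeg$values[i0:i1], rate = fs_e)
    sp <- compute_cwt(seg, freqs = seq(band[1], band[2], by = 0.25),
                      out_rate = 10)
    bp <- band_power_series(sp, band, rate_out = ls_rate, smooth_s = 0)
    pw <- detrend_series(bp$values, "mean")
    ls_p <- lomb_scargle(pw, rate = ls_rate, period_range = period_range)
    j0 <- as.integer(eps$start_s[i] * rate_t) + 1L
    j1 <- as.integer(eps$end_s[i] * rate_t)
    tp <- detrend_series(recording$temperature$values[j0:j1], "polynomial2",
                         rate = rate_t)
    ls_t <- lomb_scargle(tp, rate = rate_t, period_range = period_range)
    rows[[i]] <- data.frame(
      start_s = eps$start_s[i], duration_s = eps$duration_s[i],
      power_period_s = ls_p$peak_period,
      power_significant = length(ls_p$significant_periods) > 0,
      temp_period_s = ls_t$peak_period,
      temp_significant = length(ls_t$significant_periods) > 0)
  }
  tab <- do.call(rbind, rows)
  summ <- function(per, sig) list(
    mean = if (any(sig)) mean(per[sig]) else NA_real_,
    sd = if (sum(sig) > 1) stats::sd(per[sig]) else NA_real_,
    frac_significant = mean(sig))
  list(episodes = tab,
       summary = list(
         power = summ(tab$power_period_s, tab$power_significant),
         temp = summ(tab$temp_period_s, tab$temp_significant)))
}

#' Cross-correlation between temperature residuals and EEG band power
#'
#' Pearson-normalized cross-correlation (means subtracted, fixed
#' denominator: the product of the full-series standard deviations) over
#' lags up to +/- `max_lag` seconds.  A positive `peak_lag` means the
#' temperature follows the power envelope; the delay summary is the lag of
#' the maximum correlation restricted to positive lags.  Peaks larger than
#' `2/sqrt(N)` (N the number of samples) are significant.
#'
#' @param temp_resid numeric detrended temperature residuals.
#' @param power_series numeric band power series at the same rate (a
#'   `band_power` object is also accepted), detrended/smoothed upstream.
#' @param rate common sampling rate, Hz.
#' @param max_lag maximum lag, seconds (shrunk with a warning when the
#'   series is shorter than twice this).
#' @return An object of class `crosscorr`: `lags` (s), `r`, `n`,
#'   `sig_threshold`, `peak_lag`, `peak_r`.
#' @export
cross_correlate <- function(temp_resid, power_series, rate = 10,
                            max_lag = 100) {
  if (inherits(power_series, "band_power")) power_series <- power_series$values
  x <- as.numeric(temp_resid)
  y <- as.numeric(power_series)
  stopifnot(length(x) == length(y))
  n <- length(x)
  lag_n <- as.integer(round(max_lag * rate))
  if (n < 2L * lag_n) {
    lag_n <- n %/% 2L
    warning(sprintf("series too short for %g s lags; using %g s",
                    max_lag, lag_n / rate))
  }
  cc <- stats::ccf(x, y, lag.max = lag_n, plot = FALSE, demean = TRUE)
  r <- as.numeric(cc$acf)           # r[k] = cor(x_{t+k}, y_t)
  lags <- as.numeric(cc$lag) / rate * 1  # ccf lag unit = sample here
  lags <- seq(-lag_n, lag_n) / rate
  pos <- lags > 0
  pk <- which.max(r[pos])
  structure(list(lags = lags, r = r, n = n,
                 sig_threshold = 2 / sqrt(n),
                 peak_lag = lags[pos][pk], peak_r = r[pos][pk]),
            class = "crosscorr")
}

#' @export
print.crosscorr <- function(x, ...) {
  cat(sprintf("<crosscorr> N = %d, peak r = %.3f at %+.1f s (threshold %.4f)\n",
              x$n, x$peak_r, x$peak_lag, x$sig_threshold))
  invisible(x)
}

#' Average cross-correlations over episodes and subjects
#'
#' Correlation curves are averaged first within each subject, then across
#' subjects; the significance threshold uses the smallest episode length.
#'
#' @param cc_list list of `crosscorr` objects on a common lag grid.
#' @param subject optional vector assigning each element to a subject.
#' @return a `crosscorr` with the grand-mean correlation.
#' @export
average_crosscorr <- function(cc_list, subject = NULL) {
  stopifnot(length(cc_list) > 0L)
  if (is.null(subject)) subject <- rep(1L, length(cc_list))
  lags <- cc_list[[1]]$lags
  for (cc in cc_list) stopifnot(length(cc$lags) == length(lags))
  by_subj <- lapply(split(cc_list, subject), function(l)
    Reduce(`+`, lapply(l, `[[`, "r")) / length(l))
  r <- Reduce(`+`, by_subj) / length(by_subj)
  n_min <- min(vapply(cc_list, `[[`, numeric(1), "n"))
  pos <- lags > 0
  pk <- which.max(r[pos])
  structure(list(lags = lags, r = r, n = n_min,
                 sig_threshold = 2 / sqrt(n_min),
                 peak_lag = lags[pos][pk], peak_r = r[pos][pk]),
            class = "crosscorr")
}

#' Frequency-resolved cross-correlation heatmap
#'
#' Applies [cross_correlate()] to every frequency row of a spectrogram
#' (each row handled as a one-grid-step band: binned to 10 Hz, smoothed,
#' mean-subtracted), yielding a frequency x lag correlation matrix with
#' contours at `2/sqrt(N)` and 0.25.
#'
#' @param temp_resid detrended temperature residuals at `rate`.
#' @param spect a `cwt_spectrogram`.
#' @param rate common rate, Hz.
#' @param max_lag maximum lag, seconds.
#' @param smooth_s power smoothing window, seconds.
#' @return An object of class `crosscorr_heatmap`: `freqs`, `lags`, `r`
#'   (freq x lag), `n`, `sig_threshold`, `contours`.
#' @export
crosscorr_spectrum <- function(temp_resid, spect, rate = 10, max_lag = 100,
                               smooth_s = 20) {
  stopifnot(inherits(spect, "cwt_spectrogram"))
  rows <- which(spect$freqs > 0)
  first <- TRUE
  R <- NULL
  lags <- NULL
  n <- length(temp_resid)
  for (i in rows) {
    bp <- band_power_series(spect, rep(spect$freqs[i], 2), rate_out = rate,
                            smooth_s = smooth_s)
    v <- bp$values
    if (length(v) != length(temp_resid))
      v <- v[seq_len(min(length(v), length(temp_resid)))]
    x <- temp_resid[seq_along(v)]
    cc <- suppressWarnings(
      cross_correlate(x, v - mean(v), rate = rate, max_lag = max_lag))
    if (first) {
      R <- matrix(NA_real_, nrow = length(spect$freqs),
                  ncol = length(cc$lags))
      lags <- cc$lags
      first <- FALSE
    }
    R[i, ] <- cc$r
  }
  structure(list(freqs = spect$freqs, lags = lags, r = R, n = n,
                 sig_threshold = 2 / sqrt(n),
                 contours = c(2 / sqrt(n), 0.25)),
            class = "crosscorr_heatmap")
}

#' Average cross-correlation heatmaps over episodes and subjects
#'
#' @param hm_list list of `crosscorr_heatmap` objects on common grids.
#' @param subject optional subject assignment.
#' @return a `crosscorr_heatmap` with the grand-mean correlation matrix.
#' @export
average_heatmaps <- function(hm_list, subject = NULL) {
  stopifnot(length(hm_list) > 0L)
  if (is.null(subject)) subject <- rep(1L, length(hm_list))
  by_subj <- lapply(split(hm_list, subject), function(l)
    Reduce(`+`, lapply(l, `[[`, "r")) / length(l))
  R <- Reduce(`+`, by_subj) / length(by_subj)
  n_min <- min(vapply(hm_list, `[[`, numeric(1), "n"))
  structure(list(freqs = hm_list[[1]]$freqs, lags = hm_list[[1]]$lags,
                 r = R, n = n_min, sig_threshold = 2 / sqrt(n_min),
                 contours = c(2 / sqrt(n_min), 0.25)),
            class = "crosscorr_heatmap")
}

#' Thermal diffusion length
#'
#' Distance heat diffuses in time `t` for thermal diffusivity `D`:
#' `mu(t) = sqrt(4 D t)`.  With the calf-brain diffusivity
#' D = 0.147 mm^2/s, the observed 10-14 s delays correspond to 2.4-2.9 mm.
#'
#' @param D thermal diffusivity, mm^2/s (non-negative).
#' @param t delay, seconds (non-negative).
#' @return diffusion length in mm.
#' @export
diffusion_length <- function(D, t) {
  if (any(D < 0) || any(t < 0)) stop("D and t must be non-negative")
  sqrt(4 * D * t)
}
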