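# Temperature-only prediction of Wake / NREM / REM and hourly comparison
# against a reference hypnogram.

#' Parameters of the temperature-only scoring algorithm
#'
#' Defaults follow the published thresholds: wakefulness ends at the start
#' of a continuous temperature drop longer than 5 s; REM onset is the start
#' of a 2 s sliding window (0.1 s step) whose sigmoid fit reaches R^2 >
#' 0.97; candidate onsets within 3 s are merged keeping the earlier; a REM
#' episode ends at the first continuous drop longer than 0.4 s; 4 s of
#' wakefulness follow every REM end; episodes shorter than 20 s cannot be
#' captured.
#'
#' @param wake_end_drop minimum duration of the wake-ending drop, seconds.
#' @param rem_fit_window sigmoid fitting window, seconds.
#' @param rem_fit_step sliding step, seconds.
#' @param rem_r2_threshold R-squared threshold of the sigmoid fit.
#' @param rem_start_merge merge distance for candidate REM onsets, seconds.
#' @param rem_end_drop minimum duration of the REM-ending drop, seconds.
#' @param post_rem_wake wakefulness appended after each REM end, seconds.
#' @param min_episode minimum episode duration, seconds.
#' @param drop_smoothing moving-average width used to define "continuous"
#'   drops on noisy data, seconds.
#' @param wake_start_tol backward-search tolerance on reaching the wake-end
#'   temperature, degC.
#' @param rem_min_traverse minimum fraction of the fitted sigmoid amplitude
#'   traversed within the window (guards against near-linear segments).
#' @param rem_accel_ratio acceleration guard on REM onsets: the slope over
#'   the first 0.3 s of the window must stay below this fraction of the
#'   steepest 0.3 s slope in the window (a sigmoid onset accelerates; an
#'   ongoing near-linear rise does not).
#' @param rem_sat_horizon,rem_sat_factor saturation guard on REM onsets: a
#'   candidate is rejected when, within `rem_sat_horizon` seconds after the
#'   window, the trace climbs more than `rem_sat_factor` times the fitted
#'   amplitude above the fitted upper plateau (a genuine sigmoid saturates;
#'   an ongoing wake rise keeps climbing).
#' @param rem_plateau_ratio plateau check on REM onsets: the mean slope
#'   between 2 s and `rem_sat_horizon` seconds after the window must stay
#'   below this fraction of the window's steepest slope.
#' @return An object of class `scoring_params`.
#' @export
scoring_params <- function(wake_end_drop = 5, rem_fit_window = 2,
                           rem_fit_step = 0.1, rem_r2_threshold = 0.97,
                           rem_start_merge = 3, rem_end_drop = 0.4,
                           post_rem_wake = 4, min_episode = 20,
                           drop_smoothing = 1, wake_start_tol = 0.02,
                           rem_min_traverse = 0.25, rem_accel_ratio = 0.7,
                           rem_sat_horizon = 10, rem_sat_factor = 0.5,
                           rem_plateau_ratio = 0.25) {
  stopifnot(wake_end_drop > 0, rem_fit_window > 0,
            rem_fit_step > 0, rem_fit_step < rem_fit_window,
            rem_r2_threshold > 0, rem_r2_threshold < 1,
            min_episode > 0, drop_smoothing >= 0)
  structure(as.list(environment()), class = "scoring_params")
}

#' Detect continuous temperature drops
#'
#' Maximal intervals over which the derivative of the (moving-average
#' smoothed) trace stays negative for longer than `min_dur` seconds.
#'
#' @param trace a [temperature_trace()].
#' @param min_dur minimum drop duration, seconds (strictly longer).
#' @param smooth_s smoothing width, seconds.
#' @return data.frame with columns `start_s`, `end_s` (empty when the trace
#'   is shorter than `min_dur`).
#' @export
detect_continuous_drops <- function(trace, min_dur, smooth_s = 1) {
  stopifnot(inherits(trace, "temperature_trace"))
  rate <- trace$rate
  n <- length(trace$values)
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0))
  if (n / rate <= min_dur || n < 2L) return(empty)
  sm <- moving_average(trace$values, smooth_s, rate = rate)
  d <- diff(sm)
  r <- rle(d < 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths / rate > min_dur)
  if (!any(keep)) return(empty)
  t0 <- trace$start_time %||% 0
  data.frame(start_s = t0 + (starts[keep] - 1L) / rate,
             end_s = t0 + ends[keep] / rate)
}

#' Detect wakefulness episodes from the temperature trace
#'
#' Each continuous drop longer than `wake_end_drop` marks the end of a
#' wakefulness episode at the drop start.  The episode start is found by
#' scanning backward for the beginning of the temperature increase that
#' first brought the temperature to the wake-end level (within
#' `wake_start_tol`).  A backward scan that runs into the preceding drop
#' without falling below that level yields no episode (the decline is then
#' part of sleep, not a wake ending), and episodes shorter than
#' `min_episode` are discarded.
#'
#' @param trace a [temperature_trace()].
#' @param params a [scoring_params()].
#' @return data.frame with columns `state` ("Wake"), `start_s`, `end_s`.
#' @export
detect_wake_episodes <- function(trace, params = scoring_params()) {
  stopifnot(inherits(trace, "temperature_trace"))
  rate <- trace$rate
  t0 <- trace$start_time %||% 0
  drops <- detect_continuous_drops(trace, params$wake_end_drop,
                                   params$drop_smoothing)
  out <- data.frame(state = character(0), start_s = numeric(0),
                    end_s = numeric(0))
  if (nrow(drops) == 0L) return(out)
  sm <- moving_average(trace$values, params$drop_smoothing, rate = rate)
  for (i in seq_len(nrow(drops))) {
    end_idx <- as.integer(round((drops$start_s[i] - t0) * rate)) + 1L
    target <- sm[end_idx]
    floor_idx <- if (i > 1L)
      as.integer(round((drops$end_s[i - 1L] - t0) * rate)) + 1L else 1L
    # backward scan for the beginning of the rising run that brought the
    # temperature to the wake-end level: follow the running minimum until
    # the trace climbs back above it (the preceding decline), or until the
    # previous drop is reached
    min_idx <- end_idx
    min_val <- target
    eps <- params$wake_start_tol / 4   # keep the latest point of a flat min
    j <- end_idx - 1L
    while (j >= floor_idx) {
      if (sm[j] < min_val - eps) {
        min_val <- sm[j]
        min_idx <- j
      } else if (sm[j] > min_val + params$wake_start_tol) {
        break
      }
      j <- j - 1L
    }
    # a wake episode needs an actual preceding increase
    if (target - min_val <= params$wake_start_tol) next
    start_idx <- min_idx
    dur <- (end_idx - start_idx) / rate
    if (dur < params$min_episode) next
    out <- rbind(out, data.frame(state = "Wake",
                                 start_s = t0 + (start_idx - 1L) / rate,
                                 end_s = t0 + (end_idx - 1L) / rate))
  }
  out
}

#' Fit a sigmoid to a short temperature window
#'
#' Least-squares fit of the 4-parameter logistic
#' `L + A / (1 + exp(-k (t - t0)))`.  The fit is declared invalid (R^2
#' treated as 0) when the optimizer fails, the amplitude is negative or
#' below the noise floor, the inflection `t0` falls outside the window, or
#' less than `min_traverse` of the amplitude is traversed inside the window
#' (a near-linear segment fits a logistic with an absurdly large amplitude;
#' such fits must not count as REM onsets).
#'
#' @param segment numeric vector of temperature samples.
#' @param rate sampling rate, Hz.
#' @param noise_floor amplitude floor, degC.
#' @param min_traverse minimum traversed amplitude fraction.
#' @return list with `params` (L, A, k, t0), `r2` and `valid`.
#' @export
fit_sigmoid_window <- function(segment, rate = 10, noise_floor = 0,
                               min_traverse = 0.25) {
  n <- length(segment)
  tt <- (seq_len(n) - 1L) / rate
  out <- list(params = c(L = NA, A = NA, k = NA, t0 = NA), r2 = 0,
              valid = FALSE)
  if (n < 5L) return(out)
  ss_tot <- sum((segment - mean(segment))^2)
  rng <- max(segment) - min(segment)
  if (ss_tot <= 0 || rng <= noise_floor) return(out)
  t_end <- tt[n]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ L + A / (1 + exp(-k * (t - t0))),
      data = data.frame(t = tt, y = segment),
      start = list(L = min(segment), A = rng, k = 8 / t_end,
                   t0 = t_end / 2),
      lower = c(L = -Inf, A = 0, k = 1e-3, t0 = -t_end),
      upper = c(L = Inf, A = 20 * rng, k = 200, t0 = 2 * t_end),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(out)
  cf <- stats::coef(fit)
  r2 <- 1 - sum(stats::resid(fit)^2) / ss_tot
  lo <- logistic(cf[["k"]] * (0 - cf[["t0"]]))
  hi <- logistic(cf[["k"]] * (t_end - cf[["t0"]]))
  # the window must straddle the inflection: a convex or concave rise
  # (e.g. an exponential wake onset) pushes t0 to a window edge and covers
  # only one side of the logistic
  valid <- is.finite(r2) &&
    cf[["A"]] > max(noise_floor, 0) &&
    cf[["t0"]] >= 0 && cf[["t0"]] <= t_end &&
    (hi - lo) >= min_traverse &&
    (0.5 - lo) >= 0.05 && (hi - 0.5) >= 0.05
  list(params = cf, r2 = if (valid) r2 else 0, valid = valid)
}

# left-to-right sweep keeping the earliest of each cluster of candidate
# onsets closer than merge_s
merge_candidates <- function(times, merge_s) {
  if (length(times) == 0L) return(times)
  times <- sort(times)
  keep <- times[1]
  last <- times[1]
  for (t in times[-1]) {
    if (t - last >= merge_s) {
      keep <- c(keep, t)
    }
    last <- if (t - last >= merge_s) t else last
  }
  keep
}

#' Detect REM sleep episodes from the temperature trace
#'
#' A 2 s window slides in 0.1 s steps over the recording.  Window starts
#' whose sigmoid fit exceeds the R-squared threshold (and passes the
#' validity guards of [fit_sigmoid_window()]) are candidate REM onsets;
#' candidates within 3 s keep only the earlier one.  Each episode ends at
#' the first continuous drop longer than 0.4 s after its onset, and 4 s of
#' wakefulness are appended after the end.  Episodes shorter than
#' `min_episode` are discarded.  In [score_states()] REM labels take
#' precedence over wake labels (the rise preceding the post-REM temperature
#' decline belongs to REM sleep, not to wakefulness).
#'
#' @param trace a [temperature_trace()].
#' @param params a [scoring_params()].
#' @return data.frame with columns `state` ("REM"), `start_s`, `end_s`.
#' @export
detect_rem_episodes <- function(trace, params = scoring_params()) {
  stopifnot(inherits(trace, "temperature_trace"))
  rate <- trace$rate
  t0 <- trace$start_time %||% 0
  x <- trace$values
  n <- length(x)
  nw <- as.integer(round(params$rem_fit_window * rate))
  step <- max(1L, as.integer(round(params$rem_fit_step * rate)))
  out <- data.frame(state = character(0), start_s = numeric(0),
                    end_s = numeric(0))
  if (n < nw + 1L) return(out)
  noise_est <- stats::mad(diff(x)) / sqrt(2)
  starts <- seq(1L, n - nw, by = step)
  win_t <- t0 + (starts - 1L) / rate
  # cheap screen: enough range and a net rise (final R^2 arbitration below)
  mx <- x[starts]
  mn <- x[starts]
  for (off in seq_len(nw)) {
    xo <- x[starts + off]
    mx <- pmax(mx, xo)
    mn <- pmin(mn, xo)
  }
  rng <- mx - mn
  rise <- x[starts + nw] - x[starts]
  need <- sqrt(noise_est^2 / (1 - params$rem_r2_threshold) * 12)
  keep <- rng >= 0.8 * need & rise > 0.5 * rng & rng > 0
  starts <- starts[keep]
  win_t <- win_t[keep]
  sm <- moving_average(x, params$drop_smoothing, rate = rate)
  hor <- as.integer(round(params$rem_sat_horizon * rate))
  h <- max(2L, as.integer(round(0.3 * rate)))   # 0.3 s slope chunks
  cand <- numeric(0)
  for (j in seq_along(starts)) {
    seg <- x[starts[j]:(starts[j] + nw)]
    # acceleration guard: a sigmoid onset is steepest in the window
    # interior, an ongoing (wake) rise is already steep at the window start
    sl <- (seg[(h + 1L):(nw + 1L)] - seg[seq_len(nw + 1L - h)]) / (h / rate)
    if (max(sl) <= 0 || sl[1] > params$rem_accel_ratio * max(sl)) next
    f <- fit_sigmoid_window(seg, rate = rate,
                            noise_floor = 6 * noise_est,
                            min_traverse = params$rem_min_traverse)
    if (!(f$valid && f$r2 > params$rem_r2_threshold)) next
    # saturation guards: the plateau must hold after the window
    i1 <- starts[j] + nw
    i2 <- min(n, i1 + hor)
    if (i2 > i1) {
      upper <- f$params[["L"]] + f$params[["A"]]
      if (max(sm[(i1 + 1L):i2]) >
          upper + params$rem_sat_factor * f$params[["A"]]) next
    }
    j2 <- min(n, i1 + as.integer(round(2 * rate)))
    if (i2 > j2) {
      post_slope <- (sm[i2] - sm[j2]) / ((i2 - j2) / rate)
      if (post_slope > params$rem_plateau_ratio * max(sl)) next
    }
    cand <- c(cand, win_t[j])
  }
  cand <- merge_candidates(cand, params$rem_start_merge)
  if (length(cand) == 0L) return(out)
  drops <- detect_continuous_drops(trace, params$rem_end_drop,
                                   params$drop_smoothing)
  t_last <- t0 + (n - 1L) / rate
  cur_end <- -Inf
  for (tc in cand) {
    if (tc < cur_end) next
    ends <- drops$start_s[drops$start_s > tc]
    e <- if (length(ends) > 0L) ends[1] else t_last
    cur_end <- e + params$post_rem_wake
    if (e - tc < params$min_episode) next
    out <- rbind(out, data.frame(state = "REM", start_s = tc, end_s = e))
  }
  out
}

#' Score sleep-wake states from temperature alone
#'
#' Wakefulness episodes are detected first, then REM sleep; where they
#' overlap, REM labels take precedence (the sigmoidal rise that ends in the
#' post-REM decline belongs to REM sleep).  Everything not labeled
#' wakefulness or REM sleep is NREM sleep.  Sample-level labels are binned into 4 s epochs by majority vote
#' (ties broken REM > Wake > NREM, the rarer state winning).
#'
#' @param trace a [temperature_trace()].
#' @param params a [scoring_params()].
#' @return a [hypnogram()] over Wake / NREM / REM covering the full trace.
#' @export
score_states <- function(trace, params = scoring_params()) {
  stopifnot(inherits(trace, "temperature_trace"))
  rate <- trace$rate
  t0 <- trace$start_time %||% 0
  n <- length(trace$values)
  wake <- detect_wake_episodes(trace, params)
  rem <- detect_rem_episodes(trace, params)
  lab <- rep("NREM", n)
  mark <- function(lab, from_s, to_s, value) {
    i0 <- max(1L, as.integer(round((from_s - t0) * rate)) + 1L)
    i1 <- min(n, as.integer(round((to_s - t0) * rate)) + 1L)
    if (i1 >= i0) lab[i0:i1] <- value
    lab
  }
  for (i in seq_len(nrow(wake)))
    lab <- mark(lab, wake$start_s[i], wake$end_s[i], "Wake")
  for (i in seq_len(nrow(rem))) {
    lab <- mark(lab, rem$start_s[i], rem$end_s[i], "REM")
    lab <- mark(lab, rem$end_s[i], rem$end_s[i] + params$post_rem_wake,
                "Wake")
  }
  spe <- as.integer(round(4 * rate))
  n_ep <- n %/% spe
  ep_lab <- character(n_ep)
  prio <- c("REM", "Wake", "NREM")
  for (e in seq_len(n_ep)) {
    counts <- table(lab[((e - 1L) * spe + 1L):(e * spe)])
    best <- names(counts)[counts == max(counts)]
    ep_lab[e] <- prio[prio %in% best][1]
  }
  hypnogram(ep_lab, epoch_len = 4)
}

#' Hourly time-in-state comparison of two hypnograms
#'
#' Minutes per state per 1 h interval for both sources, with a two-sided
#' rank-sum (Mann-Whitney) test on the per-epoch state indicators within
#' each hour; hours in which any state differs at p < 0.05 are flagged.  A
#' trailing partial hour is dropped with a warning.
#'
#' @param predicted,reference hypnograms over the same span (the reference
#'   is collapsed onto Wake/NREM/REM first).
#' @param alpha flagging level.
#' @return An object of class `hourly_comparison`: list with `table`
#'   (hour, state, predicted_min, reference_min, p), `flagged_hours`,
#'   `flagged_fraction`.
#' @export
compare_hourly <- function(predicted, reference, alpha = 0.05) {
  stopifnot(inherits(predicted, "hypnogram"),
            inherits(reference, "hypnogram"),
            length(predicted$labels) == length(reference$labels))
  predicted <- collapse_states(predicted)
  reference <- collapse_states(reference)
  eph <- as.integer(3600 / predicted$epoch_len)
  n_h <- length(predicted$labels) %/% eph
  if (n_h == 0L) stop("span is shorter than one hour")
  if (length(predicted$labels) %% eph != 0L)
    warning("trailing partial hour dropped")
  states <- c("Wake", "NREM", "REM")
  rows <- list()
  flagged <- logical(n_h)
  for (h in seq_len(n_h)) {
    idx <- ((h - 1L) * eph + 1L):(h * eph)
    for (s in states) {
      pi_ <- as.integer(predicted$labels[idx] == s)
      ri <- as.integer(reference$labels[idx] == s)
      p <- if (all(pi_ == pi_[1]) && all(ri == ri[1]) && pi_[1] == ri[1])
        1 else suppressWarnings(
          stats::wilcox.test(pi_, ri, exact = FALSE)$p.value)
      if (is.na(p)) p <- 1
      rows[[length(rows) + 1L]] <- data.frame(
        hour = h, state = s,
        predicted_min = sum(pi_) * predicted$epoch_len / 60,
        reference_min = sum(ri) * reference$epoch_len / 60,
        p = p)
      if (p < alpha) flagged[h] <- TRUE
    }
  }
  structure(list(table = do.call(rbind, rows),
                 flagged_hours = which(flagged),
                 flagged_fraction = mean(flagged)),
            class = "hourly_comparison")
}

#' @export
print.hourly_comparison <- function(x, ...) {
  cat(sprintf("<hourly_comparison> %d hours, %.1f%% flagged\n",
              max(x$table$hour), 100 * x$flagged_fraction))
  invisible(x)
}
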