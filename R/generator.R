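# Synthetic recordings: coupled hypnogram + EEG + cortical temperature with
# ground-truth parameters for end-to-end recovery testing.

default_state_graph <- function(cataplexy = TRUE) {
  s <- c("Wake", "TDW", "NREM", "REM", "CAS", "REMlike")
  g <- matrix(0, 6, 6, dimnames = list(s, s))
  g["Wake", c("NREM", "TDW", "CAS")] <- c(0.72, 0.22, 0.06)
  g["TDW", c("Wake", "CAS")] <- c(0.88, 0.12)
  g["NREM", c("Wake", "REM")] <- c(0.6, 0.4)
  g["REM", "Wake"] <- 1
  g["CAS", c("Wake", "REMlike")] <- c(0.5, 0.5)
  g["REMlike", "Wake"] <- 1
  if (!cataplexy) {
    g[, "CAS"] <- 0
    g["CAS", ] <- 0
    g["REMlike", ] <- 0
  }
  g
}

default_dwell_params <- function() {
  list(Wake = list(mean = 120, sdlog = 0.5, min_epochs = 1L),
       TDW = list(mean = 36, sdlog = 0.4, min_epochs = 1L),
       NREM = list(mean = 160, sdlog = 0.5, min_epochs = 1L),
       REM = list(mean = 70, sdlog = 0.4, min_epochs = 1L),
       CAS = list(mean = 42, sdlog = 0.3, min_epochs = 1L),
       REMlike = list(mean = 40, sdlog = 0.3, min_epochs = 1L))
}

default_temp_dynamics <- function() {
  list(Wake = list(shape = "biexp", base = 35.9, slow_amp = 0.35,
                   tau_fast = 10, tau_slow = 60),
       TDW = list(shape = "biexp", base = 36.0, slow_amp = 0.3,
                  tau_fast = 10, tau_slow = 60),
       NREM = list(shape = "linear", asym = 35.4, tau = 60),
       REM = list(shape = "sigmoid", amp = 0.45, k = 0.9,
                  t0 = 6, ramp = 0.007),
       CAS = list(shape = "linear", asym = 35.5, tau = 30),
       REMlike = list(shape = "sigmoid", amp = 0.3, k = 0.7,
                      t0 = 6, ramp = 0.003))
}

default_band_defs <- function() {
  list(
    Wake = list(theta_freq = 8.0, theta_amp = 5, gamma_amp = 8,
                broadband_amp = 25),
    TDW = list(theta_freq = 8.1, theta_amp = 30, gamma_amp = 20,
               broadband_amp = 10),
    NREM = list(delta_amp = 40, sigma_amp = 35, sigma_rate = 0.6),
    REM = list(theta_freq = 8.0, theta_amp = 30, gamma_amp = 20,
               broadband_amp = 4),
    CAS = list(theta_freq = 7.0, theta_amp = 60, theta_jitter = 0.8,
               delta_amp = 30, broadband_amp = 10),
    REMlike = list(theta_freq = 8.0, theta_amp = 28, gamma_amp = 18,
                   broadband_amp = 4))
}

#' Configuration of the synthetic-recording generator
#'
#' The defaults encode the signal structure the analyses assume: 4 s scoring
#' epochs; temperature sampled at 10 Hz and EEG at 200 Hz; state-dependent
#' temperature relaxation (near-linear decay into NREM sleep and into
#' wakefulness after REM sleep, near-linear rise into wakefulness, a fast
#' sigmoidal rise plus slow drift into REM sleep, decay into CAS and a
#' smaller sigmoidal rise into the REM-sleep-like state); NREM sigma/spindle
#' wave packets whose density is modulated with a ~50 s infraslow period;
#' theta plus 55-85 Hz gamma with correlated slow envelopes in REM sleep and
#' TDW; large irregular ~7 Hz theta mixed with 3-4 Hz delta in CAS; and a
#' temperature response that follows the oscillation-power envelope with a
#' configurable 10-14 s lag.  Cataplexy chains (Wake/TDW -> CAS -> Wake or
#' REM-sleep-like -> Wake) occur only in the dark phase.
#'
#' @param epoch_len scoring epoch length, seconds (fixed at 4).
#' @param temp_rate temperature sampling rate, Hz.
#' @param eeg_rate EEG sampling rate, Hz (200 Hz gives the full 0-100 Hz
#'   spectral grid).
#' @param dwell_params per-state episode-duration distribution (truncated
#'   log-normal: `mean` seconds, `sdlog`, `min_epochs`).
#' @param state_graph transition probability matrix over the six states;
#'   rows are renormalized to 1.
#' @param temp_dynamics per-state entry dynamics: `shape` "linear" relaxes
#'   exponentially toward `asym` degC with time constant `tau` seconds
#'   (near-linear over the first tens of seconds); `shape` "sigmoid" (REM
#'   and REM-sleep-like entries) adds a fast logistic rise of amplitude
#'   `amp` degC (rate `k` 1/s, midpoint `t0` s) plus a slow linear drift
#'   `ramp` degC/s that sustains the within-episode rise.
#' @param start_temp temperature at recording start, degC.
#' @param infraslow_period period of the NREM sigma-burst density
#'   modulation, seconds.
#' @param infraslow_mod modulation depth in 0..1 (0 disables the infraslow
#'   rhythm).
#' @param coupling_lag delay of the temperature response behind the EEG
#'   power envelope, seconds.
#' @param coupling_kernel_width full width of the Gaussian coupling kernel,
#'   seconds.
#' @param coupling_gain temperature response amplitude, degC per SD of the
#'   oscillation-power drive (0 disables coupling).
#' @param band_defs per-state oscillation amplitudes (microvolt) and
#'   frequencies (Hz).
#' @param temp_noise_sd temperature measurement noise SD, degC.
#' @param eeg_noise_sd 1/f EEG background SD, microvolt.
#' @param cataplexy allow the cataplexy chain in the state graph.
#' @param initial_state state at recording start.
#' @param start_zt_s zeitgeber time of the recording start in seconds after
#'   light onset under the 12:12 h light-dark schedule (0 starts at light
#'   onset, 43200 at dark onset).
#' @param seed integer RNG seed used by [simulate_recording()].
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(epoch_len = 4, temp_rate = 10, eeg_rate = 200,
                             dwell_params = default_dwell_params(),
                             state_graph = NULL,
                             temp_dynamics = default_temp_dynamics(),
                             start_temp = 35.8,
                             infraslow_period = 50, infraslow_mod = 0.9,
                             coupling_lag = 12, coupling_kernel_width = 4,
                             coupling_gain = 0.004,
                             band_defs = default_band_defs(),
                             temp_noise_sd = 0.0015, eeg_noise_sd = 15,
                             cataplexy = TRUE, initial_state = "Wake",
                             start_zt_s = 0, seed = 1L) {
  if (is.null(state_graph)) state_graph <- default_state_graph(cataplexy)
  stopifnot(temp_rate > 0, eeg_rate > 0, epoch_len > 0,
            coupling_lag >= 0, infraslow_period > 0,
            initial_state %in% rownames(state_graph))
  rs <- rowSums(state_graph)
  state_graph[rs > 0, ] <- state_graph[rs > 0, , drop = FALSE] / rs[rs > 0]
  structure(list(epoch_len = epoch_len, temp_rate = temp_rate,
                 eeg_rate = eeg_rate, dwell_params = dwell_params,
                 state_graph = state_graph, temp_dynamics = temp_dynamics,
                 start_temp = start_temp,
                 infraslow_period = infraslow_period,
                 infraslow_mod = infraslow_mod,
                 coupling_lag = coupling_lag,
                 coupling_kernel_width = coupling_kernel_width,
                 coupling_gain = coupling_gain, band_defs = band_defs,
                 temp_noise_sd = temp_noise_sd, eeg_noise_sd = eeg_noise_sd,
                 cataplexy = cataplexy, initial_state = initial_state,
                 start_zt_s = start_zt_s, seed = as.integer(seed)),
            class = "generator_config")
}

# transition row for the current state, with cataplexy entries masked in the
# light phase.
next_state_probs <- function(config, state, phase) {
  p <- config$state_graph[state, ]
  if (phase == "light") p["CAS"] <- 0
  if (sum(p) == 0)
    stop(sprintf("state '%s' has no allowed transitions (%s phase): %s",
                 state, phase, "configuration error"))
  p / sum(p)
}

draw_dwell_epochs <- function(config, state) {
  dp <- config$dwell_params[[state]]
  if (is.null(dp)) stop("no dwell parameters for state ", state)
  meanlog <- log(dp$mean) - dp$sdlog^2 / 2
  dur <- stats::rlnorm(1, meanlog, dp$sdlog)
  max(dp$min_epochs %||% 1L, as.integer(round(dur / config$epoch_len)))
}

#' Generate a semi-Markov hypnogram
#'
#' Episode durations are drawn from per-state truncated log-normal
#' distributions (minimum one epoch) and successive states from the
#' transition graph.  Cataplexy (CAS) can only be entered during the dark
#' phase; the chain Wake/TDW -> CAS -> Wake or REM-sleep-like -> Wake is
#' enforced by the default graph.
#'
#' @param config a [generator_config()].
#' @param duration recording duration, seconds (>= one epoch).
#' @param seed RNG seed; `NULL` uses the current RNG state (as done inside
#'   [simulate_recording()]).
#' @return a [hypnogram()].
#' @export
generate_hypnogram <- function(config, duration, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"),
            duration >= config$epoch_len)
  if (!is.null(seed)) set.seed(seed)
  # reachability check over the dark-phase graph (the least restricted one)
  g <- config$state_graph
  reach <- config$initial_state
  repeat {
    nxt <- unique(c(reach, colnames(g)[colSums(g[reach, , drop = FALSE]) > 0]))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  wanted <- rownames(g)[rowSums(g) > 0 | rownames(g) %in% reach]
  unreachable <- setdiff(wanted, reach)
  if (length(unreachable) > 0L)
    stop("unreachable requested state(s): ",
         paste(unreachable, collapse = ", "))
  n_total <- as.integer(floor(duration / config$epoch_len))
  zt <- function(t) {
    ifelse((t + config$start_zt_s) %% 86400 < 43200, "light", "dark")
  }
  labels <- character(0)
  phases <- character(0)
  state <- config$initial_state
  while (length(labels) < n_total) {
    t_now <- length(labels) * config$epoch_len
    if (state == "CAS" && zt(t_now) == "light") state <- "Wake"
    n_ep <- min(draw_dwell_epochs(config, state),
                n_total - length(labels))
    labels <- c(labels, rep(state, n_ep))
    ep_start <- (seq_len(n_ep) - 1L) * config$epoch_len + t_now
    phases <- c(phases, zt(ep_start))
    t_next <- length(labels) * config$epoch_len
    p <- next_state_probs(config, state, zt(t_next))
    state <- sample(names(p), 1L, prob = p)
  }
  hypnogram(labels, epoch_len = config$epoch_len, phase = phases)
}

# -- EEG synthesis -----------------------------------------------------------

# A theta-type oscillation: sinusoid with slowly fluctuating amplitude and
# optional frequency jitter.  `slow` supplies a shared standardized slow
# fluctuation so that theta and gamma envelopes co-vary within a state run.
osc_rhythm <- function(n, rate, freq, amp, slow = NULL, jitter_hz = 0,
                       env_cv = 0.6) {
  if (n == 0L || amp <= 0) return(list(signal = numeric(n), env = numeric(n)))
  if (is.null(slow)) slow <- slow_noise(n, rate, cutoff_hz = 0.02)
  env <- amp * pmax(0.05, 1 + env_cv * slow)
  f_inst <- rep(freq, n)
  if (jitter_hz > 0)
    f_inst <- f_inst + jitter_hz * slow_noise(n, rate, cutoff_hz = 0.5)
  phase <- cumsum(2 * pi * f_inst / rate) + stats::runif(1, 0, 2 * pi)
  list(signal = env * sin(phase), env = env)
}

# Gamma band (55-85 Hz) narrowband noise with a slow envelope correlated
# with the supplied shared fluctuation.
osc_gamma <- function(n, rate, amp, slow = NULL, env_cv = 0.6) {
  if (n == 0L || amp <= 0) return(list(signal = numeric(n), env = numeric(n)))
  if (is.null(slow)) slow <- slow_noise(n, rate, cutoff_hz = 0.02)
  env <- amp * pmax(0.05, 1 + env_cv * slow)
  carrier <- band_noise(n, rate, 55, 85)
  list(signal = env * carrier, env = env)
}

# Sigma/spindle wave packets: 11-15 Hz bursts of 0.5-2 s whose occurrence
# density is modulated at the infraslow period.
osc_sigma_packets <- function(n, rate, amp, rate_hz, period, mod) {
  out <- list(signal = numeric(n), env = numeric(n))
  if (n == 0L || amp <= 0 || rate_hz <= 0) return(out)
  dur_s <- n / rate
  phi <- stats::runif(1, 0, 2 * pi)
  lambda_max <- rate_hz * (1 + mod)
  n_cand <- stats::rpois(1, lambda_max * dur_s)
  if (n_cand == 0L) return(out)
  t_cand <- stats::runif(n_cand, 0, dur_s)
  keep <- stats::runif(n_cand) <
    (1 + mod * sin(2 * pi * t_cand / period + phi)) / (1 + mod)
  t_pk <- t_cand[keep]
  for (tp in t_pk) {
    w <- stats::runif(1, 0.5, 2)
    f <- stats::runif(1, 11, 15)
    a <- amp * stats::rlnorm(1, 0, 0.3)
    i0 <- max(1L, as.integer(round(tp * rate)))
    i1 <- min(n, i0 + as.integer(round(w * rate)) - 1L)
    if (i1 <= i0) next
    m <- i1 - i0 + 1L
    hann <- 0.5 * (1 - cos(2 * pi * seq_len(m) / (m + 1)))
    tt <- (seq_len(m) - 1L) / rate
    out$signal[i0:i1] <- out$signal[i0:i1] +
      a * hann * sin(2 * pi * f * tt + stats::runif(1, 0, 2 * pi))
    out$env[i0:i1] <- out$env[i0:i1] + a * hann
  }
  out
}

#' Synthesize EEG from a hypnogram
#'
#' State-gated oscillations on a 1/f background: NREM sleep carries 1-4 Hz
#' delta plus sigma (11-15 Hz) wave packets whose density is modulated at
#' the infraslow period; REM sleep and TDW carry theta (8 / 8.1 Hz) and
#' gamma (55-85 Hz) with correlated slow envelopes; CAS carries
#' large-amplitude irregular ~7 Hz theta mixed with 3-4 Hz delta.  The
#' ground-truth per-band amplitude envelopes are returned at the temperature
#' sampling rate.
#'
#' @param hypnogram a [hypnogram()].
#' @param config a [generator_config()].
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return list with elements `eeg` (an [eeg_trace()]) and `envelopes`
#'   (data.frame `time_s`, `delta`, `theta`, `sigma`, `gamma` at
#'   `config$temp_rate`).
#' @export
synthesize_eeg <- function(hypnogram, config, seed = NULL) {
  stopifnot(inherits(hypnogram, "hypnogram"),
            inherits(config, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  fs <- config$eeg_rate
  spe <- as.integer(round(config$epoch_len * fs))
  n <- length(hypnogram$labels) * spe
  x <- colored_noise(n, fs, sd = config$eeg_noise_sd, exponent = 1)
  env <- list(delta = numeric(n), theta = numeric(n), sigma = numeric(n),
              gamma = numeric(n))
  eps <- hyp_episodes(hypnogram)
  for (i in seq_len(nrow(eps))) {
    st <- eps$state[i]
    idx <- ((eps$start_epoch[i] - 1L) * spe + 1L):(eps$end_epoch[i] * spe)
    m <- length(idx)
    bd <- config$band_defs[[st]]
    if (is.null(bd)) next
    shared <- slow_noise(m, fs, cutoff_hz = 0.02)
    if (!is.null(bd$broadband_amp) && bd$broadband_amp > 0) {
      # desynchronized broadband activity typical of active waking
      x[idx] <- x[idx] + band_noise(m, fs, 3.5, 45, sd = bd$broadband_amp)
    }
    if (!is.null(bd$delta_amp) && bd$delta_amp > 0) {
      f_lo <- if (st == "CAS") 3 else 1
      f_hi <- 4
      d <- band_noise(m, fs, f_lo, f_hi, sd = bd$delta_amp)
      x[idx] <- x[idx] + d
      env$delta[idx] <- env$delta[idx] + bd$delta_amp
    }
    if (!is.null(bd$theta_amp) && bd$theta_amp > 0) {
      th <- osc_rhythm(m, fs, bd$theta_freq, bd$theta_amp, slow = shared,
                       jitter_hz = bd$theta_jitter %||% 0)
      x[idx] <- x[idx] + th$signal
      env$theta[idx] <- env$theta[idx] + th$env
    }
    if (!is.null(bd$gamma_amp) && bd$gamma_amp > 0) {
      gm <- osc_gamma(m, fs, bd$gamma_amp, slow = shared)
      x[idx] <- x[idx] + gm$signal
      env$gamma[idx] <- env$gamma[idx] + gm$env
    }
    if (!is.null(bd$sigma_amp) && bd$sigma_amp > 0) {
      sg <- osc_sigma_packets(m, fs, bd$sigma_amp,
                              rate_hz = bd$sigma_rate %||% 0.6,
                              period = config$infraslow_period,
                              mod = config$infraslow_mod)
      x[idx] <- x[idx] + sg$signal
      env$sigma[idx] <- env$sigma[idx] + sg$env
    }
  }
  dec <- as.integer(round(fs / config$temp_rate))
  env10 <- lapply(env, bin_mean, factor = dec)
  n10 <- length(env10$delta)
  envelopes <- data.frame(time_s = (seq_len(n10) - 1L) / config$temp_rate,
                          delta = env10$delta, theta = env10$theta,
                          sigma = env10$sigma, gamma = env10$gamma)
  list(eeg = eeg_trace(x, rate = fs,
                       filters = list(highpass_hz = NA_real_,
                                      notch_hz = NA_real_)),
       envelopes = envelopes)
}

# Standardized oscillation-power drive for the temperature coupling: summed
# squared envelopes of the heat-associated bands (theta, sigma, gamma),
# lightly smoothed and z-scored over the recording.
coupling_drive <- function(envelopes, config) {
  p <- envelopes$theta^2 + envelopes$sigma^2 + envelopes$gamma^2
  p <- moving_average(p, 2, rate = config$temp_rate)
  s <- stats::sd(p)
  if (s == 0) return(numeric(length(p)))
  (p - mean(p)) / s
}

coupling_kernel <- function(config) {
  sigma <- config$coupling_kernel_width / (2 * sqrt(2 * log(2)))
  t_max <- config$coupling_lag + 4 * sigma
  tt <- seq(0, t_max, by = 1 / config$temp_rate)
  k <- exp(-(tt - config$coupling_lag)^2 / (2 * sigma^2))
  k / sum(k)
}

#' Synthesize the cortical temperature trace
#'
#' Piecewise state-driven baseline: exponential relaxation toward a state
#' asymptote (near-linear over the first tens of seconds) for wakefulness,
#' TDW, NREM sleep and CAS; a fast logistic rise plus slow linear drift for
#' REM sleep and the REM-sleep-like state.  On top of the baseline the
#' oscillation-power drive, delayed by the coupling lag through a causal
#' Gaussian kernel, and Gaussian measurement noise are added.
#'
#' @param hypnogram a [hypnogram()].
#' @param envelopes band-envelope data.frame as returned by
#'   [synthesize_eeg()] (columns `theta`, `sigma`, `gamma` at the
#'   temperature rate), or `NULL` for no coupling.
#' @param config a [generator_config()].
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return a [temperature_trace()].
#' @export
synthesize_temperature <- function(hypnogram, envelopes = NULL, config,
                                   seed = NULL) {
  stopifnot(inherits(hypnogram, "hypnogram"),
            inherits(config, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  rate <- config$temp_rate
  spe <- as.integer(round(config$epoch_len * rate))
  n <- length(hypnogram$labels) * spe
  eps <- hyp_episodes(hypnogram)
  temp <- numeric(n)
  T_cur <- config$start_temp
  for (i in seq_len(nrow(eps))) {
    dyn <- config$temp_dynamics[[eps$state[i]]]
    if (is.null(dyn)) stop("no temperature dynamics for ", eps$state[i])
    idx <- ((eps$start_epoch[i] - 1L) * spe + 1L):(eps$end_epoch[i] * spe)
    tt <- (seq_along(idx) - 1L) / rate
    if (identical(dyn$shape, "sigmoid")) {
      s0 <- logistic(-dyn$k * dyn$t0)
      lgs <- (logistic(dyn$k * (tt - dyn$t0)) - s0) / (1 - s0)
      seg <- T_cur + dyn$amp * lgs + dyn$ramp * tt
    } else if (identical(dyn$shape, "biexp")) {
      # fast thermal equilibration toward `base` plus a slow activity-driven
      # rise of `slow_amp`; entering from above (after REM) this gives the
      # characteristic decrease-then-increase course
      seg <- dyn$base + (T_cur - dyn$base) * exp(-tt / dyn$tau_fast) +
        dyn$slow_amp * (1 - exp(-tt / dyn$tau_slow))
    } else {
      seg <- dyn$asym + (T_cur - dyn$asym) * exp(-tt / dyn$tau)
    }
    temp[idx] <- seg
    T_cur <- seg[length(seg)]
  }
  if (!is.null(envelopes) && config$coupling_gain != 0) {
    drive <- coupling_drive(envelopes, config)
    if (length(drive) < n) drive <- c(drive, rep(0, n - length(drive)))
    resp <- causal_filter(drive[seq_len(n)], coupling_kernel(config))
    temp <- temp + config$coupling_gain * resp
  }
  if (config$temp_noise_sd > 0)
    temp <- temp + stats::rnorm(n, 0, config$temp_noise_sd)
  temperature_trace(temp, rate = rate)
}

#' Simulate a complete synthetic recording
#'
#' Generates a hypnogram, the matching EEG with ground-truth band envelopes,
#' and the coupled temperature trace, all from a single seed.  Identical
#' config and seed give bit-identical recordings.
#'
#' @param config a [generator_config()].
#' @param duration recording duration, seconds.
#' @return An object of class `synthetic_recording`: list with
#'   `temperature`, `eeg`, `hypnogram`, and `truth` (episode table, band
#'   envelopes, coupling drive, injected `coupling_lag` and
#'   `infraslow_period`, seed).
#' @export
simulate_recording <- function(config, duration) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  hyp <- generate_hypnogram(config, duration, seed = NULL)
  ee <- synthesize_eeg(hyp, config, seed = NULL)
  temp <- synthesize_temperature(hyp, ee$envelopes, config, seed = NULL)
  truth <- list(episodes = hyp_episodes(hyp),
                envelopes = ee$envelopes,
                drive = coupling_drive(ee$envelopes, config),
                coupling_lag = config$coupling_lag,
                infraslow_period = config$infraslow_period,
                seed = config$seed)
  structure(list(temperature = temp, eeg = ee$eeg, hypnogram = hyp,
                 truth = truth),
            class = "synthetic_recording")
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf("<synthetic_recording> %.1f min, lag %g s, infraslow %g s\n",
              length(x$hypnogram$labels) * x$hypnogram$epoch_len / 60,
              x$truth$coupling_lag, x$truth$infraslow_period))
  print(x$hypnogram)
  invisible(x)
}
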