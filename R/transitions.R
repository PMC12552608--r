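# Transition-aligned averaging of relative temperature and of epoch spectra
# around state switches, including the cataplexy chain.

#' Select qualifying state transitions
#'
#' Epoch boundaries where the label switches `from_state -> to_state` with
#' at least `pre_epochs` uniform epochs before and `post_epochs` uniform
#' epochs after the switch (defaults: 3 epochs / 12 s before and 8 epochs /
#' 32 s after).
#'
#' @param hypnogram a [hypnogram()].
#' @param from_state,to_state state labels (distinct).
#' @param pre_epochs,post_epochs minimum uniform epochs around the switch.
#' @return numeric vector of transition times (seconds at the epoch
#'   boundary); empty when no transition qualifies.
#' @export
select_transitions <- function(hypnogram, from_state, to_state,
                               pre_epochs = 3, post_epochs = 8) {
  stopifnot(inherits(hypnogram, "hypnogram"),
            from_state != to_state, pre_epochs >= 1, post_epochs >= 1)
  eps <- hyp_episodes(hypnogram)
  if (nrow(eps) < 2L) return(numeric(0))
  i <- seq_len(nrow(eps) - 1L)
  hit <- eps$state[i] == from_state & eps$state[i + 1L] == to_state &
    (eps$end_epoch[i] - eps$start_epoch[i] + 1L) >= pre_epochs &
    (eps$end_epoch[i + 1L] - eps$start_epoch[i + 1L] + 1L) >= post_epochs
  eps$end_s[i][hit]
}

#' Transition-aligned relative temperature (Delta T)
#'
#' For every event the temperature at the transition point (linearly
#' interpolated to the epoch boundary) is subtracted, producing relative
#' changes Delta T that pass through 0 at lag 0.  Each trace is clipped to
#' its flanking episodes (only the last episode before and the first after
#' the switch contribute; samples beyond them are `NA`).  Traces are
#' averaged within the recording; [average_ensembles()] averages across
#' subjects.
#'
#' @param trace a [temperature_trace()].
#' @param hypnogram the matching [hypnogram()] (defines episode bounds).
#' @param events transition times from [select_transitions()].
#' @param pre_s,post_s window around the switch, seconds.
#' @return An object of class `transition_ensemble`: `lag_s`, `traces`
#'   (events x lag matrix), `mean`, `sem`, `n_events`.  Events too close to
#'   the trace edge are dropped with a warning.
#' @export
aligned_delta_t <- function(trace, hypnogram, events, pre_s = 12,
                            post_s = 32) {
  stopifnot(inherits(trace, "temperature_trace"),
            inherits(hypnogram, "hypnogram"))
  rate <- trace$rate
  t0 <- trace$start_time %||% 0
  n <- length(trace$values)
  lag_s <- seq(-pre_s, post_s, by = 1 / rate)
  tt <- trace_times(trace)
  eps <- hyp_episodes(hypnogram)
  rows <- list()
  dropped <- 0L
  for (ev in events) {
    if (ev - pre_s < t0 - 1e-9 ||
        ev + post_s > t0 + (n - 1L) / rate + 1e-9) {
      dropped <- dropped + 1L
      next
    }
    at <- ev + lag_s
    v <- stats::approx(tt, trace$values, xout = at)$y
    v0 <- stats::approx(tt, trace$values, xout = ev)$y
    dT <- v - v0
    pre_ep <- eps[eps$end_s == ev, , drop = FALSE]
    post_ep <- eps[eps$start_s == ev, , drop = FALSE]
    if (nrow(pre_ep) == 1L) dT[at < pre_ep$start_s[1] - 1e-9] <- NA
    if (nrow(post_ep) == 1L) dT[at > post_ep$end_s[1] + 1e-9] <- NA
    rows[[length(rows) + 1L]] <- dT
  }
  if (dropped > 0L)
    warning(sprintf("%d event(s) too close to the trace edge dropped",
                    dropped))
  if (length(rows) == 0L)
    return(structure(list(lag_s = lag_s,
                          traces = matrix(numeric(0), 0, length(lag_s)),
                          mean = rep(NA_real_, length(lag_s)),
                          sem = rep(NA_real_, length(lag_s)), n_events = 0L),
                     class = "transition_ensemble"))
  M <- do.call(rbind, rows)
  mu <- colMeans(M, na.rm = TRUE)
  nn <- colSums(!is.na(M))
  sem <- apply(M, 2L, stats::sd, na.rm = TRUE) / sqrt(pmax(nn, 1L))
  structure(list(lag_s = lag_s, traces = M, mean = mu, sem = sem,
                 n_events = nrow(M)),
            class = "transition_ensemble")
}

#' Average transition ensembles across subjects
#'
#' Grand mean of per-subject mean Delta T traces (first within, then among
#' individuals), with SEM across subjects.
#'
#' @param ens_list list of `transition_ensemble` objects on a common lag
#'   grid (one per subject).
#' @return a `transition_ensemble` whose `traces` are the subject means.
#' @export
average_ensembles <- function(ens_list) {
  ens_list <- ens_list[vapply(ens_list, function(e) e$n_events > 0L,
                              logical(1))]
  stopifnot(length(ens_list) > 0L)
  lag_s <- ens_list[[1]]$lag_s
  M <- do.call(rbind, lapply(ens_list, `[[`, "mean"))
  mu <- colMeans(M, na.rm = TRUE)
  nn <- colSums(!is.na(M))
  sem <- apply(M, 2L, stats::sd, na.rm = TRUE) / sqrt(pmax(nn, 1L))
  structure(list(lag_s = lag_s, traces = M, mean = mu, sem = sem,
                 n_events = nrow(M)),
            class = "transition_ensemble")
}

#' Pre/post transition epoch spectra
#'
#' Discrete-Fourier power spectra (0-100 Hz, 0.25 Hz resolution, 49-51 Hz
#' masked) of the 4 s epochs around each event: means over `n_avg` epochs
#' before and after the switch, their post/pre ratio, and a heatmap variant
#' in which each epoch's spectrum is normalized per frequency by the mean
#' over `n_norm` pre-transition epochs.  Events whose window contains an
#' Artifact-labeled epoch are dropped from the spectral averages.
#'
#' @param eeg an [eeg_trace()].
#' @param hypnogram the matching [hypnogram()].
#' @param events transition times (seconds at epoch boundaries).
#' @param n_avg epochs averaged on each side for the pre/post spectra.
#' @param n_norm pre-transition epochs for the heatmap normalization.
#' @param post_epochs epochs after the switch shown in the heatmap.
#' @return An object of class `transition_spectra`: `freqs`, `pre`, `post`
#'   (mean spectra), `ratio`, `heatmap` (epoch x freq, normalized),
#'   `heatmap_epochs` (epoch offsets), `n_events`.
#' @export
transition_spectra <- function(eeg, hypnogram, events, n_avg = 3,
                               n_norm = 10, post_epochs = 8) {
  stopifnot(inherits(eeg, "eeg_trace"), inherits(hypnogram, "hypnogram"))
  sp <- epoch_spectra(eeg, epoch_len = hypnogram$epoch_len)
  freqs <- attr(sp, "freqs")
  n_ep <- nrow(sp)
  pre_list <- list()
  post_list <- list()
  hm_list <- list()
  hm_off <- seq(-n_norm, post_epochs - 1L)
  kept <- 0L
  for (ev in events) {
    b <- as.integer(round(ev / hypnogram$epoch_len))  # epochs before switch
    pre_idx <- (b - n_avg + 1L):b
    post_idx <- (b + 1L):(b + n_avg)
    norm_idx <- (b - n_norm + 1L):b
    hm_idx <- b + hm_off + 1L
    need <- unique(c(pre_idx, post_idx, norm_idx, hm_idx))
    if (min(need) < 1L || max(need) > n_ep) next
    if (any(hypnogram$labels[need] == "Artifact")) next
    kept <- kept + 1L
    pre_list[[kept]] <- colMeans(sp[pre_idx, , drop = FALSE])
    post_list[[kept]] <- colMeans(sp[post_idx, , drop = FALSE])
    base <- colMeans(sp[norm_idx, , drop = FALSE])
    hm_list[[kept]] <- sweep(sp[hm_idx, , drop = FALSE], 2L, base, `/`)
  }
  if (kept == 0L)
    return(structure(list(freqs = freqs, pre = NULL, post = NULL,
                          ratio = NULL, heatmap = NULL,
                          heatmap_epochs = hm_off, n_events = 0L),
                     class = "transition_spectra"))
  pre <- Reduce(`+`, pre_list) / kept
  post <- Reduce(`+`, post_list) / kept
  ratios <- mapply(function(a, b) b / a, pre_list, post_list,
                   SIMPLIFY = FALSE)
  ratio <- Reduce(`+`, ratios) / kept
  heat <- Reduce(`+`, hm_list) / kept
  structure(list(freqs = freqs, pre = pre, post = post, ratio = ratio,
                 heatmap = heat, heatmap_epochs = hm_off, n_events = kept),
            class = "transition_spectra")
}
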