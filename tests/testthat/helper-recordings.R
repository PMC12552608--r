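# Shared fixture builders.  Everything is generated in code; expensive
# recordings are cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# config whose semi-Markov graph holds a single self-looping state
single_state_config <- function(state, seed = 1, ...) {
  s <- c("Wake", "TDW", "NREM", "REM", "CAS", "REMlike")
  g <- matrix(0, 6, 6, dimnames = list(s, s))
  g[state, state] <- 1
  generator_config(state_graph = g, initial_state = state, seed = seed, ...)
}

# default config restricted to episodes of at least `min_epochs` epochs
long_episode_config <- function(seed = 1, min_epochs = 6L, ...) {
  dw <- thermosleep:::default_dwell_params()
  for (s in names(dw)) dw[[s]]$min_epochs <- min_epochs
  generator_config(dwell_params = dw, seed = seed, ...)
}

# piecewise-linear temperature trace from (duration, slope) segments
piecewise_trace <- function(segments, rate = 10, start = 35.8) {
  v <- start
  for (i in seq_len(nrow(segments))) {
    n <- as.integer(round(segments$dur[i] * rate))
    v <- c(v, v[length(v)] + segments$slope[i] * seq_len(n) / rate)
  }
  temperature_trace(v, rate = rate)
}

# exhaustive-scan oracle for qualifying state transitions over epoch labels
select_oracle <- function(lab, from, to, pre, post) {
  out <- numeric(0)
  n <- length(lab)
  for (i in seq_len(n - 1)) {
    if (lab[i] != from || lab[i + 1] != to) next
    if (i < pre || i + post > n) next
    if (any(lab[(i - pre + 1):i] != from)) next
    if (any(lab[(i + 1):(i + post)] != to)) next
    out <- c(out, i * 4)
  }
  out
}

# a 30 min light-phase recording with TDW, reused by the TDW tests
tdw_recording <- function() {
  cached("tdw_rec", {
    cfg <- generator_config(cataplexy = FALSE, seed = 21)
    simulate_recording(cfg, 1800)
  })
}

# a 2 h dark-phase recording with cataplexy, reused by transition tests
dark_recording <- function() {
  cached("dark_rec", {
    cfg <- generator_config(start_zt_s = 43200, seed = 33)
    simulate_recording(cfg, 7200)
  })
}
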