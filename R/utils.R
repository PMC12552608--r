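# Internal numeric helpers shared across modules.

# Centered moving average with truncated windows at the edges.
# width is in seconds when rate is given, otherwise in samples.
moving_average <- function(x, width, rate = 1) {
  k <- max(1L, as.integer(round(width * rate)))
  n <- length(x)
  if (k <= 1L || n == 0L) return(x)
  h1 <- (k - 1L) %/% 2L
  h2 <- k - 1L - h1
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h1, 1L)
  hi <- pmin(seq_len(n) + h2, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

logistic <- function(x) 1 / (1 + exp(-x))

# 4-parameter logistic curve L + A / (1 + exp(-k (t - t0)))
logistic_curve <- function(t, L, A, k, t0) L + A * logistic(k * (t - t0))

# Gaussian white noise shaped in the frequency domain.  exponent = 0 gives
# white noise, exponent = 1 the 1/f ("pink") background typical of EEG.
colored_noise <- function(n, rate, sd = 1, exponent = 0) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(numeric(n))
  w <- stats::rnorm(n)
  if (exponent == 0) return(w * sd)
  X <- stats::fft(w)
  f <- seq(0, rate, length.out = n + 1L)[seq_len(n)]
  f[f > rate / 2] <- rate - f[f > rate / 2]
  g <- ifelse(f > 0, f^(-exponent / 2), 0)
  x <- Re(stats::fft(X * g, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x / s * sd
}

# Band-limited Gaussian noise (flat passband between f_lo and f_hi Hz).
band_noise <- function(n, rate, f_lo, f_hi, sd = 1) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(numeric(n))
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- seq(0, rate, length.out = n + 1L)[seq_len(n)]
  f[f > rate / 2] <- rate - f[f > rate / 2]
  keep <- f >= f_lo & f <= f_hi
  x <- Re(stats::fft(X * keep, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x / s * sd
}

# Slowly varying standardized noise: Gaussian low-pass with the given cutoff
# (Hz) applied in the frequency domain.  Used for envelope fluctuations.
slow_noise <- function(n, rate, cutoff_hz, sd = 1) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(numeric(n))
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- seq(0, rate, length.out = n + 1L)[seq_len(n)]
  f[f > rate / 2] <- rate - f[f > rate / 2]
  g <- exp(-(f / cutoff_hz)^2 / 2)
  x <- Re(stats::fft(X * g, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x / s * sd
}

# Mean-bin a vector by an integer factor, truncating any remainder.
bin_mean <- function(x, factor) {
  factor <- as.integer(factor)
  if (factor <= 1L) return(x)
  nb <- length(x) %/% factor
  if (nb == 0L) return(numeric(0))
  colMeans(matrix(x[seq_len(nb * factor)], nrow = factor))
}

# Causal FIR filtering: y[i] = sum_j k[j] x[i - j + 1].  The series is
# extended before its start by repeating the first sample so that the filter
# warms up without an artificial zero step.
causal_filter <- function(x, kernel) {
  n <- length(x)
  K <- length(kernel)
  if (n == 0L) return(x)
  y <- numeric(n)
  idx <- seq_len(n)
  for (j in seq_len(K)) {
    src <- pmax(idx - j + 1L, 1L)
    y <- y + kernel[j] * x[src]
  }
  y
}

`%||%` <- function(a, b) if (is.null(a)) b else a
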