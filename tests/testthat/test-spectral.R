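test_that("detrending subtracts the named model", {
  tt <- (0:999) / 10
  quad <- 2 + 0.3 * tt - 0.01 * tt^2
  r <- detrend_series(quad, "polynomial2")
  expect_lt(max(abs(r)), 1e-8)
  expect_lt(abs(mean(r)), 1e-9 * (stats::sd(quad) + 1))

  lgs <- thermosleep:::logistic_curve(tt, 35.5, 0.5, 0.25, 40) + 0.003 * tt
  r2 <- detrend_series(lgs, "sigmoid", rate = 10)
  expect_lt(max(abs(r2)), 1e-6)

  x <- rnorm(50) + 5
  expect_equal(mean(detrend_series(x, "mean")), 0)

  # additive construction: quadratic + 50 s sine leaves the sine (many
  # cycles, so the sine is near-orthogonal to the quadratic)
  tl <- (0:71999) / 10
  quadl <- 2 + 0.3 * tl - 0.0002 * tl^2
  sine <- 0.05 * sin(2 * pi * tl / 50)
  r3 <- detrend_series(quadl + sine, "polynomial2")
  expect_lt(sqrt(mean((r3 - sine)^2)) / sqrt(mean(sine^2)), 0.01)
})

test_that("Lomb-Scargle finds injected periods with calibrated significance", {
  set.seed(77)
  tt <- 0:299
  x <- sin(2 * pi * tt / 50) + rnorm(300, 0, 0.5)
  ls <- lomb_scargle(x, rate = 1, period_range = c(20, 120))
  expect_gt(length(ls$significant_periods), 0)
  expect_lt(abs(ls$peak_period - 50), 1)

  # constant series -> no significant periods
  expect_equal(length(lomb_scargle(rep(3, 100), rate = 1)$significant_periods),
               0L)

  # series shorter than twice the longest period of interest -> error
  expect_error(lomb_scargle(rnorm(150), rate = 1, period_range = c(20, 120)),
               "twice the longest period")

  # false-alarm calibration: a significant peak in ~5% of noise series
  set.seed(78)
  hits <- replicate(1000, {
    length(lomb_scargle(rnorm(120), rate = 1)$significant_periods) > 0
  })
  expect_gt(mean(hits), 0.03)
  expect_lt(mean(hits), 0.07)
})

test_that("infraslow periodicity of NREM episodes is recovered", {
  cfg <- single_state_config("NREM", seed = 55)
  rec <- simulate_recording(cfg, 280)
  ih <- infraslow_period_histogram(rec, min_episode = 250)
  expect_equal(nrow(ih$episodes), 1L)
  expect_true(ih$episodes$power_significant[1])
  expect_lt(abs(ih$episodes$power_period_s[1] - 50), 5)

  # a 150 s episode is excluded at min_episode = 200
  rec2 <- simulate_recording(single_state_config("NREM", seed = 56), 150)
  ih2 <- infraslow_period_histogram(rec2, min_episode = 200)
  expect_equal(nrow(ih2$episodes), 0L)
  expect_true(is.na(ih2$summary$power$mean))
})

# direct-sum oracle for the Pearson-type cross-correlation at one lag
xcorr_oracle <- function(x, y, k) {
  n <- length(x)
  xm <- x - mean(x); ym <- y - mean(y)
  if (k >= 0) s <- sum(xm[(1 + k):n] * ym[1:(n - k)])
  else s <- sum(xm[1:(n + k)] * ym[(1 - k):n])
  s / n / (stats::sd(xm) * stats::sd(ym) * (n - 1) / n)
}

test_that("cross-correlation conventions match the direct-sum oracle", {
  set.seed(3)
  x <- rnorm(500)
  y <- rnorm(500)
  cc <- cross_correlate(x, y, rate = 10, max_lag = 5)
  for (k in c(-30, -7, 0, 13, 42)) {
    i <- which(abs(cc$lags - k / 10) < 1e-9)
    expect_equal(cc$r[i], xcorr_oracle(x, y, k), tolerance = 1e-10)
  }

  # a series against itself peaks at lag zero with r = 1
  self <- cross_correlate(x, x, rate = 10, max_lag = 5)
  expect_equal(self$r[self$lags == 0], 1, tolerance = 1e-10)
  expect_true(all(abs(self$r) <= 1 + 1e-12))

  # swapping the inputs mirrors the lag axis
  ab <- cross_correlate(x, y, rate = 10, max_lag = 5)
  ba <- cross_correlate(y, x, rate = 10, max_lag = 5)
  expect_equal(ab$r, rev(ba$r), tolerance = 1e-12)

  # significance threshold is 2/sqrt(N): direct evaluation of the formula
  z <- cross_correlate(rnorm(1000), rnorm(1000), rate = 10, max_lag = 20)
  expect_equal(z$sig_threshold, 2 / sqrt(1000), tolerance = 1e-12)

  expect_warning(cross_correlate(rnorm(100), rnorm(100), rate = 10,
                                 max_lag = 100),
                 "too short")
})

test_that("a kernel-delayed response is recovered at the injected lag", {
  set.seed(9)
  cfg <- generator_config(coupling_lag = 12, coupling_kernel_width = 4)
  drive <- thermosleep:::slow_noise(6000, 10, cutoff_hz = 0.02)
  resp <- thermosleep:::causal_filter(drive,
                                      thermosleep:::coupling_kernel(cfg)) +
    rnorm(6000, 0, 0.05)
  cc <- cross_correlate(resp, drive, rate = 10, max_lag = 40)
  expect_lt(abs(cc$peak_lag - 12), 1)
  expect_gt(cc$peak_r, 0.8)
})

test_that("grand-mean lag recovery bias stays below half a second", {
  s <- c("Wake", "TDW", "NREM", "REM", "CAS", "REMlike")
  g <- matrix(0, 6, 6, dimnames = list(s, s))
  g["REM", "REM"] <- 1
  for (lag in c(8, 10, 12, 14)) {
    ccs <- list()
    for (i in 1:5) {
      cfg <- generator_config(state_graph = g, initial_state = "REM",
                              coupling_lag = lag, seed = 700 + 13 * i + lag)
      r <- simulate_recording(cfg, 300)
      sp <- compute_cwt(r$eeg, freqs = seq(6, 10, 0.25), out_rate = 10)
      bp <- band_power_series(sp, c(6, 10), rate_out = 10, smooth_s = 20)
      tr <- detrend_series(r$temperature$values, "sigmoid", rate = 10)
      nn <- min(length(tr), length(bp$values))
      ccs[[i]] <- cross_correlate(tr[1:nn],
                                  bp$values[1:nn] - mean(bp$values[1:nn]),
                                  rate = 10, max_lag = 60)
    }
    gm <- average_crosscorr(ccs)
    expect_lt(abs(gm$peak_lag - lag), 0.5 + 1e-9)
  }
})

test_that("the heatmap row matches the standalone band cross-correlation", {
  set.seed(41)
  ee <- eeg_trace(rnorm(200 * 60, sd = 20), rate = 200)
  sp <- compute_cwt(ee, freqs = seq(10, 15, 0.25), out_rate = 10)
  temp_resid <- rnorm(600, 0, 0.005)
  hm <- crosscorr_spectrum(temp_resid, sp, rate = 10, max_lag = 20)
  # single-row consistency with the scalar pipeline
  i <- which(sp$freqs == 12)
  bp <- band_power_series(sp, c(12, 12), rate_out = 10, smooth_s = 20)
  cc <- suppressWarnings(
    cross_correlate(temp_resid[seq_along(bp$values)],
                    bp$values - mean(bp$values), rate = 10, max_lag = 20))
  expect_equal(hm$r[i, ], cc$r, tolerance = 1e-6)
  expect_equal(hm$contours[2], 0.25)
  expect_true(all(abs(hm$r) <= 1 + 1e-9, na.rm = TRUE))

  # uncoupled noise: no excess of significant cells
  frac_sig <- mean(abs(hm$r) > hm$sig_threshold, na.rm = TRUE)
  expect_lt(frac_sig, 0.35)   # 2/sqrt(N) is a pointwise ~5% level; smoothed
                              # rows are correlated across lags, so allow slack
})

test_that("coupled REM recordings put the strongest heatmap rows in theta", {
  s <- c("Wake", "TDW", "NREM", "REM", "CAS", "REMlike")
  g <- matrix(0, 6, 6, dimnames = list(s, s))
  g["REM", "REM"] <- 1
  hms <- list()
  for (i in 1:2) {
    cfg <- generator_config(state_graph = g, initial_state = "REM",
                            coupling_lag = 12, seed = 910 + i)
    r <- simulate_recording(cfg, 240)
    sp <- compute_cwt(r$eeg, freqs = seq(2, 20, 0.5), out_rate = 10)
    tr <- detrend_series(r$temperature$values, "sigmoid", rate = 10)
    hms[[i]] <- crosscorr_spectrum(tr, sp, rate = 10, max_lag = 30)
  }
  hm <- average_heatmaps(hms)
  pos <- hm$lags > 0
  row_peak <- apply(hm$r[, pos], 1L, max)
  best <- hm$freqs[which.max(row_peak)]
  expect_gte(best, 7)
  expect_lte(best, 9)
  # the peak lag of the best row sits at the injected delay
  best_lag <- hm$lags[pos][which.max(hm$r[which.max(row_peak), pos])]
  expect_lt(abs(best_lag - 12), 3)
})

test_that("thermal diffusion lengths reproduce the worked example", {
  expect_equal(round(diffusion_length(0.147, 10), 1), 2.4)
  expect_equal(round(diffusion_length(0.147, 14), 1), 2.9)
  expect_equal(diffusion_length(0.147, 0), 0)
  expect_error(diffusion_length(-1, 5), "non-negative")
})
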