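test_that("transition selection enforces the 3-before / 8-after rule", {
  lab <- c(rep("Wake", 3), rep("NREM", 8))
  expect_equal(select_transitions(hypnogram(lab), "Wake", "NREM"), 12)

  # only 2 epochs before: not selected
  lab2 <- c(rep("Wake", 2), rep("NREM", 9))
  expect_equal(length(select_transitions(hypnogram(lab2), "Wake", "NREM")),
               0L)

  # only 7 epochs after: not selected
  lab3 <- c(rep("Wake", 4), rep("NREM", 7))
  expect_equal(length(select_transitions(hypnogram(lab3), "Wake", "NREM")),
               0L)
})

test_that("transition selection equals the exhaustive-scan oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    lab <- sample(c("Wake", "NREM", "REM"), 500, replace = TRUE,
                  prob = c(0.4, 0.45, 0.15))
    hyp <- hypnogram(lab)
    for (pair in list(c("Wake", "NREM"), c("NREM", "REM"),
                      c("NREM", "Wake"))) {
      expect_equal(select_transitions(hyp, pair[1], pair[2]),
                   select_oracle(lab, pair[1], pair[2], 3, 8))
    }
  }
})

test_that("selection is invariant under concatenation of hypnograms", {
  set.seed(7)
  a <- sample(c("Wake", "NREM"), 200, replace = TRUE)
  b <- sample(c("Wake", "NREM"), 200, replace = TRUE)
  # sentinel padding: events of the concatenation within each half must
  # equal the halves' own events (no spurious boundary events beyond the
  # junction region)
  ev_a <- select_transitions(hypnogram(a), "Wake", "NREM")
  ev_ab <- select_transitions(hypnogram(c(a, b)), "Wake", "NREM")
  junction <- c((200 - 8) * 4, (200 + 3) * 4)
  expect_setequal(ev_ab[ev_ab < junction[1]], ev_a[ev_a < junction[1]])
  ev_b <- select_transitions(hypnogram(b), "Wake", "NREM") + 800
  expect_setequal(ev_ab[ev_ab > junction[2]], ev_b[ev_b > junction[2]])
})

test_that("aligned Delta T passes through zero and averages correctly", {
  # identical temperature course at all events -> grand mean = the profile
  lab <- rep(c(rep("Wake", 5), rep("NREM", 10)), 4)
  hyp <- hypnogram(lab)
  tt <- (seq_len(length(lab) * 40) - 1) / 10
  x <- 36 + 0.1 * sin(2 * pi * (tt %% 60) / 60)
  tr <- temperature_trace(x, rate = 10)
  ev <- select_transitions(hyp, "Wake", "NREM", pre_epochs = 3,
                           post_epochs = 8)
  expect_gt(length(ev), 1)
  ens <- aligned_delta_t(tr, hyp, ev)
  expect_true(all(abs(ens$traces[, ens$lag_s == 0]) < 1e-9))
  expect_equal(ens$mean, ens$traces[1, ], tolerance = 1e-9)

  # single event with linear post-transition slope s: Delta T = s * t
  lab2 <- c(rep("Wake", 5), rep("NREM", 10))
  hyp2 <- hypnogram(lab2)
  x2 <- c(rep(36, 200), 36 - 0.01 * (1:400) / 10)
  tr2 <- temperature_trace(x2, rate = 10)
  ens2 <- aligned_delta_t(tr2, hyp2, 20, pre_s = 8, post_s = 20)
  post <- ens2$lag_s > 0.2
  expect_equal(ens2$mean[post], -0.01 * ens2$lag_s[post], tolerance = 1e-3)

  # events too close to the edge are dropped with a warning
  expect_warning(aligned_delta_t(tr2, hyp2, c(4, 20), pre_s = 8, post_s = 20),
                 "dropped")
})

test_that("synthetic Wake->NREM ensembles decrease over the first 30 s", {
  rec <- dark_recording()
  ev <- select_transitions(rec$hypnogram, "Wake", "NREM")
  expect_gt(length(ev), 3)
  ens <- aligned_delta_t(rec$temperature, rec$hypnogram, ev)
  post <- ens$mean[ens$lag_s >= 0 & ens$lag_s <= 30]
  sm <- thermosleep:::moving_average(post, 3, rate = 10)
  expect_true(all(diff(sm[10:290]) < 1e-4))
  expect_lt(ens$mean[which.min(abs(ens$lag_s - 30))], -0.1)
})

test_that("cataplexy transitions show the expected temperature signs", {
  rec <- dark_recording()
  ev_wc <- c(select_transitions(rec$hypnogram, "Wake", "CAS"),
             select_transitions(rec$hypnogram, "TDW", "CAS"))
  expect_gt(length(ev_wc), 0)
  ens_wc <- aligned_delta_t(rec$temperature, rec$hypnogram, ev_wc)
  expect_lt(ens_wc$mean[which.min(abs(ens_wc$lag_s - 20))], 0)

  ev_cr <- select_transitions(rec$hypnogram, "CAS", "REMlike",
                              pre_epochs = 3, post_epochs = 3)
  expect_gt(length(ev_cr), 0)
  ens_cr <- aligned_delta_t(rec$temperature, rec$hypnogram, ev_cr,
                            post_s = 20)
  expect_gt(ens_cr$mean[which.min(abs(ens_cr$lag_s - 20))], 0)
})

test_that("transition spectra form pre/post means, ratios and heatmaps", {
  # identical pre/post signal -> ratio ~ 1 at the signal frequency
  set.seed(202)
  ee <- eeg_trace(sin(2 * pi * 8 * (0:(200 * 88 - 1)) / 200) * 30 +
                    rnorm(200 * 88, 0, 5), rate = 200)
  lab <- c(rep("Wake", 11), rep("NREM", 11))
  hyp <- hypnogram(lab)
  ts_ <- transition_spectra(ee, hyp, events = 44)
  expect_equal(ts_$n_events, 1L)
  expect_equal(ts_$ratio[ts_$freqs == 8], 1, tolerance = 0.1)
  band <- ts_$freqs >= 6 & ts_$freqs <= 10
  expect_equal(stats::median(ts_$ratio[band]), 1, tolerance = 0.5)
  expect_equal(dim(ts_$heatmap), c(18L, 401L))
  expect_equal(ts_$heatmap[1:10, ts_$freqs == 8], rep(1, 10),
               tolerance = 0.2, ignore_attr = TRUE)

  # doubled theta amplitude after the switch -> ratio ~ 4 in theta rows,
  # ~ 1 at an unchanged 30 Hz tone (Parseval on constructed tones)
  tt <- (0:(200 * 88 - 1)) / 200
  amp <- ifelse(tt < 44, 20, 40)
  ee2 <- eeg_trace(amp * sin(2 * pi * 8 * tt) + 15 * sin(2 * pi * 30 * tt) +
                     rnorm(length(tt), 0, 2),
                   rate = 200)
  ts2 <- transition_spectra(ee2, hyp, events = 44)
  th <- ts2$freqs >= 7.5 & ts2$freqs <= 8.5
  expect_equal(max(ts2$ratio[th]), 4, tolerance = 0.15)
  expect_equal(ts2$ratio[ts2$freqs == 30], 1, tolerance = 0.1)

  # an Artifact epoch in the window drops the event
  hyp3 <- hypnogram(replace(lab, 10, "Artifact"))
  expect_equal(transition_spectra(ee, hyp3, events = 44)$n_events, 0L)
})

test_that("Wake->CAS spectra shift theta downward and amplify it", {
  rec <- dark_recording()
  ev <- c(select_transitions(rec$hypnogram, "Wake", "CAS",
                             pre_epochs = 3, post_epochs = 3),
          select_transitions(rec$hypnogram, "TDW", "CAS",
                             pre_epochs = 3, post_epochs = 3))
  expect_gt(length(ev), 0)
  ts_ <- transition_spectra(rec$eeg, rec$hypnogram, ev, n_norm = 3,
                            post_epochs = 3)
  # the CAS theta peak sits below the pre-transition (waking) theta peak
  pre_band <- ts_$freqs >= 6 & ts_$freqs <= 10
  post_band <- ts_$freqs >= 5 & ts_$freqs <= 10
  pre_peak <- ts_$freqs[pre_band][which.max(ts_$pre[pre_band])]
  post_peak <- ts_$freqs[post_band][which.max(ts_$post[post_band])]
  expect_lt(post_peak, pre_peak)
  # and theta power increases across the switch
  th <- ts_$freqs >= 5.5 & ts_$freqs <= 8
  expect_gt(max(ts_$ratio[th], na.rm = TRUE), 1)
})
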