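# brute-force oracle for continuous drops: scan sign runs of the smoothed
# derivative directly
drops_oracle <- function(trace, min_dur, smooth_s) {
  sm <- thermosleep:::moving_average(trace$values, smooth_s, trace$rate)
  d <- diff(sm) < 0
  out <- NULL
  i <- 1L
  while (i <= length(d)) {
    if (d[i]) {
      j <- i
      while (j < length(d) && d[j + 1L]) j <- j + 1L
      if ((j - i + 1L) / trace$rate > min_dur)
        out <- rbind(out, c((i - 1L) / trace$rate, j / trace$rate))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

test_that("continuous drops are maximal negative runs longer than min_dur", {
  rate <- 10
  up <- temperature_trace(35 + seq_len(300) * 0.001, rate = rate)
  expect_equal(nrow(detect_continuous_drops(up, 5)), 0L)

  # triangle wave with 6 s limbs: every falling limb is returned
  tri <- piecewise_trace(data.frame(dur = rep(6, 10),
                                    slope = rep(c(0.02, -0.02), 5)))
  got <- detect_continuous_drops(tri, 5, smooth_s = 0.1)
  oracle <- drops_oracle(tri, 5, smooth_s = 0.1)
  expect_equal(nrow(got), 5L)
  expect_equal(as.matrix(got), oracle, ignore_attr = TRUE)

  # 4 s falling limbs stay below the 5 s threshold
  tri4 <- piecewise_trace(data.frame(dur = rep(c(8, 4), 5),
                                     slope = rep(c(0.02, -0.02), 5)))
  expect_equal(nrow(detect_continuous_drops(tri4, 5, smooth_s = 0.1)), 0L)

  # shorter trace than min_dur -> empty
  short <- temperature_trace(35 + rnorm(30, 0, 0.001), rate = rate)
  expect_equal(nrow(detect_continuous_drops(short, 5)), 0L)
})

test_that("wake episodes span the rise that ends at the temperature drop", {
  p <- scoring_params(drop_smoothing = 0.2, wake_start_tol = 1e-4)

  # one rise (40 s) then fall (30 s): a single wake episode over the rise
  tr <- piecewise_trace(data.frame(dur = c(40, 30), slope = c(0.01, -0.01)))
  w <- detect_wake_episodes(tr, p)
  expect_equal(nrow(w), 1L)
  expect_lt(abs(w$start_s - 0), 0.4)
  expect_lt(abs(w$end_s - 40), 0.4)

  # three rise-fall cycles: breakpoint-exact bounds (analytic oracle)
  tr3 <- piecewise_trace(data.frame(dur = rep(c(40, 30), 3),
                                    slope = rep(c(0.01, -0.01), 3)))
  w3 <- detect_wake_episodes(tr3, p)
  expect_equal(nrow(w3), 3L)
  expect_equal(w3$start_s, c(0, 70, 140), tolerance = 0.02)
  expect_equal(w3$end_s, c(40, 110, 180), tolerance = 0.02)

  # a 10 s rise cannot be captured (minimum episode 20 s)
  tr10 <- piecewise_trace(data.frame(dur = c(10, 30, 60, 30),
                                     slope = c(0.02, -0.01, 0.01, -0.01)))
  w10 <- detect_wake_episodes(tr10, p)
  expect_equal(nrow(w10), 1L)
  expect_gt(w10$start_s, 30)
})

test_that("sigmoid window fits separate logistic onsets from degenerate input", {
  tt <- seq(0, 2, by = 0.1)
  seg <- thermosleep:::logistic_curve(tt, L = 35.5, A = 0.4, k = 2.5, t0 = 1)
  f <- fit_sigmoid_window(seg, rate = 10)
  expect_true(f$valid)
  expect_gt(f$r2, 0.9999)

  expect_false(fit_sigmoid_window(rep(35.5, 21), rate = 10)$valid)

  lin <- 35.5 + 0.05 * tt
  expect_false(fit_sigmoid_window(lin, rate = 10,
                                  noise_floor = 0.005)$valid)
})

test_that("noisy logistic windows reach R^2 > 0.97 in at least 95% of cases", {
  tt <- seq(0, 2, by = 0.1)
  base <- thermosleep:::logistic_curve(tt, L = 0, A = 1, k = 2.5, t0 = 1)
  set.seed(404)
  ok <- replicate(1000, {
    f <- fit_sigmoid_window(base + rnorm(21, 0, 0.02), rate = 10)
    f$valid && f$r2 > 0.97
  })
  expect_gte(mean(ok), 0.95)
})

test_that("candidate onsets within 3 s keep the earlier one", {
  expect_equal(thermosleep:::merge_candidates(c(10, 12), 3), 10)
  expect_equal(thermosleep:::merge_candidates(c(10, 12, 13.5, 16), 3),
               c(10, 13.5))
  expect_equal(thermosleep:::merge_candidates(numeric(0), 3), numeric(0))
})

test_that("REM detection finds an injected sigmoidal rise and nothing else", {
  rate <- 10
  t_all <- seq(0, 150 - 0.1, by = 0.1)
  t0 <- 66   # inflection of the injected logistic (episode starts at 60)
  base <- 35.5 +
    thermosleep:::logistic_curve(t_all, L = 0, A = 0.4, k = 0.9, t0 = t0) +
    0.007 * pmax(t_all - 60, 0)
  base[t_all > 120] <- base[t_all <= 120][sum(t_all <= 120)] -
    0.012 * (t_all[t_all > 120] - 120)
  tr <- temperature_trace(base, rate = rate)
  rem <- detect_rem_episodes(tr)
  expect_equal(nrow(rem), 1L)
  # oracle: earliest sliding window that satisfies the documented guards on
  # the noiseless logistic (inflection inside the window with >= 5% of the
  # transition on both sides -> window start >= t0 - window + delta where
  # logistic(k * delta) = 0.55)
  delta <- log(0.55 / 0.45) / 0.9
  expect_lt(abs(rem$start_s - (t0 - 2 + delta)), 0.5)
  expect_gte(rem$start_s, t0 - 2)
  expect_lt(abs(rem$end_s - 120), 2)

  # monotone linear trace: the invalid-fit guard blocks everything
  lin <- temperature_trace(35.5 + 0.01 * t_all, rate = rate)
  expect_equal(nrow(detect_rem_episodes(lin)), 0L)
})

test_that("scored hypnograms cover the trace and recover synthetic truth", {
  # all-NREM recording scores as all NREM
  cfg <- single_state_config("NREM", seed = 9)
  rec <- simulate_recording(cfg, 400)
  pred <- score_states(rec$temperature)
  expect_identical(unique(pred$labels), "NREM")
  expect_equal(length(pred$labels), length(rec$hypnogram$labels))

  # 2 h default recording, episodes >= 24 s: high epochwise agreement
  # (the full-length recovery criterion is checked on 6 h in the
  # acceptance suite)
  cfg2 <- long_episode_config(seed = 7, cataplexy = FALSE)
  rec2 <- simulate_recording(cfg2, 7200)
  pred2 <- score_states(rec2$temperature)
  expect_equal(length(pred2$labels), length(rec2$hypnogram$labels))
  expect_gte(state_agreement(pred2, rec2$hypnogram), 0.8)
})

test_that("short wake/REM bouts are scored as NREM, inflating NREM time", {
  # dwell distributions concentrated below 20 s for wake and REM
  dw <- thermosleep:::default_dwell_params()
  dw$Wake <- list(mean = 12, sdlog = 0.2, min_epochs = 1L)
  dw$REM <- list(mean = 12, sdlog = 0.2, min_epochs = 1L)
  dw$NREM$min_epochs <- 8L
  cfg <- generator_config(dwell_params = dw, cataplexy = FALSE, seed = 15)
  rec <- simulate_recording(cfg, 7200)
  truth <- collapse_states(rec$hypnogram)
  bouts <- hyp_episodes(truth)
  short <- bouts[bouts$duration_s < 20 & bouts$state != "NREM", ]
  expect_gt(nrow(short), 10)
  pred <- score_states(rec$temperature)
  short_lab <- unlist(lapply(seq_len(nrow(short)), function(i)
    pred$labels[short$start_epoch[i]:short$end_epoch[i]]))
  # the short bouts are predominantly missed and labeled NREM ...
  expect_gt(mean(short_lab == "NREM"), 0.5)
  # ... so total NREM is overestimated
  expect_gt(sum(pred$labels == "NREM"), sum(truth$labels == "NREM"))
})

test_that("hourly comparison flags disagreement and is calibrated under the null", {
  set.seed(11)
  lab <- sample(c("Wake", "NREM", "REM"), 1800, replace = TRUE,
                prob = c(0.4, 0.5, 0.1))
  hyp <- hypnogram(lab)
  same <- compare_hourly(hyp, hyp)
  expect_equal(length(same$flagged_hours), 0L)
  expect_true(all(same$table$predicted_min == same$table$reference_min))

  # maximal disagreement: one hour all NREM vs all Wake
  a <- hypnogram(rep("Wake", 900))
  b <- hypnogram(rep("NREM", 900))
  expect_equal(compare_hourly(a, b)$flagged_hours, 1L)

  # permuted-epoch null: flagged fraction near the nominal level
  set.seed(12)
  flags <- replicate(300, {
    pool <- sample(c(rep("Wake", 700), rep("NREM", 1100)))
    compare_hourly(hypnogram(pool[1:900]),
                   hypnogram(pool[901:1800]))$flagged_fraction > 0
  })
  expect_gt(mean(flags), 0.02)
  expect_lt(mean(flags), 0.09)

  expect_warning(compare_hourly(hypnogram(rep("Wake", 1000)),
                                hypnogram(rep("Wake", 1000))),
                 "partial hour")
})
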