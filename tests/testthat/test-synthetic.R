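test_that("ECG generator places R peaks by construction", {
  ecg <- synth_ecg(360, 10, heart_rate_bpm = 60, rr_jitter_frac = 0, seed = 3)
  x <- ecg$samples
  expect_equal(max(abs(x)), 1) # normalized peak
  # exactly 10 R peaks, one per second
  peaks <- which(x > 0.8)
  groups <- split(peaks, cumsum(c(1, diff(peaks) > 10)))
  expect_length(groups, 10)
  centers <- vapply(groups, function(g) g[which.max(x[g])], numeric(1))
  expect_true(all(abs(diff(centers) - 360) <= 1))
  # periodicity objective recovers the heart period
  r <- nzopp(nacf(ecg), min_period_s = 0.25)
  expect_lte(abs(r$peak_lag - 360), 2)
})

test_that("generators are pure functions of parameters and seed", {
  expect_identical(synth_ecg(250, 5, seed = 9)$samples,
                   synth_ecg(250, 5, seed = 9)$samples)
  expect_false(identical(synth_ecg(250, 5, seed = 9)$samples,
                         synth_ecg(250, 5, seed = 10)$samples))
  for (k in c("BW", "EM", "MA", "MIX", "WHITE")) {
    expect_identical(synth_noise(k, 360, 1000, seed = 4)$samples,
                     synth_noise(k, 360, 1000, seed = 4)$samples)
  }
  expect_identical(synth_fiber_cardioresp(512, 10, seed = 2)$samples,
                   synth_fiber_cardioresp(512, 10, seed = 2)$samples)
  # the global RNG stream is left untouched
  set.seed(123)
  before <- stats::rnorm(3)
  set.seed(123)
  invisible(synth_ecg(250, 2, seed = 1))
  expect_identical(stats::rnorm(3), before)
})

test_that("noise generators meet their normalization and spectral contracts", {
  for (k in c("BW", "EM", "MA", "MIX", "WHITE")) {
    v <- synth_noise(k, 360, 7200, seed = 13)$samples
    expect_lt(abs(mean(v)), 1e-6)
    expect_lt(abs(mean(v^2) - 1), 1e-6)
  }
  # baseline wander: dominated by sub-hertz power
  bw <- synth_noise("BW", 360, 7200, seed = 14)$samples
  expect_gt(low_freq_power_frac(bw, 360, 1), 0.9)
  # muscle artifact: band-passed, little sub-10-Hz power
  ma <- synth_noise("MA", 360, 7200, seed = 14)$samples
  expect_lt(low_freq_power_frac(ma, 360, 10), 0.1)
  expect_error(synth_noise("PINK", 360, 100), "unknown noise kind")
})

test_that("mixing achieves the requested SNR exactly", {
  clean <- synth_ecg(360, 10, seed = 5)
  noise <- synth_noise("WHITE", 360, length(clean$samples), seed = 6)
  for (target in c(-10, 0, 5, 20)) {
    pair <- mix_at_snr(clean, noise, target)
    expect_lt(abs(snr(pair$clean, pair$noisy) - target), 1e-9)
    # the triple is consistent to floating-point accuracy
    expect_equal(pair$noisy$samples - pair$clean$samples,
                 pair$noise$samples, tolerance = 1e-12)
  }
  pair <- mix_at_snr(clean, noise, -10)
  expect_equal(sum(pair$noise$samples^2) / sum(pair$clean$samples^2), 10,
               tolerance = 1e-9)
  expect_equal(pair$noise_kind, "WHITE")
})

test_that("fiber cardiorespiratory signal has the constructed rates", {
  s <- synth_fiber_cardioresp(512, 20, heart_rate_bpm = 72, resp_rate_bpm = 15,
                              seed = 8)
  x <- s$samples
  expect_equal(max(abs(x)), 1)
  # dominant spectral line at the respiration frequency (0.25 Hz)
  sp <- Mod(stats::fft(x - mean(x)))^2
  half <- 2:(length(x) %/% 2)
  f_peak <- (which.max(sp[half])) * 512 / length(x)
  expect_lt(abs(f_peak - 0.25), 0.05)
  # the global periodicity peak sits at the (dominant) respiration period
  r <- nzopp(nacf(s), min_period_s = 0.5)
  expect_lte(abs(r$peak_lag - 512 * 60 / 15), 0.05 * 512 * 4)
  # with the sub-hertz respiration component removed, the cardiac beat
  # interval is the periodicity peak
  sp <- stats::fft(x)
  f <- (seq_along(x) - 1) * 512 / length(x)
  sp[f < 0.5 | f > 512 - 0.5] <- 0
  hp <- Re(stats::fft(sp, inverse = TRUE)) / length(x)
  rc <- nzopp(sampled_signal(hp, 512), min_period_s = 0.5)
  expect_lte(abs(rc$peak_lag - 512 * 60 / 72), 0.05 * 512 * 60 / 72)
  expect_error(synth_fiber_cardioresp(512, 10, heart_rate_bpm = 10,
                                      resp_rate_bpm = 15), "below")
})
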