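test_that("noise beds hit their calibrated levels", {
  expect_equal(measure_spl(synth_noise("high", 60, seed = 1)), 65, tolerance = 0.1)
  expect_equal(measure_spl(synth_noise("low", 60, seed = 2)), 45, tolerance = 0.1)
  expect_equal(measure_spl(synth_noise("no_playback", 60, seed = 3)), 25,
               tolerance = 0.5)
  expect_error(synth_noise("high", 0), "> 0")
})

test_that("bandpass noise confines power to the 250-500 Hz band", {
  fs <- 16000
  # oracle: the designed filter's squared magnitude response (applied
  # forward-backward, so |H|^4), integrated over frequency
  bf <- signal::butter(4, c(250, 500) / (fs / 2), type = "pass")
  f <- seq(1, fs / 2, by = 1)
  H <- signal::freqz(bf$b, bf$a, f, Fs = fs)
  g4 <- Mod(H$h)^4
  inb <- f >= 250 * 2^(-1 / 3) & f <= 500 * 2^(1 / 3)
  expect_lt(sum(g4[!inb]) / sum(g4), 0.05)
  # and the rendered noise agrees
  ps <- average_power_spectrum(synth_noise("high", 60, fs, seed = 4))
  inb2 <- ps$freqs >= 250 * 2^(-1 / 3) & ps$freqs <= 500 * 2^(1 / 3)
  expect_lt(sum(ps$power[!inb2]) / sum(ps$power), 0.05)
})

test_that("a drift- and jitter-free call is a pure harmonic series", {
  p <- synth_call_params(jitter_cv = 0, drift_frac = 0)
  cl <- synth_call(p, "no_playback", seed = 1, f0_base = 400, duration_s = 1)
  ps <- average_power_spectrum(cl$wave)
  expect_equal(ps$freqs[which.max(ps$power)], 400, tolerance = 32)
  expect_equal(measure_spl(cl$wave), 75, tolerance = 1e-6)
})

test_that("harmonic amplitudes follow the source tilt in dB/octave", {
  p <- synth_call_params(jitter_cv = 0, drift_frac = 0, n_harmonics = 8L,
                         source_tilt_by_condition = c(no_playback = -6, low = -6, high = -6))
  cl <- synth_call(p, "no_playback", seed = 2, f0_base = 400, duration_s = 1)
  ps <- average_power_spectrum(cl$wave, n_fft = 2048L, hop = 1024L)
  hk_db <- vapply(1:8, function(k) {
    sel <- abs(ps$freqs - 400 * k) <= 30
    10 * log10(sum(ps$power[sel]))
  }, numeric(1))
  expect_equal(hk_db - hk_db[1], -6 * log2(1:8), tolerance = 0.2)
})

test_that("the duration model matches the printed mean/median jointly", {
  pars <- duration_params_from_moments(0.785, 0.729)
  expect_equal(pars$mu, log(0.729))
  expect_equal(exp(pars$mu + pars$sigma^2 / 2), 0.785)  # lognormal moment identity
  d <- draw_durations(2000, synth_call_params(), seed = 11)
  expect_equal(mean(d), 0.785, tolerance = 0.02)
  expect_equal(median(d), 0.729, tolerance = 0.03)
  expect_true(all(d > 0))
})

test_that("per-call base f0 respects the [200, 800] Hz rejection bounds", {
  p <- synth_call_params(f0_median_by_condition = c(no_playback = 210, low = 210, high = 210),
                         f0_cv_by_condition = c(no_playback = 0.3, low = 0.3, high = 0.3))
  f0s <- vapply(1:50, function(i)
    synth_call(p, "low", seed = i, duration_s = 0.3)$f0_base, numeric(1))
  expect_true(all(f0s >= 200 & f0s <= 800))
})

test_that("session assembly is additive and calibrated", {
  design <- make_session_design(block_duration_s = 4, seed = 5)
  p <- synth_call_params()
  empty <- schedule_calls(design, p, seed = 5, mean_calls_per_block = 0, min_calls = 0L)
  asm0 <- assemble_session(design, p, empty, seed = 5)
  expect_identical(asm0$session$samples, asm0$noise_only$samples)
  expect_equal(nrow(asm0$annotations), 0L)

  sched <- schedule_calls(design, p, seed = 6, mean_calls_per_block = 1, min_calls = 1L)
  asm <- assemble_session(design, p, sched, seed = 5)
  diff <- asm$session$samples - asm0$session$samples
  fs <- asm$session$sample_rate
  a <- asm$annotations[1, ]
  i0 <- round(a$onset_s * fs) + 1L; i1 <- round(a$offset_s * fs)
  expect_gt(mean(diff[i0:i1]^2), 0)               # call present on its support
  outside <- rep(TRUE, length(diff))
  for (j in seq_len(nrow(asm$annotations))) {
    jj <- (round(asm$annotations$onset_s[j] * fs) + 1L):round(asm$annotations$offset_s[j] * fs)
    outside[jj] <- FALSE
  }
  expect_true(all(diff[outside] == 0))            # and nowhere else

  # mixing linearity: same design + schedule over a silent bed
  silent <- asm$session$samples - asm0$noise_only$samples
  expect_equal(asm$session$samples, asm0$noise_only$samples + silent)
})

test_that("per-call SNR over a high block is call_spl minus noise level", {
  ens <- simulate_call_ensemble("high", 30, synth_call_params(), seed = 12)
  snr <- vapply(ens$clips, function(cl)
    call_intensity(cl$wave, cl$context_noise)$snr_db, numeric(1))
  expect_equal(mean(snr, na.rm = TRUE), 75 - 65, tolerance = 0.5)
})

test_that("schedules that cross block boundaries are rejected", {
  design <- make_session_design(block_duration_s = 4, seed = 7)
  bad <- data.frame(block = 1L, condition = design$condition[1], seal_id = "A",
                    onset_s = 3.5, offset_s = 4.6, duration_s = 1.1)
  expect_error(assemble_session(design, synth_call_params(), bad, seed = 7),
               "schedule overflow")
})
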