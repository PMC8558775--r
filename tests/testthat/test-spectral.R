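test_that("average spectra satisfy the Parseval normalization identity", {
  set.seed(41)
  w <- waveform(rnorm(8192, 0, 0.1), 16000)
  ps <- average_power_spectrum(w)
  # mean windowed-frame power, computed directly in the time domain
  win <- 0.54 - 0.46 * cos(2 * pi * (0:511) / 511)
  starts <- seq(1, length(w$samples) - 511, by = 256)
  fp <- vapply(starts, function(s0)
    sum((w$samples[s0:(s0 + 511)] * win)^2) / sum(win^2), numeric(1))
  expect_equal(sum(ps$power), mean(fp), tolerance = 1e-6)
  # white noise: total power ~ variance
  expect_equal(sum(ps$power), 0.01, tolerance = 0.05)
  expect_equal(average_power_spectrum(waveform(numeric(1024), 16000))$power,
               rep(0, 257))
  expect_error(average_power_spectrum(waveform(numeric(100), 16000)), "too short")
})

test_that("a sine at an exact bin concentrates its power there", {
  fs <- 16000
  f <- 1000                                  # bin 32 of 512 at 16 kHz
  w <- waveform(0.4 * sin(2 * pi * f * (1:8192) / fs), fs)
  ps <- average_power_spectrum(w)
  k <- which.min(abs(ps$freqs - f))
  expect_gte(sum(ps$power[(k - 1):(k + 1)]) / sum(ps$power), 0.95)
  expect_equal(sum(ps$power), 0.4^2 / 2, tolerance = 0.4^2 / 2 * 0.05)
})

test_that("spectral subtraction is exact on identical inputs and identity on zero noise", {
  set.seed(42)
  w <- waveform(rnorm(4096, 0, 0.05), 16000)
  ps <- average_power_spectrum(w)
  zero <- average_power_spectrum(waveform(numeric(4096), 16000))
  expect_equal(spectral_subtract(ps, ps)$power, rep(0, length(ps$power)))
  expect_equal(spectral_subtract(ps, zero)$power, ps$power)
  w8 <- average_power_spectrum(waveform(rnorm(4096), 8000))
  expect_error(spectral_subtract(ps, w8), "sample rate")
})

test_that("spectral subtraction recovers the mean clean spectrum per band", {
  p <- synth_call_params()
  n <- 80
  ens <- simulate_call_ensemble("high", n, p, seed = 43)
  sub_bands <- 0; clean_bands <- 0
  for (i in seq_len(n)) {
    cl <- ens$clips[[i]]
    noisy <- average_power_spectrum(cl$wave)
    noise <- average_power_spectrum(cl$context_noise)
    clean <- waveform(cl$wave$samples - cl$context_noise$samples, cl$wave$sample_rate)
    sub <- spectral_subtract(noisy, noise)
    sub_bands <- sub_bands + third_octave_energies(sub, fmin = 200)$energy / n
    clean_bands <- clean_bands + third_octave_energies(average_power_spectrum(clean),
                                                       fmin = 200)$energy / n
  }
  rel <- abs(sub_bands - clean_bands) / clean_bands
  expect_true(all(rel < 0.10))
})

test_that("session gain estimation recovers planted preamp factors", {
  design <- make_session_design(block_duration_s = 4, seed = 44)
  p <- synth_call_params()
  sched <- schedule_calls(design, p, seed = 44, mean_calls_per_block = 1)
  asm <- assemble_session(design, p, sched, seed = 44)

  g1 <- estimate_session_gain(asm$noise_only, asm$noise_only,
                              asm$annotations[0, ], design)
  expect_equal(g1$session_gain, 1.0, tolerance = 1e-12)

  doubled <- waveform(asm$session$samples * 2, asm$session$sample_rate)
  g2 <- estimate_session_gain(doubled, asm$noise_only, asm$annotations, design)
  expect_equal(g2$session_gain, 4.0, tolerance = 0.02)
  # both noisy conditions see the same true preamp factor
  expect_equal(unname(g2$per_condition["low"] / g2$per_condition["high"]), 1,
               tolerance = 0.05)
  comp <- apply_gain_compensation(doubled, g2$session_gain)
  expect_equal(mean(comp$samples^2), mean(asm$session$samples^2), tolerance = 0.02)
})

test_that("features are invariant to session amplitude scaling", {
  design <- make_session_design(block_duration_s = 4, seed = 45)
  p <- synth_call_params()
  sched <- schedule_calls(design, p, seed = 45, mean_calls_per_block = 1)
  asm <- assemble_session(design, p, sched, seed = 45)
  f1 <- extract_call_features(asm$session, asm$noise_only, asm$annotations, design)
  scaled <- waveform(asm$session$samples * 1.7, asm$session$sample_rate)
  f2 <- extract_call_features(scaled, asm$noise_only, asm$annotations, design)
  for (col in c("f0_median_hz", "intensity_linear", "snr_db",
                "octave_slope_db_per_oct", "r14_db")) {
    ok <- !is.na(f1[[col]]) & !is.na(f2[[col]])
    expect_equal(f2[[col]][ok], f1[[col]][ok], tolerance = 1e-6)
  }
})

test_that("noise-compensated intensity is exact without noise and centered on noise", {
  fs <- 16000
  call <- waveform(0.1 * sin(2 * pi * 350 * (1:8000) / fs), fs)
  silent <- waveform(numeric(8000), fs)
  r <- call_intensity(call, silent)
  expect_equal(r$call_intensity, mean(call$samples^2))
  # noise-only intervals: compensated intensity centered on zero across seeds
  vals <- vapply(1:30, function(s) {
    a <- synth_noise("high", 0.5, fs, seed = s)
    b <- synth_noise("high", 0.5, fs, seed = s + 1000)
    call_intensity(a, b)$call_intensity
  }, numeric(1))
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)) + 1e-5)
  expect_true(is.na(call_intensity(silent, call)$snr_db))
})

test_that("third-octave bands double per octave on a flat spectrum", {
  flat <- structure(list(freqs = seq(0, 8000, by = 8000 / 512),
                         power = rep(1, 513), n_fft = 1024L, hop = 512L,
                         sample_rate = 16000, n_frames = 1L),
                    class = "pv_power_spectrum")
  b <- third_octave_energies(flat)
  expect_true(1000 %in% round(b$center_hz))
  expect_false(any(abs(b$center_hz - 315) < 1))   # 315*2^(1/6) < 400: excluded
  expect_gt(min(b$center_hz), 400)
  # bandwidth doubles per octave: energies at c and 2c differ by factor 2
  e1000 <- b$energy[abs(b$center_hz - 1000) < 1]
  e2000 <- b$energy[abs(b$center_hz - 2000) < 1]
  expect_equal(e2000 / e1000, 2, tolerance = 0.05)
})

test_that("octave slope matches closed-form OLS on log-linear data", {
  centers <- 1000 * 2^((-3:8) / 3)
  # halving per band step: 10*log10(2) dB down per 1/3 octave -> -9.0309 dB/oct
  bands <- data.frame(center_hz = centers, octaves = log2(centers / 1000),
                      energy = 2^(-(0:11)))
  expect_equal(octave_slope(bands)$slope, -30 * log10(2), tolerance = 1e-9)
  bands$energy <- rep(3, 12)
  expect_equal(octave_slope(bands)$slope, 0)
  bands$energy <- c(5, rep(-1, 11))
  sl <- octave_slope(bands)
  expect_true(is.na(sl$slope))
  expect_match(sl$discard_reason, "positive")
  expect_equal(sl$n_positive_bands, 1L)
})

test_that("R14 equals the bandwidth ratio on a flat spectrum and guards signs", {
  flat <- structure(list(freqs = seq(0, 8000, length.out = 4097),
                         power = rep(1 / 4097, 4097), n_fft = 8192L, hop = 4096L,
                         sample_rate = 16000, n_frames = 1L),
                    class = "pv_power_spectrum")
  expect_equal(r14(flat)$r14, 10 * log10(600 / 3000), tolerance = 0.02)
  lowonly <- flat
  lowonly$power[lowonly$freqs > 1000] <- -1e-9
  expect_true(is.na(r14(lowonly)$r14))
  # boosting 1-4 kHz lowers R14 monotonically
  vals <- vapply(c(1, 2, 4), function(boost) {
    s <- flat
    s$power[s$freqs > 1000 & s$freqs <= 4000] <-
      s$power[s$freqs > 1000 & s$freqs <= 4000] * boost
    r14(s)$r14
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})
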