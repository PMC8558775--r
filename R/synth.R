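#' Synthesis parameters for pup-like calls
#'
#' Defaults encode the study conditions the pipeline is built to emulate:
#' per-condition population median f0 of 403 / 374 / 324 Hz (no playback /
#' low / high noise), lower f0 dispersion under high noise, lognormal call
#' durations with mean 0.785 s and median 0.729 s, and a constant call level
#' of 75 dB SPL in every condition (no intrinsic Lombard response, so the
#' high-noise signal-to-noise ratio is +10 dB). Per-condition overrides of
#' `call_spl_by_condition` and `source_tilt_by_condition` express
#' Lombard-response scenarios (intensity gain, tilt flattening) for single
#' individuals.
#'
#' @param f0_median_by_condition Named numeric: population median f0 (Hz) per
#'   condition; medians must lie in [200, 800] Hz.
#' @param f0_cv_by_condition Named numeric: population coefficient of
#'   variation of the per-call base f0 per condition (>= 0).
#' @param source_tilt_by_condition Named numeric: harmonic source tilt in
#'   dB/octave per condition (harmonic k sits at `tilt * log2(k)` dB relative
#'   to the fundamental).
#' @param call_spl_by_condition Named numeric: calibrated call level in dB SPL
#'   per condition; must not exceed the calibration point.
#' @param duration_mu,duration_sigma Lognormal parameters of call duration in
#'   seconds (`mu` is the log-median).
#' @param n_harmonics Number of harmonics in the source (harmonics above
#'   0.45 * sample_rate are dropped at render time).
#' @param jitter_cv Cycle-to-cycle multiplicative jitter of the instantaneous
#'   f0 (coefficient of variation, dimensionless).
#' @param drift_frac Peak fractional depth of the slow sinusoidal f0 drift.
#' @param drift_rate_hz Range (length 2) of the drift rate in Hz.
#' @param onset_ramp Raised-cosine onset/offset ramp length in seconds.
#' @return A `pv_call_params` list.
#' @export
synth_call_params <- function(
    f0_median_by_condition = c(no_playback = 403, low = 374, high = 324),
    f0_cv_by_condition = c(no_playback = 0.08, low = 0.08, high = 0.05),
    source_tilt_by_condition = c(no_playback = -6, low = -6, high = -6),
    call_spl_by_condition = c(no_playback = 75, low = 75, high = 75),
    duration_mu = log(0.729),
    duration_sigma = sqrt(2 * log(0.785 / 0.729)),
    n_harmonics = 18L,
    jitter_cv = 0.02,
    drift_frac = 0.03,
    drift_rate_hz = c(2, 4),
    onset_ramp = 0.02) {
  p <- list(f0_median_by_condition = f0_median_by_condition,
            f0_cv_by_condition = f0_cv_by_condition,
            source_tilt_by_condition = source_tilt_by_condition,
            call_spl_by_condition = call_spl_by_condition,
            duration_mu = duration_mu, duration_sigma = duration_sigma,
            n_harmonics = as.integer(n_harmonics), jitter_cv = jitter_cv,
            drift_frac = drift_frac, drift_rate_hz = drift_rate_hz,
            onset_ramp = onset_ramp)
  for (nm in c("f0_median_by_condition", "f0_cv_by_condition",
               "source_tilt_by_condition", "call_spl_by_condition")) {
    if (!all(CONDITIONS %in% names(p[[nm]])))
      stop(nm, " must be named with all of: ", paste(CONDITIONS, collapse = ", "))
  }
  if (any(p$f0_median_by_condition < 200 | p$f0_median_by_condition > 800))
    stop("f0 medians must lie in [200, 800] Hz")
  if (any(p$f0_cv_by_condition < 0)) stop("f0 CVs must be >= 0")
  if (p$duration_sigma < 0 || p$onset_ramp < 0 || p$jitter_cv < 0)
    stop("duration_sigma, onset_ramp and jitter_cv must be >= 0")
  class(p) <- "pv_call_params"
  p
}

#' Lognormal duration parameters from a mean and a median
#'
#' For a lognormal variable, `median = exp(mu)` and
#' `mean = exp(mu + sigma^2/2)`, so `mu = log(median)` and
#' `sigma = sqrt(2 * log(mean / median))`. This is how the default duration
#' model is parameterized from a printed mean of 0.785 s and median of
#' 0.729 s.
#'
#' @param mean_s,median_s Target mean and median in seconds; `mean_s >=
#'   median_s > 0`.
#' @return List with elements `mu` and `sigma`.
#' @export
duration_params_from_moments <- function(mean_s, median_s) {
  stopifnot(median_s > 0, mean_s >= median_s)
  list(mu = log(median_s), sigma = sqrt(2 * log(mean_s / median_s)))
}

#' Draw call durations from the lognormal duration model
#'
#' @param n Number of draws.
#' @param params A [synth_call_params()] object.
#' @param seed Integer seed.
#' @return Numeric vector of durations in seconds.
#' @export
draw_durations <- function(n, params = synth_call_params(), seed = 1L) {
  rng_local(derive_seed(seed, 7L), {
    stats::rlnorm(n, meanlog = params$duration_mu, sdlog = params$duration_sigma)
  })
}

#' Synthesize a noise bed for one condition
#'
#' Low- and high-noise beds are white Gaussian noise bandpass-filtered to
#' 250-500 Hz with a 4th-order Butterworth filter applied forward-backward
#' (zero phase), then RMS-calibrated to 45 / 65 dB SPL. The no-playback bed
#' is broadband Gaussian noise calibrated to the 25 dB SPL ambient level.
#' Calibration is applied after filtering, so measured levels are exact.
#'
#' @param condition One of `"no_playback"`, `"low"`, `"high"`.
#' @param duration_s Duration in seconds (> 0).
#' @param sample_rate Sampling rate in Hz.
#' @param cal A [calibration()] object.
#' @param seed Integer seed.
#' @param spl_by_condition Named levels in dB SPL; defaults 25 / 45 / 65.
#' @return A [waveform()].
#' @export
synth_noise <- function(condition, duration_s, sample_rate = 16000,
                        cal = calibration(), seed = 1L,
                        spl_by_condition = c(no_playback = 25, low = 45, high = 65)) {
  condition <- match.arg(condition, CONDITIONS)
  if (duration_s <= 0) stop("duration_s must be > 0")
  n <- round(duration_s * sample_rate)
  pad <- round(0.5 * sample_rate)    # absorb filter edge transients
  x <- rng_local(derive_seed(seed, 11L), stats::rnorm(n + 2L * pad))
  if (condition != "no_playback") {
    bf <- noise_band_filter(sample_rate)
    x <- signal::filtfilt(bf, x)
  }
  x <- x[(pad + 1L):(pad + n)]
  x <- x * spl_to_rms(spl_by_condition[[condition]], cal) / sqrt(mean(x^2))
  waveform(x, sample_rate)
}

# 4th-order Butterworth bandpass 250-500 Hz (applied forward-backward, so the
# effective magnitude response is |H|^2).
noise_band_filter <- function(sample_rate, band = c(250, 500)) {
  signal::butter(4, band / (sample_rate / 2), type = "pass")
}

#' Synthesize one pup-like call
#'
#' The source is a sum of `n_harmonics` harmonics at multiples of a
#' time-varying f0: a per-call constant base (drawn lognormally so the
#' condition's population median and CV match `params`), a slow sinusoidal
#' drift, and multiplicative cycle-level jitter. Harmonic amplitudes follow
#' the condition's source tilt in dB/octave; raised-cosine ramps shape onset
#' and offset; duration is lognormal; the rendered call is RMS-calibrated to
#' the condition's call level. Base f0 draws falling outside [200, 800] Hz
#' are rejected and redrawn.
#'
#' @param params A [synth_call_params()].
#' @param condition Noise condition the call is produced in.
#' @param seed Integer seed.
#' @param sample_rate Sampling rate in Hz.
#' @param cal A [calibration()] object.
#' @param duration_s Optional fixed duration override (else drawn).
#' @param f0_base Optional fixed base f0 override in Hz (else drawn).
#' @return List: `wave` ([waveform()]), and ground truth `f0_base` (Hz),
#'   `f0_contour` (data.frame time_s, f0_hz), `duration_s`, `spl_db`,
#'   `tilt_db_per_oct`, `n_rejected` (f0 redraws).
#' @export
synth_call <- function(params, condition, seed = 1L, sample_rate = 16000,
                       cal = calibration(), duration_s = NULL, f0_base = NULL) {
  condition <- match.arg(condition, CONDITIONS)
  med <- params$f0_median_by_condition[[condition]]
  cv <- params$f0_cv_by_condition[[condition]]
  tilt <- params$source_tilt_by_condition[[condition]]
  spl <- params$call_spl_by_condition[[condition]]

  rng_local(derive_seed(seed, 13L), {
    n_rejected <- 0L
    if (is.null(f0_base)) {
      sdlog <- sqrt(log(1 + cv^2))   # lognormal: median exp(mu), CV sqrt(exp(s^2)-1)
      repeat {
        f0_base <- stats::rlnorm(1, meanlog = log(med), sdlog = sdlog)
        if (f0_base >= 200 && f0_base <= 800) break
        n_rejected <- n_rejected + 1L
      }
    }
    if (is.null(duration_s))
      duration_s <- stats::rlnorm(1, params$duration_mu, params$duration_sigma)
    n <- max(round(duration_s * sample_rate), 32L)
    t <- (seq_len(n) - 0.5) / sample_rate

    drift_rate <- stats::runif(1, params$drift_rate_hz[1], params$drift_rate_hz[2])
    drift_phase <- stats::runif(1, 0, 2 * pi)
    f0_inst <- f0_base * (1 + params$drift_frac * sin(2 * pi * drift_rate * t + drift_phase))
    if (params$jitter_cv > 0) {
      n_cycles <- max(ceiling(duration_s * f0_base) + 1L, 2L)
      jit <- stats::rnorm(n_cycles, 0, params$jitter_cv)
      cyc_t <- seq(0, duration_s, length.out = n_cycles)
      f0_inst <- f0_inst * pmax(1 + stats::approx(cyc_t, jit, xout = t, rule = 2)$y, 0.5)
    }

    phase <- 2 * pi * cumsum(f0_inst) / sample_rate
    k_max <- min(params$n_harmonics, floor(0.45 * sample_rate / max(f0_inst)))
    k_max <- max(k_max, 1L)
    amps <- 10^(tilt * log2(seq_len(k_max)) / 20)
    x <- numeric(n)
    for (k in seq_len(k_max)) x <- x + amps[k] * sin(k * phase)

    nr <- min(round(params$onset_ramp * sample_rate), floor(n / 2))
    if (nr > 0) {
      ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
      x[seq_len(nr)] <- x[seq_len(nr)] * ramp
      x[(n - nr + 1L):n] <- x[(n - nr + 1L):n] * rev(ramp)
    }
    x <- x * spl_to_rms(spl, cal) / sqrt(mean(x^2))
  })

  step <- 0.01
  ft <- seq(step / 2, duration_s, by = step)
  fc <- stats::approx(t, f0_inst, xout = pmin(ft, max(t)), rule = 2)$y
  list(wave = waveform(x, sample_rate),
       f0_base = f0_base,
       f0_contour = data.frame(time_s = ft, f0_hz = fc),
       duration_s = n / sample_rate,
       spl_db = spl,
       tilt_db_per_oct = tilt,
       n_rejected = n_rejected)
}

#' Schedule calls inside the blocks of a session design
#'
#' Draws a number of calls per block (Poisson with mean
#' `mean_calls_per_block`, at least `min_calls`) and places them sequentially
#' with random gaps so that no call crosses a block boundary and calls within
#' a block do not overlap. Seals alternate between the two housed
#' individuals.
#'
#' @param design A [make_session_design()] result.
#' @param params A [synth_call_params()] (used for duration draws).
#' @param seed Integer seed.
#' @param mean_calls_per_block Poisson mean of calls per block.
#' @param min_calls Minimum number of calls per block.
#' @param seal_ids Character vector of seals present in the session.
#' @param margin_s Guard margin kept clear at each block edge, seconds.
#' @return data.frame: `block`, `condition`, `seal_id`, `onset_s`,
#'   `offset_s`, `duration_s` (session-relative seconds).
#' @export
schedule_calls <- function(design, params = synth_call_params(), seed = 1L,
                           mean_calls_per_block = 4, min_calls = 1L,
                           seal_ids = c("A", "B"), margin_s = 0.2) {
  validate_design(design)
  out <- vector("list", nrow(design))
  for (b in seq_len(nrow(design))) {
    blk <- design[b, ]
    rng_local(derive_seed(seed, 17L, b), {
      n_calls <- max(stats::rpois(1, mean_calls_per_block), min_calls)
      durs <- stats::rlnorm(n_calls, params$duration_mu, params$duration_sigma)
      avail <- blk$duration_s - 2 * margin_s - sum(durs)
      while (avail <= 0 && n_calls > 0) {      # drop calls that cannot fit
        n_calls <- n_calls - 1L
        durs <- durs[seq_len(n_calls)]
        avail <- blk$duration_s - 2 * margin_s - sum(durs)
      }
      if (n_calls == 0L) {
        out[b] <- list(NULL)
      } else {
        gaps <- stats::runif(n_calls + 1L)
        gaps <- gaps / sum(gaps) * avail
        onsets <- blk$onset_s + margin_s + cumsum(gaps[seq_len(n_calls)]) +
          c(0, cumsum(durs))[seq_len(n_calls)]
        out[[b]] <- data.frame(
          block = blk$block, condition = blk$condition,
          seal_id = rep_len(seal_ids, n_calls),
          onset_s = onsets, offset_s = onsets + durs, duration_s = durs,
          stringsAsFactors = FALSE)
      }
    })
  }
  sched <- do.call(rbind, out)
  if (is.null(sched))
    sched <- data.frame(block = integer(), condition = character(),
                        seal_id = character(), onset_s = numeric(),
                        offset_s = numeric(), duration_s = numeric(),
                        stringsAsFactors = FALSE)
  rownames(sched) <- NULL
  sched
}

#' Assemble a full session: noise bed plus scheduled calls
#'
#' Builds the per-block noise bed, renders each scheduled call and adds it
#' sample-wise onto the bed, and emits a matched noise-only rendering of the
#' identical design (the surrogate for separate noise-only recordings).
#' Mixing is strictly additive, so the session minus the noise bed equals the
#' sum of call waveforms exactly.
#'
#' @param design A [make_session_design()] result.
#' @param params A [synth_call_params()].
#' @param schedule A call schedule as from [schedule_calls()] (may have zero
#'   rows). Calls must fit inside their blocks.
#' @param cal A [calibration()] object.
#' @param seed Integer session seed; per-block and per-call child seeds are
#'   derived deterministically.
#' @param sample_rate Sampling rate in Hz.
#' @param session_id Session label recorded in the annotations.
#' @param gain Linear amplitude factor applied to the session rendering only
#'   (emulates per-session preamplifier gain; the noise-only rendering is
#'   left at reference gain).
#' @param noise_spl_by_condition Noise levels in dB SPL per condition.
#' @return List: `session` ([waveform()]), `noise_only` ([waveform()]),
#'   `annotations` (data.frame with identity columns, screening flag
#'   `extraneous_noise`, and ground-truth `true_*` columns).
#' @export
assemble_session <- function(design, params = synth_call_params(),
                             schedule = NULL, cal = calibration(), seed = 1L,
                             sample_rate = 16000, session_id = "S1", gain = 1,
                             noise_spl_by_condition = c(no_playback = 25, low = 45, high = 65)) {
  validate_design(design)
  total_n <- round(sum(design$duration_s) * sample_rate)
  bed <- numeric(total_n)
  for (b in seq_len(nrow(design))) {
    blk <- design[b, ]
    nw <- synth_noise(blk$condition, blk$duration_s, sample_rate, cal,
                      seed = derive_seed(seed, 19L, b),
                      spl_by_condition = noise_spl_by_condition)
    i0 <- round(blk$onset_s * sample_rate) + 1L
    bed[i0:(i0 + length(nw$samples) - 1L)] <- nw$samples
  }

  if (is.null(schedule)) schedule <- schedule_calls(design, params, seed = seed)
  n_calls <- if (is.null(schedule)) 0L else nrow(schedule)
  mix <- bed
  ann <- vector("list", n_calls)
  if (n_calls > 0) {
    for (i in seq_len(n_calls)) {
      row <- schedule[i, ]
      blk <- design[design$block == row$block, ]
      if (row$onset_s < blk$onset_s || row$offset_s > blk$offset_s)
        stop(sprintf("schedule overflow: call %d [%.3f, %.3f] s does not fit block %d [%.1f, %.1f] s",
                     i, row$onset_s, row$offset_s, row$block, blk$onset_s, blk$offset_s))
      cl <- synth_call(params, row$condition, seed = derive_seed(seed, 23L, i),
                       sample_rate = sample_rate, cal = cal,
                       duration_s = row$duration_s)
      i0 <- round(row$onset_s * sample_rate) + 1L
      idx <- i0:(i0 + length(cl$wave$samples) - 1L)
      mix[idx] <- mix[idx] + cl$wave$samples
      ann[[i]] <- data.frame(
        session_id = session_id, seal_id = row$seal_id,
        condition = row$condition, trial_index = row$block,
        onset_s = (i0 - 1L) / sample_rate,
        offset_s = (i0 - 1L + length(cl$wave$samples)) / sample_rate,
        extraneous_noise = FALSE,
        true_f0_median_hz = stats::median(cl$f0_contour$f0_hz),
        true_f0_base_hz = cl$f0_base,
        true_duration_s = cl$duration_s,
        true_spl_db = cl$spl_db,
        true_tilt_db_per_oct = cl$tilt_db_per_oct,
        stringsAsFactors = FALSE)
    }
  }
  annotations <- if (n_calls > 0) do.call(rbind, ann) else
    data.frame(session_id = character(), seal_id = character(),
               condition = character(), trial_index = integer(),
               onset_s = numeric(), offset_s = numeric(),
               extraneous_noise = logical(),
               true_f0_median_hz = numeric(), true_f0_base_hz = numeric(),
               true_duration_s = numeric(), true_spl_db = numeric(),
               true_tilt_db_per_oct = numeric(), stringsAsFactors = FALSE)
  rownames(annotations) <- NULL
  list(session = waveform(mix * gain, sample_rate),
       noise_only = waveform(bed, sample_rate),
       annotations = annotations,
       design = design)
}
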