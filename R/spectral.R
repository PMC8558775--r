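#' Average power spectrum of a waveform
#'
#' Welch-style average of framed periodograms: frames of `n_fft` samples at
#' hop `hop`, Hamming-windowed. The normalizer is chosen so that the summed
#' one-sided bin power equals the mean windowed-frame power
#' `sum((x*w)^2) / sum(w^2)`: the spectrum of a sine of amplitude A
#' integrates to A^2/2 and white noise of variance s^2 integrates to s^2,
#' i.e. spectra integrate to RMS power and are directly comparable with
#' [call_intensity()] values.
#'
#' @param w A [waveform()] of at least `n_fft` samples.
#' @param n_fft Frame / FFT length in samples.
#' @param hop Hop between frames in samples.
#' @return A `pv_power_spectrum`: list with `freqs` (Hz, 0..Nyquist), `power`
#'   (linear power per bin), `n_fft`, `hop`, `sample_rate`, `n_frames`.
#' @export
average_power_spectrum <- function(w, n_fft = 512L, hop = 256L) {
  x <- w$samples
  if (length(x) < n_fft)
    stop(sprintf("input too short: %d samples < n_fft = %d", length(x), n_fft))
  starts <- seq(1L, length(x) - n_fft + 1L, by = hop)
  win <- 0.54 - 0.46 * cos(2 * pi * (seq_len(n_fft) - 1) / (n_fft - 1))
  idx <- outer(seq_len(n_fft) - 1L, starts, `+`)
  frames <- matrix(x[idx], nrow = n_fft) * win
  spec <- stats::mvfft(frames)
  n_bins <- n_fft %/% 2L + 1L
  p2 <- rowMeans(Mod(spec[seq_len(n_bins), , drop = FALSE])^2)
  coef <- c(1, rep(2, n_bins - 2L), 1)          # one-sided doubling
  power <- coef * p2 / (n_fft * sum(win^2))
  structure(list(freqs = (seq_len(n_bins) - 1L) * w$sample_rate / n_fft,
                 power = power, n_fft = n_fft, hop = hop,
                 sample_rate = w$sample_rate, n_frames = length(starts)),
            class = "pv_power_spectrum")
}

#' Subtract a noise power spectrum from a call power spectrum
#'
#' Bin-wise difference with negative values preserved: under independence of
#' call and noise the expectation of the difference equals the clean-call
#' spectrum, so consumers (tilt fits, band ratios) decide how to treat
#' negative bins. The two spectra must share FFT size and sample rate.
#'
#' @param call,noise `pv_power_spectrum` objects.
#' @return A signed `pv_power_spectrum`.
#' @export
spectral_subtract <- function(call, noise) {
  stopifnot(inherits(call, "pv_power_spectrum"), inherits(noise, "pv_power_spectrum"))
  if (call$n_fft != noise$n_fft || call$sample_rate != noise$sample_rate)
    stop("spectra differ in n_fft or sample rate")
  out <- call
  out$power <- call$power - noise$power
  out
}

#' Estimate the per-session preamplifier gain
#'
#' Recording sessions carry an unknown gain relative to the noise-only
#' reference recordings. The gain is estimated as the RMS power of the
#' session's non-vocal portions (annotated calls masked out) in each noisy
#' condition, divided by the matching power in the noise-only reference; the
#' session gain is the geometric mean over the low and high conditions.
#' Dividing the session samples by `sqrt(session_gain)` equalizes the
#' condition powers with the reference (see [apply_gain_compensation()]).
#'
#' @param session Session [waveform()].
#' @param noise_ref Matched noise-only [waveform()] (same length/rate).
#' @param annotations Annotation data.frame (calls masked out of the
#'   non-vocal power estimate).
#' @param design Session design giving block condition intervals.
#' @param conditions Conditions used for the estimate (default low + high).
#' @return List: `session_gain` (linear power factor), `per_condition`
#'   (named vector of per-condition gains).
#' @export
estimate_session_gain <- function(session, noise_ref, annotations, design,
                                  conditions = c("low", "high")) {
  fs <- session$sample_rate
  n <- length(session$samples)
  voiced <- rep(FALSE, n)
  if (nrow(annotations) > 0) {
    for (i in seq_len(nrow(annotations))) {
      i0 <- floor(annotations$onset_s[i] * fs) + 1L
      i1 <- min(ceiling(annotations$offset_s[i] * fs), n)
      voiced[i0:i1] <- TRUE
    }
  }
  gains <- vapply(conditions, function(cond) {
    mask <- rep(FALSE, n)
    blocks <- design[design$condition == cond, , drop = FALSE]
    for (b in seq_len(nrow(blocks))) {
      i0 <- floor(blocks$onset_s[b] * fs) + 1L
      i1 <- min(round(blocks$offset_s[b] * fs), n)
      mask[i0:i1] <- TRUE
    }
    keep <- mask & !voiced
    if (!any(keep)) stop("no non-vocal audio in condition ", cond)
    mean(session$samples[keep]^2) / mean(noise_ref$samples[keep]^2)
  }, numeric(1))
  names(gains) <- conditions
  list(session_gain = exp(mean(log(gains))), per_condition = gains)
}

#' Apply gain compensation to a waveform
#'
#' Divides samples by `sqrt(session_gain)` (gain is a power-domain factor),
#' matching the session's level to the noise-only reference. Worked example:
#' a session recorded with the preamplifier at twice the reference amplitude
#' has `session_gain = 4`; dividing by `sqrt(4) = 2` restores reference
#' level.
#'
#' @param w A [waveform()].
#' @param session_gain Linear power-domain gain from
#'   [estimate_session_gain()].
#' @return Compensated [waveform()].
#' @export
apply_gain_compensation <- function(w, session_gain) {
  stopifnot(session_gain > 0)
  waveform(w$samples / sqrt(session_gain), w$sample_rate)
}

#' Noise-compensated call intensity and SNR
#'
#' Call intensity is the RMS power of the (gain-compensated) call interval
#' minus the RMS power of the matched noise-only interval. For low-SNR calls
#' the difference can be negative; the estimator is kept linear (no flooring)
#' because the mean over calls is then an unbiased estimate of the mean
#' clean-call power, so condition comparisons are done in the linear
#' (non-decibel) domain. The SNR in dB is only defined for calls with
#' positive compensated intensity.
#'
#' @param call_wave Call interval [waveform()] (gain-compensated).
#' @param noise_wave Matched noise-only interval [waveform()].
#' @return List: `call_intensity` (linear power, may be negative),
#'   `noise_intensity` (linear power), `snr_db` (dB, NA when intensity <= 0).
#' @export
call_intensity <- function(call_wave, noise_wave) {
  p_call <- mean(call_wave$samples^2)
  p_noise <- mean(noise_wave$samples^2)
  intensity <- p_call - p_noise
  list(call_intensity = intensity,
       noise_intensity = p_noise,
       snr_db = if (intensity > 0) 10 * log10(intensity / p_noise) else NA_real_)
}

#' One-third-octave band energies
#'
#' Bands are centered on `ref * 2^(k/3)` Hz with edges a factor `2^(1/6)`
#' either side; only centers strictly above `fmin` and at most `fmax` are
#' kept, so with the default 400 Hz cut the lowest band is centered at
#' 500 Hz. Band energy is the sum of the (signed) bin powers whose
#' frequencies fall in the band, so post-subtraction spectra may yield
#' negative band energies; positivity is enforced later, at the fit stage.
#'
#' @param s A `pv_power_spectrum` (typically after [spectral_subtract()]).
#' @param ref Reference frequency in Hz (band centers pass through it).
#' @param fmin Lower cut in Hz: bands centered at or below it are dropped.
#' @param fmax Upper limit in Hz for band centers; default
#'   `min(8000, Nyquist * 2^(-1/6))` so the top band fits below Nyquist.
#' @return data.frame: `center_hz`, `octaves` (log2(center/ref)), `energy`.
#' @export
third_octave_energies <- function(s, ref = 1000, fmin = 400, fmax = NULL) {
  nyq <- s$sample_rate / 2
  if (is.null(fmax)) fmax <- min(8000, nyq * 2^(-1 / 6))
  ks <- seq(ceiling(3 * log2(fmin / ref) - 1e-9), floor(3 * log2(fmax / ref) + 1e-9))
  centers <- ref * 2^(ks / 3)
  centers <- centers[centers > fmin & centers <= fmax]
  energy <- vapply(centers, function(fc) {
    lo <- fc * 2^(-1 / 6); hi <- fc * 2^(1 / 6)
    sum(s$power[s$freqs > lo & s$freqs <= hi])
  }, numeric(1))
  data.frame(center_hz = centers, octaves = log2(centers / ref), energy = energy)
}

#' One-third-octave spectral slope (dB/octave)
#'
#' Ordinary least squares of `10*log10(energy)` on octaves relative to the
#' reference frequency, fitted only on bands whose energy remained positive
#' after spectral subtraction. With fewer than two positive bands the slope
#' cannot be estimated and the call is flagged for discard from the slope
#' analysis. A tilt *flattening* is an increase of the slope toward 0.
#'
#' @param bands Band table from [third_octave_energies()].
#' @return List: `slope` (dB/octave, NA when undefined), `n_positive_bands`,
#'   `discard_reason` (NA or explanation).
#' @export
octave_slope <- function(bands) {
  pos <- bands[bands$energy > 0, , drop = FALSE]
  if (nrow(pos) < 2L)
    return(list(slope = NA_real_, n_positive_bands = nrow(pos),
                discard_reason = "fewer than 2 positive band energies"))
  fit <- stats::lm.fit(cbind(1, pos$octaves), 10 * log10(pos$energy))
  list(slope = unname(fit$coefficients[2]), n_positive_bands = nrow(pos),
       discard_reason = NA_character_)
}

#' R14 spectral band-energy ratio (dB)
#'
#' Ratio of the (signed) spectral energy in (0.4, 1] kHz to that in
#' (1, 4] kHz, in dB; energies below 400 Hz are excluded because the call f0
#' sits near that frequency and masking noise corrupts the band below it.
#' Undefined (with a reason) when either band energy is non-positive after
#' spectral subtraction. A tilt flattening shows as a *decrease* of R14.
#'
#' @param s A `pv_power_spectrum` (typically after [spectral_subtract()]).
#' @return List: `r14` (dB or NA), `e_low`, `e_high` (linear band energies),
#'   `discard_reason`.
#' @export
r14 <- function(s) {
  e1 <- sum(s$power[s$freqs > 400 & s$freqs <= 1000])
  e2 <- sum(s$power[s$freqs > 1000 & s$freqs <= 4000])
  if (e1 <= 0 || e2 <= 0)
    return(list(r14 = NA_real_, e_low = e1, e_high = e2,
                discard_reason = "non-positive band energy"))
  list(r14 = 10 * log10(e1 / e2), e_low = e1, e_high = e2,
       discard_reason = NA_character_)
}

#' Both spectral-tilt measures for one subtracted spectrum
#'
#' @param s A signed `pv_power_spectrum` after [spectral_subtract()].
#' @param ... Passed to [third_octave_energies()].
#' @return List: `octave_slope`, `r14`, `n_positive_bands`,
#'   `discard_reason` (NA, or the first applicable reason).
#' @export
tilt_measures <- function(s, ...) {
  sl <- octave_slope(third_octave_energies(s, ...))
  rr <- r14(s)
  list(octave_slope = sl$slope, r14 = rr$r14,
       n_positive_bands = sl$n_positive_bands,
       discard_reason = if (!is.na(sl$discard_reason)) sl$discard_reason
                        else rr$discard_reason)
}
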