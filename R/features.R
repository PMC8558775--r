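#' Extract the per-call feature table for one session
#'
#' Runs the full per-session measurement chain: estimate and apply the
#' session gain, cut call clips with matched noise context, screen calls
#' (clipping, overlap, extraneous noise, trackability), track pitch, and
#' compute noise-compensated intensity, SNR and both spectral-tilt measures
#' from the spectral-subtracted average spectrum. Pitch/intensity/tilt
#' columns are filled for every call; the `clean` flag marks which calls the
#' amplitude and f0 analyses may use (rate and duration analyses use all
#' calls).
#'
#' @param session Session [waveform()].
#' @param noise_only Matched noise-only [waveform()].
#' @param annotations Annotation data.frame for the session.
#' @param design Session design (block intervals and conditions).
#' @param settings A [pitch_settings()].
#' @param n_fft,hop FFT framing for the average spectra.
#' @param compensate_gain Estimate and undo the session gain first (needs
#'   non-vocal audio in the low and high blocks).
#' @return data.frame, one row per call: identity columns, screening flags,
#'   `duration_s`, `f0_median_hz`, `f0_mean_hz`, `voiced_fraction`,
#'   `intensity_linear`, `noise_intensity_linear`, `snr_db`,
#'   `octave_slope_db_per_oct`, `r14_db`, `discard_reason`, `session_gain`,
#'   and any `true_*` ground-truth columns present in the annotations.
#' @export
extract_call_features <- function(session, noise_only, annotations, design,
                                  settings = pitch_settings(),
                                  n_fft = 512L, hop = 256L,
                                  compensate_gain = TRUE) {
  if (nrow(annotations) == 0) return(empty_features())
  session_gain <- 1
  if (compensate_gain) {
    g <- estimate_session_gain(session, noise_only, annotations, design)
    session_gain <- g$session_gain
    session <- apply_gain_compensation(session, session_gain)
  }
  clips <- cut_clips(session, noise_only, annotations)
  tracks <- lapply(clips, function(cl) track_pitch(cl$wave, settings))
  scr <- screen_calls(clips, settings, tracks = tracks)
  audit <- scr$audit

  n <- length(clips)
  feat <- vector("list", n)
  for (i in seq_len(n)) {
    cl <- clips[[i]]
    f0 <- call_f0_summary(tracks[[i]])
    inten <- call_intensity(cl$wave, cl$context_noise)
    tilt <- list(octave_slope = NA_real_, r14 = NA_real_,
                 discard_reason = "clip shorter than one FFT frame")
    if (length(cl$wave$samples) >= n_fft) {
      ps_call <- average_power_spectrum(cl$wave, n_fft, hop)
      ps_noise <- average_power_spectrum(cl$context_noise, n_fft, hop)
      tilt <- tilt_measures(spectral_subtract(ps_call, ps_noise))
    }
    feat[[i]] <- data.frame(
      duration_s = cl$annotation$offset_s - cl$annotation$onset_s,
      f0_median_hz = f0$f0_median, f0_mean_hz = f0$f0_mean,
      voiced_fraction = f0$voiced_fraction,
      intensity_linear = inten$call_intensity,
      noise_intensity_linear = inten$noise_intensity,
      snr_db = inten$snr_db,
      octave_slope_db_per_oct = tilt$octave_slope,
      r14_db = tilt$r14,
      discard_reason = if (is.na(tilt$discard_reason)) NA_character_ else tilt$discard_reason,
      stringsAsFactors = FALSE)
  }
  out <- cbind(audit, do.call(rbind, feat))
  out$session_gain <- session_gain
  rownames(out) <- NULL
  out
}

empty_features <- function() {
  data.frame(session_id = character(), seal_id = character(),
             condition = character(), trial_index = integer(),
             onset_s = numeric(), offset_s = numeric(),
             extraneous_noise = logical(), clipped = logical(),
             overlapped = logical(), untrackable = logical(),
             clean = logical(), duration_s = numeric(),
             f0_median_hz = numeric(), f0_mean_hz = numeric(),
             voiced_fraction = numeric(), intensity_linear = numeric(),
             noise_intensity_linear = numeric(), snr_db = numeric(),
             octave_slope_db_per_oct = numeric(), r14_db = numeric(),
             discard_reason = character(), session_gain = numeric(),
             stringsAsFactors = FALSE)
}

#' Simulate an ensemble of calls mixed over condition noise beds
#'
#' Convenience generator for estimator studies: `n` calls of one condition,
#' each rendered and added onto its own freshly synthesized noise bed of the
#' same condition, with the matched noise-only bed kept as context. This is
#' the study design in miniature — known ground truth per call, masking noise
#' of the right band and level — without full-session bookkeeping.
#'
#' @param condition Noise condition for both calls and beds.
#' @param n Number of calls.
#' @param params A [synth_call_params()].
#' @param seed Integer seed (per-call child seeds are derived).
#' @param sample_rate Sampling rate in Hz.
#' @param cal A [calibration()] object.
#' @param pad_s Noise padding around each call in seconds.
#' @return List of clips (as in [cut_clips()]: `annotation`, `wave`,
#'   `context_noise`) plus a `truth` data.frame (`true_f0_base_hz`,
#'   `true_f0_median_hz`, `true_duration_s`, `true_spl_db`,
#'   `true_tilt_db_per_oct`).
#' @export
simulate_call_ensemble <- function(condition, n, params = synth_call_params(),
                                   seed = 1L, sample_rate = 16000,
                                   cal = calibration(), pad_s = 0.1) {
  clips <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    cl <- synth_call(params, condition, seed = derive_seed(seed, 29L, i),
                     sample_rate = sample_rate, cal = cal)
    n_call <- length(cl$wave$samples)
    n_pad <- round(pad_s * sample_rate)
    bed <- synth_noise(condition, (n_call + 2L * n_pad) / sample_rate,
                       sample_rate, cal, seed = derive_seed(seed, 31L, i))
    mix <- bed$samples
    idx <- (n_pad + 1L):(n_pad + n_call)
    mix[idx] <- mix[idx] + cl$wave$samples
    ann <- data.frame(session_id = "ENS", seal_id = "A", condition = condition,
                      trial_index = i,
                      onset_s = n_pad / sample_rate,
                      offset_s = (n_pad + n_call) / sample_rate,
                      extraneous_noise = FALSE, stringsAsFactors = FALSE)
    clips[[i]] <- list(annotation = ann,
                       wave = waveform(mix[idx], sample_rate),
                       context_noise = waveform(bed$samples[idx], sample_rate))
    truth[[i]] <- data.frame(true_f0_base_hz = cl$f0_base,
                             true_f0_median_hz = stats::median(cl$f0_contour$f0_hz),
                             true_duration_s = cl$duration_s,
                             true_spl_db = cl$spl_db,
                             true_tilt_db_per_oct = cl$tilt_db_per_oct)
  }
  list(clips = clips, truth = do.call(rbind, truth))
}
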