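#' Sampled audio waveform
#'
#' Lightweight container for mono audio: a numeric sample vector in
#' full-scale units (|x| <= 1 for generated audio) plus a sample rate.
#'
#' @param samples Numeric vector of amplitudes.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @return An object of class `pv_waveform`.
#' @export
waveform <- function(samples, sample_rate) {
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a single positive number")
  if (!is.numeric(samples)) stop("samples must be numeric")
  if (anyNA(samples) || any(!is.finite(samples))) stop("samples must be finite")
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate),
            class = "pv_waveform")
}

#' @export
print.pv_waveform <- function(x, ...) {
  cat(sprintf("<pv_waveform> %d samples @ %g Hz (%.3f s), peak %.4f\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate,
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

#' @export
length.pv_waveform <- function(x) length(x$samples)

#' Duration of a waveform in seconds
#' @param w A [waveform()].
#' @return Duration in seconds.
#' @export
wave_duration <- function(w) length(w$samples) / w$sample_rate

#' Extract a time interval from a waveform
#'
#' Intervals are half-open `[onset, offset)` in seconds from the start of the
#' waveform, matching the annotation convention.
#'
#' @param w A [waveform()].
#' @param onset_s,offset_s Interval bounds in seconds, `offset_s > onset_s`.
#' @return A [waveform()] holding the interval.
#' @export
wave_slice <- function(w, onset_s, offset_s) {
  stopifnot(offset_s > onset_s, onset_s >= 0)
  i0 <- floor(onset_s * w$sample_rate) + 1L
  i1 <- floor(offset_s * w$sample_rate)
  if (i1 > length(w$samples))
    stop("interval extends past end of waveform")
  waveform(w$samples[i0:i1], w$sample_rate)
}

# Deterministic child seed derivation: one session-level seed fans out to
# per-block / per-call streams without overlap. Kept below 2^31 - 1.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  x <- as.double(seed) %% 2147483647
  for (k in idx) {
    x <- (x * 69069 + 12345 + 97911 * as.double(k)) %% 2147483647
  }
  as.integer(x)
}
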