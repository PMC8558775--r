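#' Digital SPL calibration convention
#'
#' All audio in pupvox lives on a full-scale digital amplitude axis. A
#' calibration convention declares which sound pressure level (dB SPL)
#' corresponds to a digital RMS of 1.0, so that levels such as "65 dB SPL"
#' can be realized and measured digitally.
#'
#' The default of 100 dB SPL at digital RMS 1.0 leaves more than 20 dB of
#' headroom above the default 75 dB SPL call level, so mixed sessions never
#' approach full scale.
#'
#' @param cal_db Sound pressure level (dB SPL) assigned to a digital RMS
#'   amplitude of 1.0. Must be finite.
#' @return An object of class `pv_calibration`.
#' @examples
#' cal <- calibration()
#' spl_to_rms(65, cal)
#' @export
calibration <- function(cal_db = 100) {
  if (!is.numeric(cal_db) || length(cal_db) != 1L || !is.finite(cal_db))
    stop("cal_db must be a single finite number")
  structure(list(cal_db = cal_db), class = "pv_calibration")
}

#' @export
print.pv_calibration <- function(x, ...) {
  cat(sprintf("<pv_calibration> digital RMS 1.0 == %.1f dB SPL\n", x$cal_db))
  invisible(x)
}

#' Convert a sound pressure level to a digital RMS amplitude
#'
#' @param level Level in dB SPL. Must not exceed `cal$cal_db` (a level above
#'   the calibration point would demand RMS > 1, i.e. clipped audio).
#' @param cal A [calibration()] object.
#' @return Linear RMS amplitude in full-scale units.
#' @seealso [rms_to_spl()]
#' @export
spl_to_rms <- function(level, cal = calibration()) {
  stopifnot(inherits(cal, "pv_calibration"), is.numeric(level))
  if (any(level > cal$cal_db))
    stop(sprintf("calibration overflow: level %.2f dB SPL exceeds cal_db %.2f",
                 max(level), cal$cal_db))
  10^((level - cal$cal_db) / 20)
}

#' Convert a digital RMS amplitude to a sound pressure level
#'
#' Inverse of [spl_to_rms()]; the round trip is exact to well below 1e-9 dB.
#'
#' @param rms Linear RMS amplitude (> 0).
#' @param cal A [calibration()] object.
#' @return Level in dB SPL.
#' @export
rms_to_spl <- function(rms, cal = calibration()) {
  stopifnot(inherits(cal, "pv_calibration"), is.numeric(rms), all(rms > 0))
  cal$cal_db + 20 * log10(rms)
}

#' Measure the SPL of a waveform
#'
#' @param w A [waveform()].
#' @param cal A [calibration()] object.
#' @return Measured level in dB SPL of the whole waveform.
#' @export
measure_spl <- function(w, cal = calibration()) {
  rms_to_spl(sqrt(mean(w$samples^2)), cal)
}
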