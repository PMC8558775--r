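#' Pitch tracker settings
#'
#' Settings for the normalized-autocorrelation pitch tracker. The analysis
#' values used throughout the pipeline are a 0.01 s time step with a 200 Hz
#' floor and an 800 Hz ceiling (the pup f0 search range); the remaining
#' knobs follow the classical autocorrelation tracker design: analysis
#' window of 3 floor-periods, Hann weighting with correction by the window's
#' own autocorrelation, voicing decided against `voicing_threshold` with a
#' silence gate, and a Viterbi path over candidates trading octave errors
#' (`octave_cost`) against pitch jumps (`jump_cost`).
#'
#' @param time_step Frame step in seconds.
#' @param floor,ceiling Pitch search range in Hz; `0 < floor < ceiling`.
#' @param voicing_threshold Minimum normalized autocorrelation for voicing.
#' @param silence_threshold Local peak (relative to the global peak) below
#'   which frames are treated as silent.
#' @param octave_cost Per-octave preference for higher candidates (guards
#'   against octave-down errors).
#' @param jump_cost Per-octave cost of pitch movement between frames.
#' @param voiced_unvoiced_cost Cost of a voicing transition.
#' @param max_candidates Voiced candidates kept per frame.
#' @return A `pv_pitch_settings` list.
#' @export
pitch_settings <- function(time_step = 0.01, floor = 200, ceiling = 800,
                           voicing_threshold = 0.45, silence_threshold = 0.03,
                           octave_cost = 0.01, jump_cost = 0.35,
                           voiced_unvoiced_cost = 0.14, max_candidates = 4L) {
  stopifnot(time_step > 0, floor > 0, ceiling > floor)
  structure(list(time_step = time_step, floor = floor, ceiling = ceiling,
                 voicing_threshold = voicing_threshold,
                 silence_threshold = silence_threshold,
                 octave_cost = octave_cost, jump_cost = jump_cost,
                 voiced_unvoiced_cost = voiced_unvoiced_cost,
                 max_candidates = as.integer(max_candidates)),
            class = "pv_pitch_settings")
}

#' Track fundamental frequency by normalized autocorrelation
#'
#' Frames are Hann-windowed and mean-subtracted; the frame autocorrelation is
#' normalized and divided by the window's own autocorrelation, which unbiases
#' the estimate at non-zero lags. Local maxima in the lag range
#' `[1/ceiling, 1/floor]` become voiced candidates after parabolic peak
#' interpolation; an unvoiced candidate competes through the voicing and
#' silence thresholds; a Viterbi pass picks the lowest-cost path.
#'
#' @param w A [waveform()]; `ceiling` must be below Nyquist.
#' @param s A [pitch_settings()].
#' @return A `pv_pitch_track` data.frame with columns `time_s`, `f0_hz`
#'   (NA when unvoiced) and `strength`. Empty (with a warning) when the input
#'   is shorter than one analysis window.
#' @export
track_pitch <- function(w, s = pitch_settings()) {
  fs <- w$sample_rate
  stopifnot(s$ceiling < fs / 2)
  x <- w$samples
  n_w <- round(3 / s$floor * fs)            # window = 3 periods of the floor
  if (length(x) < n_w) {
    warning("input shorter than one analysis window; empty pitch track")
    return(empty_track())
  }
  hop <- s$time_step * fs
  centers <- seq(n_w / 2, length(x) - n_w / 2, by = hop)
  n_frames <- length(centers)
  if (n_frames == 0) return(empty_track())

  starts <- round(centers - n_w / 2)
  idx <- outer(seq_len(n_w) - 1L, starts, `+`) + 1L
  frames <- matrix(x[idx], nrow = n_w)
  frames <- sweep(frames, 2, colMeans(frames))
  local_peak <- apply(abs(frames), 2, max)
  global_peak <- max(abs(x - mean(x)))

  win <- 0.5 * (1 - cos(2 * pi * (seq_len(n_w) - 1) / (n_w - 1)))
  wf <- frames * win

  nfft <- 2^ceiling(log2(2L * n_w))
  lmin <- max(floor(fs / s$ceiling), 2L)
  lmax <- min(ceiling(fs / s$floor), n_w - 2L)

  # frame autocorrelations via FFT, normalized at lag 0
  padded <- rbind(wf, matrix(0, nfft - n_w, n_frames))
  spec <- stats::mvfft(padded)
  ac <- Re(stats::mvfft(spec * Conj(spec), inverse = TRUE))
  r0 <- ac[1L, ]
  r0[r0 <= 0] <- Inf
  r <- sweep(ac[seq_len(lmax + 2L), , drop = FALSE], 2, r0, `/`)
  # window autocorrelation correction
  wpad <- c(win, numeric(nfft - n_w))
  wsp <- stats::fft(wpad)
  wac <- Re(stats::fft(wsp * Conj(wsp), inverse = TRUE))
  wac <- wac[seq_len(lmax + 2L)] / wac[1L]
  r <- r / wac

  silence_gate <- s$silence_threshold / (1 + s$voicing_threshold)

  time_s <- centers / fs
  f0 <- rep(NA_real_, n_frames)
  strength <- numeric(n_frames)
  cand_f <- vector("list", n_frames)
  cand_s <- vector("list", n_frames)
  for (j in seq_len(n_frames)) {
    rv <- r[, j]
    lags <- lmin:lmax
    v <- rv[lags + 1L]
    is_peak <- v > rv[lags] & v >= rv[lags + 2L]
    pk <- lags[is_peak]
    fi <- numeric(0); si <- numeric(0)
    if (length(pk)) {
      a <- rv[pk]; b <- rv[pk + 1L]; cc <- rv[pk + 2L]
      den <- a - 2 * b + cc
      delta <- ifelse(abs(den) > 1e-12, 0.5 * (a - cc) / den, 0)
      delta <- pmin(pmax(delta, -0.5), 0.5)
      lag_star <- pk + delta
      s_star <- pmin(b - 0.25 * (a - cc) * delta, 1)
      fi <- fs / lag_star
      keep <- fi >= s$floor & fi <= s$ceiling & s_star > 0
      fi <- fi[keep]; s_star <- s_star[keep]
      if (length(fi) > s$max_candidates) {
        o <- order(s_star, decreasing = TRUE)[seq_len(s$max_candidates)]
        fi <- fi[o]; s_star <- s_star[o]
      }
      si <- s_star
    }
    # voiced candidate scores (octave bias) + unvoiced candidate
    sc <- if (length(fi)) si - s$octave_cost * log2(s$ceiling / fi) else numeric(0)
    unvoiced_score <- s$voicing_threshold +
      max(0, 2 - (local_peak[j] / max(global_peak, .Machine$double.eps)) / silence_gate)
    cand_f[[j]] <- c(fi, NA_real_)
    cand_s[[j]] <- c(sc, unvoiced_score)
  }

  # Viterbi over candidates: maximize sum of scores minus transition costs
  prev_delta <- cand_s[[1L]]
  back <- vector("list", n_frames)
  for (j in seq_len(n_frames)[-1L]) {
    fj <- cand_f[[j]]; fp <- cand_f[[j - 1L]]
    nj <- length(fj); np <- length(fp)
    trans <- matrix(0, np, nj)
    for (a in seq_len(np)) for (b in seq_len(nj)) {
      va <- !is.na(fp[a]); vb <- !is.na(fj[b])
      trans[a, b] <- if (va && vb) s$jump_cost * abs(log2(fp[a] / fj[b]))
                     else if (va != vb) s$voiced_unvoiced_cost else 0
    }
    tot <- prev_delta - trans                      # np x nj
    best_prev <- max.col(t(tot), ties.method = "first")
    prev_delta <- cand_s[[j]] + tot[cbind(best_prev, seq_len(nj))]
    back[[j]] <- best_prev
  }
  path <- integer(n_frames)
  path[n_frames] <- which.max(prev_delta)
  for (j in rev(seq_len(n_frames)[-1L])) path[j - 1L] <- back[[j]][path[j]]
  for (j in seq_len(n_frames)) {
    f0[j] <- cand_f[[j]][path[j]]
    strength[j] <- cand_s[[j]][path[j]]
  }

  out <- data.frame(time_s = time_s, f0_hz = f0, strength = strength)
  class(out) <- c("pv_pitch_track", "data.frame")
  out
}

empty_track <- function() {
  out <- data.frame(time_s = numeric(), f0_hz = numeric(), strength = numeric())
  class(out) <- c("pv_pitch_track", "data.frame")
  out
}

#' Per-call f0 summary
#'
#' Location statistics over voiced frames only. The per-call statistic used
#' downstream is the median (robust to occasional tracker outliers); the mean
#' is reported alongside. With no voiced frames the summary is undefined and
#' the call should be flagged untrackable.
#'
#' @param track A pitch track from [track_pitch()].
#' @return List: `f0_median`, `f0_mean` (Hz; NA when no voiced frame),
#'   `voiced_fraction`.
#' @export
call_f0_summary <- function(track) {
  voiced <- track$f0_hz[!is.na(track$f0_hz)]
  n <- nrow(track)
  list(f0_median = if (length(voiced)) stats::median(voiced) else NA_real_,
       f0_mean = if (length(voiced)) mean(voiced) else NA_real_,
       voiced_fraction = if (n > 0) length(voiced) / n else 0)
}

#' Export a pitch track as delimiter-separated text
#'
#' Columns `time_s`, `f0_hz`, `strength`; unvoiced frames have an empty
#' `f0_hz` field.
#'
#' @param path Output path.
#' @param track A pitch track.
#' @export
write_pitch_track <- function(path, track) {
  utils::write.table(track, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
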