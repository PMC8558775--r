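#' Read / write call annotation tables
#'
#' Annotations are tab-separated text with a header row. Required columns:
#' `session_id`, `seal_id`, `condition`, `trial_index`, `onset_s`,
#' `offset_s`; a logical `extraneous_noise` flag and ground-truth columns
#' prefixed `true_` are carried through when present. Intervals are half-open
#' `[onset, offset)` in 0-based seconds from session start.
#'
#' @param path File path.
#' @return data.frame of annotations.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("session_id", "seal_id", "condition", "trial_index", "onset_s", "offset_s")
  miss <- setdiff(req, names(ann))
  if (length(miss)) stop("annotation table missing columns: ", paste(miss, collapse = ", "))
  if (any(ann$offset_s <= ann$onset_s)) stop("annotations with offset_s <= onset_s")
  if (!all(ann$condition %in% CONDITIONS))
    stop("unknown condition labels: ",
         paste(setdiff(unique(ann$condition), CONDITIONS), collapse = ", "))
  if (is.null(ann$extraneous_noise)) ann$extraneous_noise <- FALSE
  ann
}

#' @rdname read_annotations
#' @param ann Annotation data.frame.
#' @export
write_annotations <- function(path, ann) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Detect amplitude clipping
#'
#' A waveform counts as clipped when it contains at least `min_run`
#' consecutive samples at or above `threshold` in absolute value — the
#' flat-topped runs a hard limiter produces. Isolated full-scale samples are
#' not clipping.
#'
#' @param w A [waveform()].
#' @param threshold Amplitude threshold as a fraction of full scale.
#' @param min_run Minimum run length in samples.
#' @return Logical scalar.
#' @export
detect_clipping <- function(w, threshold = 0.999, min_run = 3L) {
  hit <- abs(w$samples) >= threshold
  if (!any(hit)) return(FALSE)
  r <- rle(hit)
  any(r$values & r$lengths >= min_run)
}

#' Detect temporal overlap with calls of other individuals
#'
#' Intervals are half-open, so a call ending exactly where another starts
#' does not overlap it. Only calls of a *different* `seal_id` in the same
#' session count.
#'
#' @param a One annotation row (data.frame or list with `session_id`,
#'   `seal_id`, `onset_s`, `offset_s`).
#' @param others Annotation data.frame to test against (may include `a`).
#' @return Logical scalar.
#' @export
detect_overlap <- function(a, others) {
  if (nrow(others) == 0) return(FALSE)
  o <- others[others$session_id == a$session_id & others$seal_id != a$seal_id, , drop = FALSE]
  if (nrow(o) == 0) return(FALSE)
  any(a$onset_s < o$offset_s & o$onset_s < a$offset_s)
}

#' Cut call clips with matched noise context
#'
#' For each annotation, extracts the annotated interval from the session
#' waveform and the identical interval from the noise-only rendering.
#'
#' @param session A [waveform()] of the full session.
#' @param noise_only The matched noise-only [waveform()] (same length and
#'   sample rate).
#' @param annotations Annotation data.frame.
#' @return List of clips; each clip is a list with `annotation` (one-row
#'   data.frame), `wave` and `context_noise` ([waveform()]s of equal length).
#' @export
cut_clips <- function(session, noise_only, annotations) {
  stopifnot(length(session$samples) == length(noise_only$samples),
            session$sample_rate == noise_only$sample_rate)
  lapply(seq_len(nrow(annotations)), function(i) {
    a <- annotations[i, , drop = FALSE]
    list(annotation = a,
         wave = wave_slice(session, a$onset_s, a$offset_s),
         context_noise = wave_slice(noise_only, a$onset_s, a$offset_s))
  })
}

#' Screen calls by the four exclusion criteria
#'
#' Applies the call-screening rules used for amplitude and f0 analyses:
#' (1) not clipped, (2) not overlapping a call of another individual,
#' (3) free of extraneous (non-playback) noise, and (4) trackable by the
#' pitch tracker. Criteria 1, 2 and 4 are computed automatically; criterion 3
#' is honoured via the `extraneous_noise` flag supplied with the annotations
#' (human judgement on real data, always `FALSE` on synthetic fixtures).
#' Untrackable means a voiced fraction below `voiced_min` of pitch frames.
#'
#' Rate and duration analyses intentionally keep the full call set; only
#' amplitude/f0 analyses use the clean subset.
#'
#' @param clips List of clips from [cut_clips()].
#' @param settings A [pitch_settings()] used for the trackability check.
#' @param voiced_min Minimum voiced fraction for criterion 4.
#' @param tracks Optional precomputed list of pitch tracks (one per clip), to
#'   avoid tracking twice when the caller also needs f0.
#' @return List: `audit` — the annotation table with logical columns
#'   `clipped`, `overlapped`, `extraneous_noise`, `untrackable`, `clean`;
#'   `clean` — the clean subset of clip indices; `counts` — named exclusion
#'   counts per criterion (a call may fail several).
#' @export
screen_calls <- function(clips, settings = pitch_settings(), voiced_min = 0.5,
                         tracks = NULL) {
  n <- length(clips)
  ann <- do.call(rbind, lapply(clips, `[[`, "annotation"))
  all_ann <- ann
  clipped <- logical(n); overlapped <- logical(n); untrack <- logical(n)
  for (i in seq_len(n)) {
    clipped[i] <- detect_clipping(clips[[i]]$wave)
    overlapped[i] <- detect_overlap(ann[i, ], all_ann)
    tr <- if (!is.null(tracks)) tracks[[i]] else track_pitch(clips[[i]]$wave, settings)
    vf <- if (nrow(tr)) mean(!is.na(tr$f0_hz)) else 0
    untrack[i] <- vf < voiced_min
  }
  extr <- if (!is.null(ann$extraneous_noise)) as.logical(ann$extraneous_noise) else rep(FALSE, n)
  audit <- ann
  audit$clipped <- clipped
  audit$overlapped <- overlapped
  audit$extraneous_noise <- extr
  audit$untrackable <- untrack
  audit$clean <- !(clipped | overlapped | extr | untrack)
  rownames(audit) <- NULL
  list(audit = audit,
       clean = which(audit$clean),
       counts = c(clipped = sum(clipped), overlapped = sum(overlapped),
                  extraneous_noise = sum(extr), untrackable = sum(untrack),
                  clean = sum(audit$clean), total = n))
}
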