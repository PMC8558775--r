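#' Pipeline run configuration
#'
#' Bundles every knob of the end-to-end run. Defaults mirror the study
#' design at desk scale: 14 sessions of nine randomized blocks (two housed
#' seals per session, sessions grouped into pairs of seals, i.e. seven
#' sessions per pair), 30 s blocks standing in for the 5-min playback blocks
#' (pass `block_duration_s = 300` for the full design), and the default
#' synthesis, pitch and statistical settings.
#'
#' @param out_dir Artifact directory (created if missing).
#' @param n_sessions Number of sessions to simulate.
#' @param seals_per_session Seals housed (and vocalizing) per session.
#' @param sessions_per_pair Sessions recorded from one housed pair before
#'   moving to the next pair of seals.
#' @param block_duration_s Block duration in seconds (scalar or length 9).
#' @param mean_calls_per_block Poisson mean of calls per block.
#' @param sample_rate Sampling rate in Hz.
#' @param params A [synth_call_params()].
#' @param cal A [calibration()].
#' @param pitch A [pitch_settings()].
#' @param n_perm Permutations for every test.
#' @param gain_range Range of the random per-session preamplifier amplitude
#'   factor (uniform draw; the analysis must undo it).
#' @param seed Global integer seed; all stage seeds derive from it.
#' @return A `pv_run_config` list.
#' @export
run_config <- function(out_dir = tempfile("pupvox_run_"),
                       n_sessions = 14L, seals_per_session = 2L,
                       sessions_per_pair = 7L,
                       block_duration_s = 30, mean_calls_per_block = 4,
                       sample_rate = 16000, params = synth_call_params(),
                       cal = calibration(), pitch = pitch_settings(),
                       n_perm = 1000L, gain_range = c(0.7, 1.4), seed = 1L) {
  structure(list(out_dir = out_dir, n_sessions = as.integer(n_sessions),
                 seals_per_session = as.integer(seals_per_session),
                 sessions_per_pair = as.integer(sessions_per_pair),
                 block_duration_s = block_duration_s,
                 mean_calls_per_block = mean_calls_per_block,
                 sample_rate = sample_rate, params = params, cal = cal,
                 pitch = pitch, n_perm = as.integer(n_perm),
                 gain_range = gain_range, seed = as.integer(seed)),
            class = "pv_run_config")
}

log_line <- function(config, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
  cat(line, "\n", file = file.path(config$out_dir, "run.log"), append = TRUE)
  invisible(line)
}

session_ids <- function(config) sprintf("S%02d", seq_len(config$n_sessions))

session_seals <- function(config, s) {
  pair <- (s - 1L) %/% config$sessions_per_pair
  LETTERS[pair * config$seals_per_session + seq_len(config$seals_per_session)]
}

#' Stage 1: generate synthetic sessions
#'
#' Writes, per session, `audio/<id>.wav` (the recorded mix, with a random
#' per-session preamplifier gain), `audio/<id>_noise.wav` (the matched
#' noise-only rendering at reference gain), the block design, and the
#' annotation table with ground truth. Every derived seed is logged.
#'
#' @param config A [run_config()].
#' @return Invisibly, the vector of session ids.
#' @export
stage_generate <- function(config) {
  dir.create(file.path(config$out_dir, "audio"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(config$out_dir, "tables"), recursive = TRUE, showWarnings = FALSE)
  ids <- session_ids(config)
  for (s in seq_along(ids)) {
    sid <- ids[s]
    seed_s <- derive_seed(config$seed, 101L, s)
    design <- make_session_design(config$block_duration_s, seed = seed_s)
    sched <- schedule_calls(design, config$params, seed = seed_s,
                            mean_calls_per_block = config$mean_calls_per_block,
                            seal_ids = session_seals(config, s))
    amp <- rng_local(derive_seed(seed_s, 3L),
                     stats::runif(1, config$gain_range[1], config$gain_range[2]))
    asm <- assemble_session(design, config$params, sched, config$cal,
                            seed = seed_s, sample_rate = config$sample_rate,
                            session_id = sid, gain = amp)
    write_wav(file.path(config$out_dir, "audio", paste0(sid, ".wav")), asm$session)
    write_wav(file.path(config$out_dir, "audio", paste0(sid, "_noise.wav")), asm$noise_only)
    utils::write.table(design, file.path(config$out_dir, "tables", paste0(sid, "_design.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_annotations(file.path(config$out_dir, "tables", paste0(sid, "_annotations.tsv")),
                      asm$annotations)
    log_line(config, "generate %s: seed=%d gain=%.4f calls=%d", sid, seed_s,
             amp^2, nrow(asm$annotations))
  }
  invisible(ids)
}

#' Stage 2: extract per-call features from persisted audio
#'
#' Reads each session's audio, noise-only rendering, design and annotations
#' back from the artifact directory and runs [extract_call_features()];
#' writes `tables/features.tsv`.
#'
#' @param config A [run_config()].
#' @return Invisibly, the feature data.frame.
#' @export
stage_features <- function(config) {
  ids <- session_ids(config)
  feats <- vector("list", length(ids))
  for (s in seq_along(ids)) {
    sid <- ids[s]
    session <- read_wav(file.path(config$out_dir, "audio", paste0(sid, ".wav")))
    noise <- read_wav(file.path(config$out_dir, "audio", paste0(sid, "_noise.wav")))
    design <- utils::read.delim(file.path(config$out_dir, "tables",
                                          paste0(sid, "_design.tsv")))
    ann <- read_annotations(file.path(config$out_dir, "tables",
                                      paste0(sid, "_annotations.tsv")))
    feats[[s]] <- tryCatch(
      extract_call_features(session, noise, ann, design, config$pitch),
      error = function(e) stop("feature stage failed for session ", sid, ": ",
                               conditionMessage(e)))
    log_line(config, "features %s: %d calls, %d clean", sid,
             nrow(feats[[s]]), sum(feats[[s]]$clean))
  }
  features <- do.call(rbind, feats)
  utils::write.table(format_num(features),
                     file.path(config$out_dir, "tables", "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(features)
}

# fixed-precision formatting so stage outputs are byte-stable across runs
format_num <- function(df) {
  for (j in seq_along(df)) if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
    df[[j]] <- formatC(df[[j]], digits = 10, format = "g")
  df
}

#' Stage 3: statistical analysis of the feature table
#'
#' Reproduces the study's inference layer on the extracted features: call
#' rate and duration on all calls; f0 on the clean subset (main effect plus
#' the three pairwise comparisons, permutation-tested at 0.05 and 0.05/3);
#' coefficient-of-variation analyses for duration and f0; per-seal
#' Mann-Whitney tests of intensity and tilt at 0.05/(3 * seals). Writes
#' `tables/results.tsv` and `tables/per_seal_results.tsv`. With too few
#' calls the stage writes a note instead of failing.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of result tables.
#' @export
stage_stats <- function(config) {
  path <- file.path(config$out_dir, "tables", "features.tsv")
  features <- utils::read.delim(path, stringsAsFactors = FALSE)
  np <- config$n_perm
  seed <- derive_seed(config$seed, 103L)

  if (nrow(features) < 10 || length(unique(features$condition)) < 2) {
    note <- data.frame(comparison = "none", response = "none",
                       statistic = NA_real_, p_perm = NA_real_,
                       pseudo_r2 = NA_real_, n = nrow(features),
                       alpha_adjusted = NA_real_, significant = NA,
                       stringsAsFactors = FALSE)
    utils::write.table(note, file.path(config$out_dir, "tables", "results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_line(config, "stats: insufficient data (%d calls)", nrow(features))
    return(invisible(list(results = note, note = "insufficient data")))
  }

  res <- list()
  rate_tab <- calls_per_group(features)
  res$n_calls_main <- condition_effect_test(rate_tab, "n_calls",
                                            fixed_other = character(0),
                                            n_perm = np, seed = derive_seed(seed, 1L))
  res$duration_main <- condition_effect_test(features, "duration_s",
                                             n_perm = np, seed = derive_seed(seed, 2L))
  clean <- features[features$clean & !is.na(features$f0_median_hz), , drop = FALSE]
  res$f0_main <- condition_effect_test(clean, "f0_median_hz",
                                       n_perm = np, seed = derive_seed(seed, 3L))
  res$f0_pairwise <- pairwise_condition_tests(clean, "f0_median_hz",
                                              n_perm = np, seed = derive_seed(seed, 4L))
  cv_dur <- cv_condition_analysis(features, "duration_s",
                                  n_perm = np, seed = derive_seed(seed, 5L))
  cv_f0 <- cv_condition_analysis(clean, "f0_median_hz",
                                 n_perm = np, seed = derive_seed(seed, 6L))

  results <- rbind(res$n_calls_main, res$duration_main, res$f0_main,
                   res$f0_pairwise,
                   cv_dur$main, cv_dur$pairwise, cv_f0$main, cv_f0$pairwise)
  utils::write.table(format_num(results),
                     file.path(config$out_dir, "tables", "results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  per_seal <- per_seal_intensity_tests(clean)
  utils::write.table(format_num(per_seal),
                     file.path(config$out_dir, "tables", "per_seal_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_line(config, "stats: %d result rows, %d per-seal rows",
           nrow(results), nrow(per_seal))
  invisible(list(results = results, per_seal = per_seal,
                 cv_duration = cv_dur$cv_table, cv_f0 = cv_f0$cv_table))
}

#' Stage 4: recovery report
#'
#' Writes `report.txt`: valid-session count (a session is valid when every
#' housed seal produced at least two calls), per-condition recovery of the
#' generator's ground truth (estimated vs true f0 medians, call SPL vs
#' compensated intensity, SNR), the screening audit, and the rendered result
#' sentences.
#'
#' @param config A [run_config()].
#' @return Invisibly, the report lines.
#' @export
stage_report <- function(config) {
  features <- utils::read.delim(file.path(config$out_dir, "tables", "features.tsv"),
                                stringsAsFactors = FALSE)
  results <- utils::read.delim(file.path(config$out_dir, "tables", "results.tsv"),
                               stringsAsFactors = FALSE)
  lines <- c("pupvox run report", "=================", "")

  if (nrow(features) == 0) {
    lines <- c(lines, "no calls recorded; nothing to report")
    writeLines(lines, file.path(config$out_dir, "report.txt"))
    log_line(config, "report written (no calls)")
    return(invisible(lines))
  }

  ids <- session_ids(config)
  valid <- vapply(seq_along(ids), function(s) {
    seals <- session_seals(config, s)
    counts <- vapply(seals, function(sl)
      sum(features$session_id == ids[s] & features$seal_id == sl), integer(1))
    all(counts >= 2)
  }, logical(1))
  lines <- c(lines, sprintf("sessions: %d; valid sessions (>= 2 calls per pup): %d",
                            length(valid), sum(valid)), "")

  lines <- c(lines, "f0 recovery (clean calls):")
  clean <- features[features$clean & !is.na(features$f0_median_hz), , drop = FALSE]
  for (cond in CONDITIONS) {
    sub <- clean[clean$condition == cond, ]
    if (!nrow(sub)) next
    lines <- c(lines, sprintf(
      "  %-12s est median %6.1f Hz | true median %6.1f Hz | n = %d",
      cond, stats::median(sub$f0_median_hz), stats::median(sub$true_f0_median_hz),
      nrow(sub)))
  }
  lines <- c(lines, "", "intensity / SNR (clean calls with positive intensity):")
  for (cond in CONDITIONS) {
    sub <- clean[clean$condition == cond & !is.na(clean$snr_db), ]
    if (!nrow(sub)) next
    lines <- c(lines, sprintf(
      "  %-12s mean snr %5.1f dB | mean intensity %.3e | n = %d",
      cond, mean(sub$snr_db), mean(sub$intensity_linear), nrow(sub)))
  }
  lines <- c(lines, "", "screening audit:",
             sprintf("  total %d | clean %d | clipped %d | overlapped %d | extraneous %d | untrackable %d",
                     nrow(features), sum(features$clean), sum(features$clipped),
                     sum(features$overlapped), sum(features$extraneous_noise),
                     sum(features$untrackable)),
             "", "statistics:", paste0("  ", render_results_text(results)))
  writeLines(lines, file.path(config$out_dir, "report.txt"))
  log_line(config, "report written")
  invisible(lines)
}

#' Run the full pipeline: generate, features, stats, report
#'
#' Stages communicate only through files in `config$out_dir`, so any stage
#' can be re-run from persisted intermediates with identical results; a
#' fixed seed makes the whole artifact directory reproducible.
#'
#' @param config A [run_config()].
#' @return Invisibly, `config$out_dir`.
#' @export
run_end_to_end <- function(config = run_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_line(config, "run start: seed=%d sessions=%d", config$seed, config$n_sessions)
  stage_generate(config)
  stage_features(config)
  stage_stats(config)
  stage_report(config)
  invisible(config$out_dir)
}
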