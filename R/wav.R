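#' Read a WAV file
#'
#' Minimal RIFF/WAVE reader for the formats this package writes: uncompressed
#' PCM (16-bit integer) and IEEE float32, mono or multichannel (channels are
#' averaged to mono). Float data round-trips bit-exactly; 16-bit PCM maps to
#' amplitudes in [-1, 1).
#'
#' @param path Path to a `.wav` file.
#' @return A [waveform()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")    # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(sz) == 0) stop("truncated WAV file: ", path)
    if (id == "fmt ") {
      body <- readBin(con, "raw", sz)
      if (length(body) < 16) stop("truncated WAV fmt chunk: ", path)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, 2, endian = "little"),
        n_channels   = readBin(body[3:4], "integer", 1, 2, endian = "little"),
        sample_rate  = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(body[15:16], "integer", 1, 2, endian = "little"))
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", sz)
      if (length(data_raw) < sz) stop("truncated WAV data chunk: ", path)
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("truncated or malformed WAV file: ", path)

  if (fmt$audio_format == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", length(data_raw) / 2, 2,
                 signed = TRUE, endian = "little") / 32768
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "numeric", length(data_raw) / 4, 4, endian = "little")
  } else {
    stop(sprintf("unsupported WAV encoding: format tag %d, %d bits",
                 fmt$audio_format, fmt$bits))
  }
  if (fmt$n_channels > 1L) {
    x <- colMeans(matrix(x, nrow = fmt$n_channels))
  }
  waveform(x, fmt$sample_rate)
}

#' Write a WAV file
#'
#' @param path Output path.
#' @param w A [waveform()].
#' @param format `"float32"` (lossless round trip, default) or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(path, w, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  stopifnot(inherits(w, "pv_waveform"))
  n <- length(w$samples)
  bytes_per <- if (format == "float32") 4L else 2L
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))

  w16 <- function(v) writeBin(as.integer(v), con, 2, endian = "little")
  w32 <- function(v) writeBin(as.integer(v), con, 4, endian = "little")

  writeChar("RIFF", con, 4, eos = NULL)
  w32(36L + data_size)
  writeChar("WAVE", con, 4, eos = NULL)
  writeChar("fmt ", con, 4, eos = NULL)
  w32(16L)
  w16(if (format == "float32") 3L else 1L)          # format tag
  w16(1L)                                           # mono
  w32(as.integer(w$sample_rate))
  w32(as.integer(w$sample_rate) * bytes_per)        # byte rate
  w16(bytes_per)                                    # block align
  w16(8L * bytes_per)
  writeChar("data", con, 4, eos = NULL)
  w32(data_size)
  if (format == "float32") {
    writeBin(w$samples, con, 4, endian = "little")
  } else {
    q <- pmin(pmax(round(w$samples * 32768), -32768), 32767)
    writeBin(as.integer(q), con, 2, endian = "little")
  }
  invisible(path)
}
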