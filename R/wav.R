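#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader covering the formats stimuli are exchanged in:
#' 16- or 24-bit integer PCM and 32-bit IEEE float, single channel (the
#' first channel is taken from multi-channel files).
#'
#' @param path file path.
#' @param calibration_spl calibration attached to the returned signal.
#' @return an `audio_signal` with samples scaled to \[-1, 1\].
#' @export
wav_read <- function(path, calibration_spl = 65) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4)
  if (hdr != "RIFF") stop("not a RIFF file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little",
                               signed = FALSE),
        channels = readBin(con, "integer", 1, 2, endian = "little"),
        rate = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, 4, endian = "little"),
        block_align = readBin(con, "integer", 1, 2, endian = "little"),
        bits = readBin(con, "integer", 1, 2, endian = "little"))
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (id == "data") {
      data <- readBin(con, "raw", size)
      break
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
  }
  if (is.null(fmt) || is.null(data)) stop("malformed WAV: missing chunk")
  s <- switch(
    as.character(fmt$bits),
    "16" = readBin(data, "integer", length(data) / 2, 2, signed = TRUE,
                   endian = "little") / 32768,
    "24" = {
      m <- matrix(as.integer(data), nrow = 3)
      v <- m[1, ] + m[2, ] * 256L + m[3, ] * 65536L
      ifelse(v >= 8388608, v - 16777216, v) / 8388608
    },
    "32" = {
      if (fmt$audio_format == 3)
        readBin(data, "double", length(data) / 4, 4, endian = "little")
      else readBin(data, "integer", length(data) / 4, 4,
                   endian = "little") / 2147483648
    },
    stop("unsupported bit depth: ", fmt$bits))
  if (fmt$channels > 1)
    s <- s[seq(1, length(s), by = fmt$channels)]
  audio_signal(s, fmt$rate, calibration_spl = calibration_spl)
}

#' Write a mono WAV file
#'
#' @param x an `audio_signal` (samples clipped to \[-1, 1\]).
#' @param path output path.
#' @param bits 16 (integer PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
wav_write <- function(x, path, bits = 16) {
  stopifnot(inherits(x, "audio_signal"), bits %in% c(16, 32))
  s <- pmin(pmax(x$samples, -1), 1)
  n <- length(s)
  bytes <- bits / 8
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + n * bytes), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(if (bits == 32) 3L else 1L, 1L), con, 2, endian = "little")
  writeBin(as.integer(x$rate), con, 4, endian = "little")
  writeBin(as.integer(x$rate * bytes), con, 4, endian = "little")
  writeBin(c(as.integer(bytes), as.integer(bits)), con, 2,
           endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n * bytes), con, 4, endian = "little")
  if (bits == 16)
    writeBin(as.integer(round(s * 32767)), con, 2, endian = "little")
  else
    writeBin(s, con, 4, endian = "little")
  invisible(path)
}
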