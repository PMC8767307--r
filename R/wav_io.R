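# Minimal RIFF/PCM WAV codec (16-bit mono/first-channel), readBin/writeBin based.

#' Read a PCM WAV file
#'
#' Minimal reader for 16-bit PCM RIFF/WAVE files.  Multi-channel files are
#' reduced to their first channel.  Amplitudes are returned in \[-1, 1\].
#'
#' @param path file path.
#' @return list with `waveform` (numeric) and `sampleRate` (Hz).
#' @export
readWav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  sampleRate <- NULL; nChannels <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, 2, endian = "little", signed = FALSE)
      nChannels <- fmt[2]
      sampleRate <- readBin(con, "integer", 1, 4, endian = "little")
      invisible(readBin(con, "integer", 1, 4, endian = "little")) # byte rate
      invisible(readBin(con, "integer", 1, 2, endian = "little")) # block align
      bits <- readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      if (size > 16L) invisible(readBin(con, "raw", size - 16L))
      if (fmt[1] != 1L) stop("only PCM WAV is supported")
      if (bits != 16L) stop("only 16-bit PCM WAV is supported")
    } else if (identical(id, "data")) {
      samples <- readBin(con, "integer", size %/% 2L, 2, endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
  }
  if (is.null(sampleRate) || is.null(samples))
    stop("malformed WAV (missing fmt or data chunk): ", path)
  if (nChannels > 1L) samples <- samples[seq(1L, length(samples), by = nChannels)]
  list(waveform = samples / 32767, sampleRate = sampleRate)
}

#' Write a PCM WAV file
#'
#' Writes a mono 16-bit PCM RIFF/WAVE file.  Amplitudes outside \[-1, 1\]
#' are clipped.
#'
#' @param waveform numeric amplitude vector in \[-1, 1\].
#' @param sampleRate sampling rate in Hz.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeWav <- function(waveform, sampleRate, path) {
  x <- as.integer(round(pmin(1, pmax(-1, waveform)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  dataSize <- 2L * length(x)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataSize), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")                  # PCM
  writeBin(1L, con, 2, endian = "little")                  # mono
  writeBin(as.integer(sampleRate), con, 4, endian = "little")
  writeBin(as.integer(sampleRate * 2L), con, 4, endian = "little")
  writeBin(2L, con, 2, endian = "little")
  writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(dataSize, con, 4, endian = "little")
  writeBin(x, con, 2, endian = "little")
  invisible(path)
}
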