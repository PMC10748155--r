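#' Write a mono 16-bit PCM WAV file
#'
#' Amplitudes are clipped to [-1, 1] and quantized to signed 16-bit samples.
#' Only the canonical 44-byte RIFF/WAVE header is written, which is what the
#' recording hardware emulated by the cohort generator produces.
#'
#' @param samples numeric vector of amplitudes in [-1, 1].
#' @param path output file path.
#' @param sample_rate sampling frequency in Hz.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate = 4000L) {
  if (!is.numeric(samples) || anyNA(samples) || any(!is.finite(samples)))
    stopf("samples must be finite numeric")
  pcm <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + 2L * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")          # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2L * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path WAV file written by [write_wav()] (or any canonical mono
#'   16-bit PCM file with a plain `data` chunk).
#' @return list with `samples` (numeric in [-1, 1]) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stopf("%s: not a RIFF file", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stopf("%s: not a WAVE file", path)
  sample_rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stopf("%s: no data chunk", path)
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) stopf("%s: only mono PCM supported", path)
      sample_rate <- readBin(con, "integer", 1, 4, endian = "little")
      readBin(con, "raw", size - 8)
    } else if (id == "data") {
      pcm <- readBin(con, "integer", size / 2, 2, signed = TRUE,
                     endian = "little")
      return(list(samples = pcm / 32767, sample_rate = sample_rate))
    } else readBin(con, "raw", size)
  }
}
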