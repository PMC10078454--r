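#' Waveform objects
#'
#' A `Waveform` is a mono audio signal: numeric samples in `[-1, 1]` plus a
#' sampling rate. All analysis and synthesis functions in the package
#' consume and produce this container.
#'
#' @param samples numeric vector of samples
#' @param rate sampling rate in Hz
#' @return an object of class `Waveform`
#' @export
waveform <- function(samples, rate) {
  stopifnot(is.numeric(samples), length(rate) == 1, rate > 0)
  structure(list(samples = as.numeric(samples), rate = rate),
            class = "Waveform")
}

#' @export
print.Waveform <- function(x, ...) {
  cat(sprintf("<Waveform: %.3f s @ %d Hz, peak %.3f>\n",
              length(x$samples) / x$rate, as.integer(x$rate),
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

#' @export
length.Waveform <- function(x) length(x$samples)

#' Duration of a waveform in seconds
#' @param w a [waveform()]
#' @export
wav_duration <- function(w) length(w$samples) / w$rate

#' Read and write mono WAV files
#'
#' Minimal RIFF/WAVE support: reads mono PCM (16- or 24-bit) and IEEE
#' float32 files, normalizing samples to `[-1, 1]`; writes 16-bit PCM.
#' Multichannel files are rejected with a pointer to downmix first.
#'
#' @param path file path
#' @param w a [waveform()]
#' @return `read_wav` returns a [waveform()]; `write_wav` returns `path`
#'   invisibly.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        format = readBin(raw[1:2], "integer", 1, 2, endian = "little"),
        channels = readBin(raw[3:4], "integer", 1, 2, endian = "little"),
        rate = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt")
      if (fmt$channels != 1) {
        stop("only mono WAV is supported (file has ", fmt$channels,
             " channels); downmix to mono first")
      }
      if (fmt$format == 3 && fmt$bits == 32) {
        samples <- readBin(con, "double", size / 4, 4, endian = "little")
      } else if (fmt$format == 1 && fmt$bits == 16) {
        samples <- readBin(con, "integer", size / 2, 2, signed = TRUE,
                           endian = "little") / 32768
      } else if (fmt$format == 1 && fmt$bits == 24) {
        raw <- readBin(con, "raw", size)
        n <- length(raw) %/% 3
        b <- matrix(as.integer(raw[seq_len(n * 3)]), nrow = 3)
        v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        samples <- v / 8388608
      } else {
        stop("unsupported WAV encoding: format ", fmt$format, ", ",
             fmt$bits, " bits")
      }
      break
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  waveform(samples, fmt$rate)
}

#' @rdname read_wav
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "Waveform"))
  x <- pmax(-1, pmin(1, w$samples))
  pcm <- as.integer(round(x * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, 4, endian = "little")
  writeBin(as.integer(1), con, 2, endian = "little") # PCM
  writeBin(as.integer(1), con, 2, endian = "little") # mono
  writeBin(as.integer(w$rate), con, 4, endian = "little")
  writeBin(as.integer(w$rate * 2), con, 4, endian = "little")
  writeBin(as.integer(2), con, 2, endian = "little")
  writeBin(as.integer(16), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}
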