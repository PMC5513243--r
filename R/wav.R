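# Minimal RIFF/WAVE reader and writer for multichannel recordings.
# Supports 16-bit integer PCM (format 1) and 32-bit IEEE float (format 3),
# little-endian, which covers the files the pipeline produces and consumes.

#' Write a multichannel WAV file
#'
#' @param samples numeric matrix, one column per channel, values nominally in
#'   \[-1, 1\] (a vector is treated as one channel).
#' @param path output file path.
#' @param sample_rate sample rate in Hz.
#' @param format `"float32"` (default; stores amplitudes exactly within
#'   single precision) or `"pcm16"` (values are clipped to \[-1, 1\] and
#'   scaled by 32767).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1L)
  check_positive(sample_rate, "sample_rate")
  nch <- ncol(samples)
  n <- nrow(samples)
  bits <- if (format == "float32") 32L else 16L
  block_align <- nch * bits %/% 8L
  data_bytes <- n * block_align
  fmt_code <- if (format == "float32") 3L else 1L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(fmt_code, con, size = 2L, endian = "little")
  writeBin(nch, con, size = 2L, endian = "little")
  writeBin(as.integer(round(sample_rate)), con, size = 4L, endian = "little")
  writeBin(as.integer(round(sample_rate) * block_align), con, size = 4L,
           endian = "little")
  writeBin(block_align, con, size = 2L, endian = "little")
  writeBin(bits, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4L, endian = "little")
  interleaved <- as.vector(t(samples))
  if (format == "float32") {
    writeBin(interleaved, con, size = 4L, endian = "little")
  } else {
    clipped <- pmin(pmax(interleaved, -1), 1)
    writeBin(as.integer(round(clipped * 32767)), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

#' Read a multichannel WAV file
#'
#' Reads 16-bit PCM or 32-bit float RIFF/WAVE files; unknown chunks are
#' skipped. Integer samples are rescaled to \[-1, 1\] by 1/32767 so that a
#' `write_wav(..., format = "pcm16")` round trip is the identity up to
#' quantization.
#'
#' @param path WAV file path.
#' @return List with `samples` (numeric matrix, one column per channel),
#'   `sample_rate` (Hz) and `bit_depth`.
#' @export
read_wav <- function(path) {
  if (!file.exists(path))
    fl_stop(sprintf("WAV file not found: %s", path), "flightloc_io_error")
  con <- file(path, "rb")
  on.exit(close(con))
  read_tag <- function() readChar(con, 4L, useBytes = TRUE)
  read_u32 <- function() readBin(con, "integer", size = 4L, endian = "little")
  read_u16 <- function() readBin(con, "integer", size = 2L, signed = FALSE,
                                 endian = "little")
  if (!identical(read_tag(), "RIFF") ||
      { read_u32(); !identical(read_tag(), "WAVE") })
    fl_stop(sprintf("not a RIFF/WAVE file: %s", path), "flightloc_io_error")

  fmt <- NULL
  repeat {
    tag <- read_tag()
    if (length(tag) == 0L || nchar(tag) < 4L)
      fl_stop(sprintf("malformed WAV (no data chunk): %s", path),
              "flightloc_io_error")
    size <- read_u32()
    if (tag == "fmt ") {
      fmt <- list(code = read_u16(), nch = read_u16(), rate = read_u32(),
                  byte_rate = read_u32(), block = read_u16(), bits = read_u16())
      if (size > 16L) readBin(con, "raw", n = size - 16L)
    } else if (tag == "data") {
      if (is.null(fmt))
        fl_stop(sprintf("malformed WAV (data before fmt): %s", path),
                "flightloc_io_error")
      if (!fmt$code %in% c(1L, 3L))
        fl_stop(sprintf("unsupported WAV format code %d", fmt$code),
                "flightloc_io_error")
      n_values <- size %/% (fmt$bits %/% 8L)
      if (fmt$code == 3L && fmt$bits == 32L) {
        vals <- readBin(con, "double", n = n_values, size = 4L,
                        endian = "little")
      } else if (fmt$code == 1L && fmt$bits == 16L) {
        vals <- readBin(con, "integer", n = n_values, size = 2L,
                        endian = "little") / 32767
      } else {
        fl_stop(sprintf("unsupported WAV bit depth %d for format %d",
                        fmt$bits, fmt$code), "flightloc_io_error")
      }
      samples <- matrix(vals, ncol = fmt$nch, byrow = TRUE)
      return(list(samples = samples, sample_rate = fmt$rate,
                  bit_depth = fmt$bits))
    } else {
      readBin(con, "raw", n = size + (size %% 2L))  # chunks are word-aligned
    }
  }
}
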