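# Minimal RIFF/WAVE reader and writer, mono only. Supports format tag 1
# (16-bit integer PCM) and tag 3 (32-bit IEEE float). Little-endian byte
# order is mandated by the RIFF container and assumed of the file, not the
# host (readBin/writeBin are told the endianness explicitly).

#' Write an acoustic record to a WAV file
#'
#' @param record An [acoustic_record()]; samples are expected in \[-1, 1\]
#'   (values outside are clipped for 16-bit PCM with a warning).
#' @param path Output file path.
#' @param format `"pcm16"` (default) for 16-bit integer PCM or `"float32"`
#'   for 32-bit IEEE float (lossless round-trip).
#' @return `path`, invisibly.
#' @seealso [read_record()]
#' @export
write_record <- function(record, path, format = c("pcm16", "float32")) {
  stopifnot(inherits(record, "acoustic_record"))
  format <- match.arg(format)
  x <- record$samples
  if (length(x) == 0L) stop("refusing to write an empty record", call. = FALSE)
  fs <- as.integer(round(record$fs))
  if (abs(fs - record$fs) > 0)
    stop("WAV sampling rates must be integer Hz", call. = FALSE)

  con <- file(path, "wb")
  on.exit(close(con))
  if (format == "pcm16") {
    if (any(abs(x) > 1)) {
      warning("samples outside [-1, 1] clipped for 16-bit PCM")
      x <- pmin(1, pmax(-1, x))
    }
    pcm <- as.integer(round(x * 32767))
    data_bytes <- 2L * length(pcm)
    fmt_tag <- 1L; bits <- 16L
  } else {
    data_bytes <- 4L * length(x)
    fmt_tag <- 3L; bits <- 32L
  }
  block_align <- bits %/% 8L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_tag, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * block_align, con, size = 4, endian = "little")
  writeBin(block_align, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (format == "pcm16") {
    writeBin(pcm, con, size = 2, endian = "little")
  } else {
    writeBin(x, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file into an acoustic record
#'
#' Accepts 16-bit integer PCM (scaled to \[-1, 1\] by 1/32767) and 32-bit
#' IEEE float files; refuses multi-channel input.
#'
#' @param path WAV file path.
#' @return An [acoustic_record()].
#' @seealso [write_record()]
#' @export
read_record <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, "integer", 1, size = 4, endian = "little")   # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)

  fmt <- NULL; samples <- NULL; fs <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_tag <- readBin(con, "integer", 1, size = 2, endian = "little")
      n_chan <- readBin(con, "integer", 1, size = 2, endian = "little")
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")  # byte rate
      readBin(con, "integer", 1, size = 2, endian = "little")  # block align
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (sz > 16L) readBin(con, "raw", sz - 16L)
      if (n_chan != 1L)
        stop("only mono WAV supported (file has ", n_chan, " channels)",
             call. = FALSE)
      fmt <- list(tag = fmt_tag, bits = bits)
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data before fmt", call. = FALSE)
      if (fmt$tag == 1L && fmt$bits == 16L) {
        samples <- readBin(con, "integer", sz %/% 2L, size = 2,
                           signed = TRUE, endian = "little") / 32767
      } else if (fmt$tag == 3L && fmt$bits == 32L) {
        samples <- readBin(con, "double", sz %/% 4L, size = 4,
                           endian = "little")
      } else {
        stop("unsupported WAV format (tag ", fmt$tag, ", ", fmt$bits,
             " bits); use 16-bit PCM or 32-bit float", call. = FALSE)
      }
      break
    } else {
      readBin(con, "raw", sz + (sz %% 2L))                  # skip, pad to even
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path, call. = FALSE)
  acoustic_record(samples, fs)
}
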