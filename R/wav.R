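# Minimal RIFF/WAVE I/O: 16-bit PCM (format 1) and 32-bit float (format 3),
# mono. Enough to round-trip synthesized stimuli; no installed R package
# provides audio I/O.

#' Write a waveform to a WAV file
#'
#' @param w a `waveform` with samples in `[-1, 1]`.
#' @param path output path.
#' @param bits 16 (PCM integer) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path, bits = 16) {
  stopifnot(inherits(w, "waveform"), bits %in% c(16, 32))
  con <- tryCatch(suppressWarnings(file(path, "wb")), error = function(e)
    stop("cannot open for writing: ", path, call. = FALSE))
  on.exit(close(con))
  n <- length(w$samples)
  sr <- as.integer(round(w$sample_rate))
  bytes_per <- bits / 8
  fmt <- if (bits == 16) 1L else 3L
  data_len <- n * bytes_per

  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_len), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                 # mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(as.integer(sr * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_len), con, size = 4, endian = "little")
  if (bits == 16) {
    x <- as.integer(round(pmax(-1, pmin(1, w$samples)) * 32767))
    writeBin(x, con, size = 2, endian = "little")
  } else {
    writeBin(w$samples, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file
#'
#' Reads mono or multi-channel 16-bit PCM or 32-bit float WAV; multi-channel
#' input is averaged to mono.
#'
#' @param path WAV file path.
#' @return a `waveform`.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readChar(con, 4), "RIFF"))
    stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, integer(), size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE"))
    stop("not a WAVE file: ", path, call. = FALSE)
  fmt <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    len <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        code = readBin(con, integer(), size = 2, endian = "little"),
        channels = readBin(con, integer(), size = 2, endian = "little"),
        sr = readBin(con, integer(), size = 4, endian = "little"))
      readBin(con, raw(), n = len - 8)
    } else if (id == "data") {
      if (is.null(fmt)) stop("malformed WAV: data before fmt", call. = FALSE)
      if (fmt$code == 1L) {
        x <- readBin(con, integer(), n = len / 2, size = 2, signed = TRUE,
                     endian = "little") / 32767
      } else if (fmt$code == 3L) {
        x <- readBin(con, double(), n = len / 4, size = 4, endian = "little")
      } else stop("unsupported WAV format code ", fmt$code, call. = FALSE)
      if (fmt$channels > 1L)
        x <- colMeans(matrix(x, nrow = fmt$channels))
      samples <- x
      break
    } else {
      readBin(con, raw(), n = len)
    }
  }
  if (is.null(samples)) stop("no data chunk in ", path, call. = FALSE)
  waveform(samples, fmt$sr)
}
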