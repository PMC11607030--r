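# Minimal RIFF/WAVE I/O: 16-bit PCM and 32-bit IEEE float, any channel
# count. Only the fmt and data chunks are interpreted; others are skipped.

#' Write an audio signal or impulse response to a WAV file
#'
#' @param x an `audio_signal`, `impulse_response`, or numeric vector/matrix.
#' @param path output file path.
#' @param fs sampling rate; taken from `x` when it carries one.
#' @param format `"float32"` (default, lossless for analysis data in
#'   \[-1, 1\] and beyond) or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, fs = NULL, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  if (inherits(x, "audio_signal") || inherits(x, "impulse_response")) {
    if (is.null(fs)) fs <- x$fs
    x <- x$samples
  }
  if (is.null(fs)) stop("fs required when writing a bare numeric vector")
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  n_ch <- ncol(x)
  n_frames <- nrow(x)
  interleaved <- as.numeric(t(x))

  bits <- if (format == "float32") 32L else 16L
  audio_fmt <- if (format == "float32") 3L else 1L
  block_align <- n_ch * bits %/% 8L
  data_bytes <- n_frames * block_align

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(audio_fmt, con, size = 2, endian = "little")
  writeBin(n_ch, con, size = 2, endian = "little")
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * block_align), con, size = 4, endian = "little")
  writeBin(block_align, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (format == "float32") {
    writeBin(interleaved, con, size = 4, endian = "little")
  } else {
    q <- pmax(pmin(round(interleaved * 32767), 32767), -32768)
    writeBin(as.integer(q), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file
#'
#' @param path file path.
#' @return an `audio_signal` (multi-channel samples as a matrix).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readChar(con, 4), "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, integer(), size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) stop("no data chunk found in ", path)
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      raw_fmt <- readBin(con, raw(), n = sz)
      fmt <- list(
        audio_format = readBin(raw_fmt[1:2], integer(), size = 2, endian = "little"),
        n_ch = readBin(raw_fmt[3:4], integer(), size = 2, endian = "little"),
        fs = readBin(raw_fmt[5:8], integer(), size = 4, endian = "little"),
        bits = readBin(raw_fmt[15:16], integer(), size = 2, endian = "little")
      )
    } else if (id == "data") {
      if (is.null(fmt)) stop("data chunk precedes fmt chunk in ", path)
      bytes_per <- fmt$bits %/% 8L
      n_vals <- sz %/% bytes_per
      x <- if (fmt$audio_format == 3L && fmt$bits == 32L) {
        readBin(con, numeric(), n = n_vals, size = 4, endian = "little")
      } else if (fmt$audio_format == 1L && fmt$bits == 16L) {
        readBin(con, integer(), n = n_vals, size = 2, endian = "little",
                signed = TRUE) / 32767
      } else {
        stop(sprintf("unsupported WAV encoding (format %d, %d bit) in %s",
                     fmt$audio_format, fmt$bits, path))
      }
      samples <- if (fmt$n_ch > 1L) t(matrix(x, nrow = fmt$n_ch)) else x
      return(audio_signal(samples, fs = fmt$fs))
    } else {
      readBin(con, raw(), n = sz + sz %% 2L)  # skip unknown chunk (word-aligned)
    }
  }
}

#' Write an impulse response as WAV plus JSON sidecar
#'
#' The sidecar records name, sampling rate, length and any extra metadata
#' (e.g. channel-profile breakpoints or MLS measurement parameters).
#'
#' @param ir an `impulse_response`.
#' @param path output WAV path; the sidecar is `path` with `.json` appended.
#' @param meta named list of additional metadata fields.
#' @return `path`, invisibly.
#' @export
write_ir <- function(ir, path, meta = list()) {
  stopifnot(inherits(ir, "impulse_response"))
  write_wav(ir, path)
  sidecar <- c(list(name = ir$label, fs = ir$fs, length = length(ir$samples),
                    source = ir$source), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an impulse response written by [write_ir()]
#'
#' @param path WAV path (sidecar `path`.json is read when present).
#' @return an `impulse_response` with a `meta` attribute holding the sidecar.
#' @export
read_ir <- function(path) {
  sig <- read_wav(path)
  sidecar_path <- paste0(path, ".json")
  meta <- if (file.exists(sidecar_path)) jsonlite::read_json(sidecar_path) else list()
  ir <- impulse_response(sig$samples, fs = sig$fs,
                         source = if (identical(meta$source, "measured")) "measured" else "synthetic",
                         label = if (!is.null(meta$name)) meta$name else NA_character_)
  attr(ir, "meta") <- meta
  ir
}
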