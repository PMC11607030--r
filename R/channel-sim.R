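# Acoustic channel simulation: convolve audio with an adapter impulse
# response, at single-signal and dataset scale, so recordings behave as if
# captured through the adapter.

# Linear (full) convolution via zero-padded FFT.
fft_convolve <- function(x, h) {
  n_out <- length(x) + length(h) - 1L
  nf <- 2^ceiling(log2(n_out))
  X <- stats::fft(c(x, numeric(nf - length(x))))
  H <- stats::fft(c(h, numeric(nf - length(h))))
  Re(stats::fft(X * H, inverse = TRUE))[seq_len(n_out)] / nf
}

#' Convolve an audio signal with an impulse response
#'
#' Computes the full linear convolution sum
#' `y[n] = sum_j f[j] g[n - j]` (output length `M + N - 1`), optionally
#' trimmed back to the input length `M` keeping the leading alignment, so
#' convolved recordings are drop-in replacements for the originals.
#'
#' @param signal an `audio_signal` (mono).
#' @param ir an `impulse_response`. If its rate differs from the signal's,
#'   set `resample_ir = TRUE` to resample the IR (polyphase) to the
#'   signal's rate; otherwise the mismatch is an error.
#' @param trim keep only the first `M` samples (default `TRUE`).
#' @param normalize anti-clipping guard: if the output peak exceeds 1,
#'   scale to peak 0.99 and record the factor in attribute
#'   `"applied_gain"`. Off by default here; the dataset writer
#'   [convolve_dataset()] enables it so every output is a valid WAV.
#' @param resample_ir allow IR resampling on rate mismatch.
#' @return an `audio_signal` with label and source_id preserved.
#' @export
convolve_signal <- function(signal, ir, trim = TRUE, normalize = FALSE,
                            resample_ir = FALSE) {
  stopifnot(inherits(signal, "audio_signal"), inherits(ir, "impulse_response"))
  if (length(ir$samples) < 1L) stop("empty impulse response")
  g <- ir$samples
  if (signal$fs != ir$fs) {
    if (!resample_ir)
      stop(sprintf("sampling rates differ (signal %g Hz, IR %g Hz); set resample_ir = TRUE",
                   signal$fs, ir$fs))
    g <- resample_to(g, ir$fs, signal$fs)
  }
  y <- fft_convolve(signal$samples, g)
  if (trim) y <- y[seq_len(n_samples(signal))]
  gain <- 1
  peak <- max(abs(y))
  if (normalize && peak > 1) {
    gain <- 0.99 / peak
    y <- y * gain
  }
  out <- audio_signal(y, fs = signal$fs, label = signal$label,
                      source_id = signal$source_id)
  attr(out, "applied_gain") <- gain
  out
}

#' Convolve every recording in a dataset manifest with one channel IR
#'
#' Writes one output WAV per input row, preserving class labels, and
#' returns (and writes) a manifest extended with the IR identifier and any
#' anti-clipping gain applied. Any unreadable input aborts the run.
#'
#' @param manifest data.frame with at least `path`, `class` columns (as
#'   produced by [make_dataset()]), or a path to such a CSV.
#' @param ir an `impulse_response`.
#' @param out_dir output directory (created if missing).
#' @param trim,normalize,resample_ir passed to [convolve_signal()].
#' @return the output manifest data.frame (columns of the input plus
#'   `ir_name`, `applied_gain`), invisibly written to
#'   `file.path(out_dir, "manifest.csv")`.
#' @export
convolve_dataset <- function(manifest, ir, out_dir, trim = TRUE,
                             normalize = TRUE, resample_ir = TRUE) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  stopifnot(inherits(ir, "impulse_response"),
            all(c("path", "class") %in% names(manifest)))
  missing <- manifest$path[!file.exists(manifest$path)]
  if (length(missing) > 0)
    stop("unreadable input file(s): ", paste(missing, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ir_name <- if (is.na(ir$label)) "ir" else ir$label

  out <- manifest
  out$ir_name <- ir_name
  out$applied_gain <- NA_real_
  for (i in seq_len(nrow(manifest))) {
    sig <- read_wav(manifest$path[i])
    sig$label <- manifest$class[i]
    conv <- convolve_signal(sig, ir, trim = trim, normalize = normalize,
                            resample_ir = resample_ir)
    out_path <- file.path(out_dir, basename(manifest$path[i]))
    write_wav(conv, out_path)
    out$path[i] <- out_path
    out$applied_gain[i] <- attr(conv, "applied_gain")
  }
  utils::write.csv(out, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  out
}
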