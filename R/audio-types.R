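#' Construct an audio signal
#'
#' Lightweight container for a sampled single- or multi-channel waveform.
#' Samples are stored as a numeric vector (mono) or a matrix with one
#' column per channel.
#'
#' @param samples numeric vector, or matrix with channels in columns.
#' @param fs sampling rate in Hz.
#' @param label optional class label (e.g. tissue type).
#' @param source_id optional identifier of the originating recording.
#' @return an object of class `audio_signal`.
#' @export
audio_signal <- function(samples, fs, label = NA_character_,
                         source_id = NA_character_) {
  if (is.matrix(samples) && ncol(samples) == 1L) samples <- samples[, 1L]
  if (length(samples) < 1L) stop("audio signal must contain at least one sample")
  if (!all(is.finite(samples))) stop("audio samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  structure(
    list(samples = samples, fs = fs,
         label = as.character(label), source_id = as.character(source_id)),
    class = "audio_signal"
  )
}

#' @export
print.audio_signal <- function(x, ...) {
  n <- n_samples(x)
  cat(sprintf("<audio_signal> %d samples @ %g Hz (%.3f s)%s%s\n",
              n, x$fs, n / x$fs,
              if (is.na(x$label)) "" else paste0(", label=", x$label),
              if (n_channels(x) > 1L) sprintf(", %d channels", n_channels(x)) else ""))
  invisible(x)
}

n_samples <- function(x) if (is.matrix(x$samples)) nrow(x$samples) else length(x$samples)
n_channels <- function(x) if (is.matrix(x$samples)) ncol(x$samples) else 1L

#' @export
length.audio_signal <- function(x) n_samples(x)

duration_s <- function(x) n_samples(x) / x$fs

#' Construct an impulse response
#'
#' A finite discrete impulse response h[n] of a linear time-invariant
#' acoustic path, with measurement metadata.
#'
#' @param samples numeric vector of IR coefficients.
#' @param fs sampling rate in Hz.
#' @param source `"measured"` (estimated from an excitation/recording pair)
#'   or `"synthetic"` (designed from a channel profile).
#' @param label free-text description of the measured condition.
#' @return an object of class `impulse_response`.
#' @export
impulse_response <- function(samples, fs, source = c("synthetic", "measured"),
                             label = NA_character_) {
  source <- match.arg(source)
  if (length(samples) < 1L) stop("impulse response must have length >= 1")
  if (!all(is.finite(samples))) stop("impulse response samples must be finite")
  if (fs <= 0) stop("fs must be positive")
  structure(
    list(samples = as.numeric(samples), fs = fs, source = source,
         label = as.character(label)),
    class = "impulse_response"
  )
}

#' @export
print.impulse_response <- function(x, ...) {
  cat(sprintf("<impulse_response> %d taps @ %g Hz, %s%s\n",
              length(x$samples), x$fs, x$source,
              if (is.na(x$label)) "" else paste0(" (", x$label, ")")))
  invisible(x)
}

#' @export
length.impulse_response <- function(x) length(x$samples)

rms <- function(x) {
  s <- if (inherits(x, "audio_signal")) x$samples else x
  sqrt(mean(s^2))
}

db <- function(x) 20 * log10(x)
undb <- function(x) 10^(x / 20)
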