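# Maximum length sequences and impulse-response estimation by circular
# cross-correlation. An MLS of order m is the ±1-valued output of a
# maximal linear-feedback shift register: period 2^m - 1, one-period sum
# ±1, and circular autocorrelation equal to the period at lag 0 and -1 at
# every other lag, which is what makes the cross-correlation inversion
# work.

# Standard primitive-polynomial tap sets (Fibonacci LFSR feedback
# positions) per order.
MLS_TAPS <- list(
  `2` = c(2, 1),  `3` = c(3, 2),  `4` = c(4, 3),  `5` = c(5, 3),
  `6` = c(6, 5),  `7` = c(7, 6),  `8` = c(8, 6, 5, 4), `9` = c(9, 5),
  `10` = c(10, 7), `11` = c(11, 9), `12` = c(12, 6, 4, 1),
  `13` = c(13, 4, 3, 1), `14` = c(14, 5, 3, 1), `15` = c(15, 14),
  `16` = c(16, 15, 13, 4), `17` = c(17, 14), `18` = c(18, 11),
  `19` = c(19, 6, 2, 1), `20` = c(20, 17)
)

#' Generate a maximum length sequence
#'
#' @param order LFSR order m, between 2 and 20; period is `2^m - 1`.
#' @param taps optional feedback tap positions (must form a primitive
#'   polynomial; rejected if the generated period falls short).
#' @return an `mls_sequence` with ±1 `samples` of length `period`.
#' @export
generate_mls <- function(order, taps = NULL) {
  order <- as.integer(order)
  if (order < 2L || order > 20L) stop("order must be between 2 and 20")
  if (is.null(taps)) taps <- MLS_TAPS[[as.character(order)]]
  taps <- as.integer(taps)
  if (any(taps < 1L | taps > order)) stop("taps must lie in 1..order")
  period <- 2L^order - 1L

  reg <- rep(1L, order)
  init <- reg
  out <- integer(period)
  for (i in seq_len(period)) {
    out[i] <- reg[order]
    fb <- sum(reg[taps]) %% 2L
    reg <- c(fb, reg[-order])
    if (i < period && all(reg == init))
      stop("taps are not primitive: LFSR period ", i, " < ", period)
  }
  if (!all(reg == init))
    stop("taps are not primitive: LFSR state does not close after one period")
  structure(
    list(order = order, period = period, taps = taps,
         samples = 1 - 2 * out),
    class = "mls_sequence"
  )
}

#' @export
print.mls_sequence <- function(x, ...) {
  cat(sprintf("<mls_sequence> order %d, period %d, taps (%s)\n",
              x$order, x$period, paste(x$taps, collapse = ", ")))
  invisible(x)
}

# Circular cross-correlation c[k] = sum_n y[n] x[n-k] via FFT.
circular_xcorr <- function(y, x) {
  Re(stats::fft(stats::fft(y) * Conj(stats::fft(x)), inverse = TRUE)) / length(x)
}

#' Estimate an impulse response from an MLS recording
#'
#' Recovers h by circular cross-correlation of the recording with the
#' excitation, scaled by `1 / (period + 1)` with an exact DC correction so
#' that an identity channel yields a unit impulse. When the recording
#' holds more than one full period, the first period is discarded
#' (channel settling) and the remaining complete periods are averaged.
#'
#' @param excitation an `mls_sequence`.
#' @param recording an `audio_signal` (or numeric vector) of at least one
#'   MLS period, captured through the system under test.
#' @param fs sampling rate to stamp on the result when `recording` is a
#'   bare vector.
#' @param label free-text condition label for the result.
#' @return an `impulse_response` of length `period`, `source = "measured"`;
#'   index i holds the coefficient at lag i - 1.
#' @export
estimate_ir <- function(excitation, recording, fs = NULL,
                        label = NA_character_) {
  stopifnot(inherits(excitation, "mls_sequence"))
  if (inherits(recording, "audio_signal")) {
    if (is.null(fs)) fs <- recording$fs
    y <- recording$samples
  } else {
    y <- as.numeric(recording)
  }
  if (is.null(fs)) stop("fs must be supplied when recording is a bare vector")
  P <- excitation$period
  if (length(y) < P)
    stop(sprintf("recording (%d samples) is shorter than one MLS period (%d)",
                 length(y), P))
  if (all(y == 0)) {
    warning("recording is silent; returning an all-zero impulse response")
    return(impulse_response(numeric(P) + 0, fs = fs, source = "measured",
                            label = label))
  }
  n_periods <- length(y) %/% P
  y_avg <- if (n_periods >= 2L) {
    blocks <- matrix(y[seq_len(n_periods * P)], nrow = P)
    rowMeans(blocks[, -1L, drop = FALSE])
  } else {
    y[seq_len(P)]
  }
  cc <- circular_xcorr(y_avg, excitation$samples)
  # MLS autocorrelation is (P+1)*delta - 1, so cc = (P+1) h - sum(h) and
  # sum(cc) = sum(h); adding sum(cc) back inverts exactly.
  h <- (cc + sum(cc)) / (P + 1)
  impulse_response(h, fs = fs, source = "measured", label = label)
}

#' Simulate an MLS measurement through a known channel
#'
#' Replaces the loudspeaker/microphone chain: the repeated MLS stream is
#' passed through a known FIR channel (linear convolution) with optional
#' additive white noise. Emits `periods + 1` periods; [estimate_ir()]
#' discards the first.
#'
#' @param excitation an `mls_sequence`.
#' @param channel an `impulse_response` (the true channel).
#' @param periods number of periods to average over (default 4).
#' @param noise_db white-noise level in dB relative to the signal RMS;
#'   `NULL` for noiseless.
#' @param seed RNG seed for the noise.
#' @return an `audio_signal` holding the simulated recording.
#' @export
simulate_mls_measurement <- function(excitation, channel, periods = 4,
                                     noise_db = NULL, seed = 1) {
  stopifnot(inherits(excitation, "mls_sequence"),
            inherits(channel, "impulse_response"))
  stream <- rep(excitation$samples, periods + 1)
  y <- fft_convolve(stream, channel$samples)[seq_along(stream)]
  if (!is.null(noise_db)) {
    y <- with_seed(seed, {
      y + stats::rnorm(length(y), sd = rms(y) * undb(noise_db))
    })
  }
  audio_signal(y, fs = channel$fs, source_id = "mls_simulation")
}
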