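# Synthetic adapter impulse responses. A channel is declared as magnitude
# breakpoints (freq_hz, gain_db); the gain curve is interpolated linearly
# in log-frequency and realized as a minimum-phase FIR via the real-cepstrum
# method. Minimum phase avoids pre-ringing and matches a physical acoustic
# path.

#' Declare an adapter channel by magnitude breakpoints
#'
#' @param name channel name.
#' @param breakpoints two-column matrix or data.frame `(freq_hz, gain_db)`;
#'   frequencies strictly increasing.
#' @param ir_length_samples FIR length (default 1024 taps).
#' @param phase `"minimum"` (cepstral minimum phase) or `"linear"`.
#' @return a `channel_profile`.
#' @export
channel_profile <- function(name, breakpoints, ir_length_samples = 1024L,
                            phase = c("minimum", "linear")) {
  phase <- match.arg(phase)
  bp <- as.matrix(breakpoints)
  stopifnot(ncol(bp) == 2L, nrow(bp) >= 1L, all(is.finite(bp)),
            all(bp[, 1] > 0), ir_length_samples >= 64L)
  if (is.unsorted(bp[, 1], strictly = TRUE))
    stop("breakpoint frequencies must be strictly increasing")
  colnames(bp) <- c("freq_hz", "gain_db")
  structure(list(name = name, breakpoints = bp,
                 ir_length_samples = as.integer(ir_length_samples),
                 phase = phase),
            class = "channel_profile")
}

#' Built-in channel profiles for the three adapter designs plus a reference
#'
#' `reference` is flat 0 dB (identity path). `dual_channel` is near-flat
#' with 9.4 dB average attenuation. `luer_lock` rolls off from 200 Hz and
#' sits 10-20 dB below the tube between 300 Hz and 1 kHz. `tube` rolls off
#' from 300 Hz and reaches about -40 dB at 1 kHz.
#'
#' @param name one of `"reference"`, `"dual_channel"`, `"luer_lock"`,
#'   `"tube"`.
#' @return a `channel_profile`.
#' @export
default_channel_profile <- function(name = c("reference", "dual_channel",
                                             "luer_lock", "tube")) {
  name <- match.arg(name)
  bp <- switch(name,
    reference    = cbind(c(100, 7500), c(0, 0)),
    dual_channel = cbind(c(100, 7500), c(-9.4, -9.4)),
    luer_lock    = cbind(c(100, 200, 600, 1000, 7500),
                         c(0, 0, -35, -52, -60)),
    tube         = cbind(c(100, 300, 600, 1000, 7500),
                         c(0, 0, -20, -40, -48))
  )
  channel_profile(name, bp)
}

#' Evaluate a profile's designed gain at arbitrary frequencies
#'
#' Linear interpolation of gain (dB) against log10(frequency); gains are
#' held constant below the first and above the last breakpoint.
#'
#' @param profile a `channel_profile`.
#' @param freqs_hz numeric vector of frequencies (Hz); 0 maps to the first
#'   breakpoint's gain.
#' @return gains in dB.
#' @export
profile_gain_db <- function(profile, freqs_hz) {
  bp <- profile$breakpoints
  f <- pmax(freqs_hz, bp[1, 1] * 1e-6)
  if (nrow(bp) == 1L) return(rep(bp[1, 2], length(f)))
  stats::approx(log10(bp[, 1]), bp[, 2], xout = log10(f), rule = 2)$y
}

# Minimum-phase spectrum for a given magnitude sampled on a full FFT grid.
minimum_phase_spectrum <- function(mag_full) {
  n <- length(mag_full)
  logmag <- log(pmax(mag_full, 1e-12))
  cep <- Re(stats::fft(logmag, inverse = TRUE)) / n
  w <- c(1, rep(2, n / 2 - 1), 1, rep(0, n / 2 - 1))
  exp(stats::fft(cep * w))
}

#' Synthesize an adapter impulse response from a channel profile
#'
#' @param profile a [channel_profile()].
#' @param fs sampling rate in Hz (>= 16 kHz).
#' @param n_fft synthesis grid; default is the next power of two at or
#'   above eight times the FIR length.
#' @return an `impulse_response` with `source = "synthetic"`.
#' @export
synth_adapter_ir <- function(profile, fs = 48000, n_fft = NULL) {
  stopifnot(inherits(profile, "channel_profile"))
  if (fs < 16000) stop("fs must be at least 16 kHz")
  if (any(profile$breakpoints[, 1] > fs / 2))
    stop("profile has breakpoints above the Nyquist frequency; unattainable at fs = ", fs)
  n_taps <- profile$ir_length_samples
  if (is.null(n_fft)) n_fft <- 2^ceiling(log2(8 * n_taps))
  freqs <- seq(0, fs / 2, length.out = n_fft / 2 + 1)
  gains <- profile_gain_db(profile, freqs)
  mag_half <- undb(gains)
  mag_full <- c(mag_half, rev(mag_half[2:(n_fft / 2)]))

  if (profile$phase == "minimum") {
    H <- minimum_phase_spectrum(mag_full)
    h <- Re(stats::fft(H, inverse = TRUE)) / n_fft
    h <- h[seq_len(n_taps)]
  } else {
    # linear phase: zero-phase design circularly shifted to the center tap
    h0 <- Re(stats::fft(mag_full, inverse = TRUE)) / n_fft
    half <- n_taps %/% 2
    h <- c(h0[(n_fft - half + 1):n_fft], h0[seq_len(n_taps - half)])
    h <- h * signal::hanning(n_taps)
  }
  impulse_response(h, fs = fs, source = "synthetic", label = profile$name)
}

# Magnitude response of an FIR at specific frequencies (direct DTFT).
fir_gain_db <- function(h, fs, freqs_hz) {
  n <- seq_along(h) - 1
  vapply(freqs_hz, function(f) {
    db(Mod(sum(h * exp(-2i * pi * f * n / fs))))
  }, numeric(1))
}
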