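# Log-mel spectrogram front end. Audio is standardized to mono 16 kHz,
# high-passed at 100 Hz, segmented into 0.98 s windows with 75% overlap,
# and each window becomes a 96 x 64 log-mel patch (25 ms Hann frames,
# 10 ms hop, 64 mel bands spanning 125-7500 Hz, log(mel + 0.001)).

PP_FS <- 16000L
PP_WIN_S <- 0.98
PP_OVERLAP <- 0.75
PP_STFT_WIN <- 400L   # 25 ms at 16 kHz
PP_STFT_HOP <- 160L   # 10 ms
PP_N_FFT <- 512L
PP_N_MEL <- 64L
PP_MEL_LO <- 125
PP_MEL_HI <- 7500
PP_LOG_OFFSET <- 0.001

# Polyphase resampling by a rational factor (integer rates assumed).
resample_to <- function(x, fs_in, fs_out) {
  if (fs_in == fs_out) return(x)
  g <- gcd_int(as.integer(round(fs_out)), as.integer(round(fs_in)))
  as.numeric(signal::resample(x, fs_out %/% g, fs_in %/% g))
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)

#' Standardize audio to mono 16 kHz
#'
#' Multi-channel input is averaged across channels; sampling rates other
#' than 16 kHz are converted by polyphase resampling. Already-conforming
#' input passes through unchanged.
#'
#' @param audio an `audio_signal`.
#' @return a mono `audio_signal` at 16 kHz.
#' @export
standardize <- function(audio) {
  stopifnot(inherits(audio, "audio_signal"))
  if (n_samples(audio) < 1L) stop("empty audio")
  x <- if (is.matrix(audio$samples)) rowMeans(audio$samples) else audio$samples
  if (audio$fs != PP_FS) x <- resample_to(x, audio$fs, PP_FS)
  audio_signal(x, fs = PP_FS, label = audio$label, source_id = audio$source_id)
}

# One IIR pass initialized at the step steady state (past inputs = x[1],
# past outputs = DC gain * x[1]), which suppresses the start-up transient
# a zero-state filter would ring with.
iir_pass <- function(b, a, x) {
  y0 <- x[1] * sum(b) / sum(a)
  as.numeric(signal::filter(b, a, x,
                            init.x = rep(x[1], length(b) - 1),
                            init.y = rep(y0, length(a) - 1)))
}

#' High-pass filter an audio signal
#'
#' 4th-order Butterworth applied forward-backward (zero phase, so
#' transient timing is preserved), with steady-state initialization at
#' both ends to avoid edge transients.
#'
#' @param audio an `audio_signal`.
#' @param fc corner frequency in Hz (default 100), below Nyquist.
#' @return filtered `audio_signal`.
#' @export
highpass <- function(audio, fc = 100) {
  stopifnot(inherits(audio, "audio_signal"))
  if (fc >= audio$fs / 2) stop("corner frequency must be below Nyquist")
  bt <- signal::butter(4, fc / (audio$fs / 2), type = "high")
  y <- iir_pass(bt$b, bt$a, audio$samples)
  y <- rev(iir_pass(bt$b, bt$a, rev(y)))
  audio_signal(y, fs = audio$fs, label = audio$label,
               source_id = audio$source_id)
}

#' Segment a standardized signal into overlapping analysis windows
#'
#' Consecutive windows of `win_s` seconds with the given overlap
#' (hop = `win_s * (1 - overlap)`). Signals shorter than one window are
#' zero-padded at the end to a single full window; a trailing remainder of
#' a longer signal is dropped.
#'
#' @param audio a mono `audio_signal` at 16 kHz.
#' @param win_s window length in seconds (default 0.98).
#' @param overlap fractional overlap (default 0.75).
#' @return list of numeric windows, each `win_s * fs` samples.
#' @export
segment_windows <- function(audio, win_s = PP_WIN_S, overlap = PP_OVERLAP) {
  stopifnot(inherits(audio, "audio_signal"))
  x <- audio$samples
  W <- round(win_s * audio$fs)
  H <- round(W * (1 - overlap))
  L <- length(x)
  if (L < W) return(list(c(x, numeric(W - L))))
  n_win <- (L - W) %/% H + 1L
  lapply(seq_len(n_win), function(i) x[((i - 1L) * H + 1L):((i - 1L) * H + W)])
}

#' Number of analysis windows for a signal length
#'
#' `floor((L - W) / H) + 1` for `L >= W`, else 1 (zero-padded window).
#'
#' @param n_samples signal length in samples.
#' @param fs sampling rate.
#' @param win_s,overlap as in [segment_windows()].
#' @return integer window count.
#' @export
count_windows <- function(n_samples, fs = PP_FS, win_s = PP_WIN_S,
                          overlap = PP_OVERLAP) {
  W <- round(win_s * fs)
  H <- round(W * (1 - overlap))
  if (n_samples < W) 1L else as.integer((n_samples - W) %/% H + 1L)
}

#' Mel filterbank matrix
#'
#' Triangular filters on the HTK mel scale (`2595 log10(1 + f/700)`),
#' evaluated on the one-sided FFT bin frequencies.
#'
#' @param n_mel number of bands.
#' @param n_fft FFT length.
#' @param fs sampling rate.
#' @param f_lo,f_hi mel range edges in Hz.
#' @return matrix of dim `(n_fft/2 + 1) x n_mel`; attribute
#'   `"center_freqs_hz"` holds the band centers.
#' @export
mel_filterbank <- function(n_mel = PP_N_MEL, n_fft = PP_N_FFT, fs = PP_FS,
                           f_lo = PP_MEL_LO, f_hi = PP_MEL_HI) {
  hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
  mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)
  edges <- mel_to_hz(seq(hz_to_mel(f_lo), hz_to_mel(f_hi),
                         length.out = n_mel + 2))
  bin_f <- (0:(n_fft / 2)) * fs / n_fft
  W <- matrix(0, nrow = length(bin_f), ncol = n_mel)
  for (b in seq_len(n_mel)) {
    lo <- edges[b]; c0 <- edges[b + 1]; hi <- edges[b + 2]
    up <- (bin_f - lo) / (c0 - lo)
    down <- (hi - bin_f) / (hi - c0)
    W[, b] <- pmax(0, pmin(up, down))
  }
  attr(W, "center_freqs_hz") <- edges[2:(n_mel + 1)]
  W
}

#' Log-mel patch of one analysis window
#'
#' STFT with 25 ms periodic Hann frames and 10 ms hop (no centering: the
#' first frame starts at sample 0, which makes the 96-frame count exact),
#' magnitude spectrogram pooled through the 64-band mel filterbank, then
#' `log(mel + 0.001)`.
#'
#' @param window numeric vector of exactly 15680 samples (0.98 s at
#'   16 kHz).
#' @param fb optional precomputed [mel_filterbank()].
#' @return matrix of dim 96 x 64 (time frames x mel bands).
#' @export
logmel <- function(window, fb = NULL) {
  W <- round(PP_WIN_S * PP_FS)
  if (length(window) != W)
    stop(sprintf("window must be exactly %d samples (got %d)", W, length(window)))
  if (is.null(fb)) fb <- mel_filterbank()
  n_frames <- (W - PP_STFT_WIN) %/% PP_STFT_HOP + 1L
  starts <- (seq_len(n_frames) - 1L) * PP_STFT_HOP
  idx <- outer(seq_len(PP_STFT_WIN), starts, "+")
  frames <- matrix(window[idx], nrow = PP_STFT_WIN)
  hann <- 0.5 - 0.5 * cos(2 * pi * (0:(PP_STFT_WIN - 1)) / PP_STFT_WIN)
  frames <- frames * hann
  padded <- rbind(frames, matrix(0, PP_N_FFT - PP_STFT_WIN, n_frames))
  mag <- Mod(stats::mvfft(padded))[1:(PP_N_FFT / 2 + 1), , drop = FALSE]
  mel <- crossprod(fb, mag)               # n_mel x n_frames
  t(log(mel + PP_LOG_OFFSET))             # n_frames x n_mel
}

#' Full preprocessing of one audio signal into a patch set
#'
#' standardize -> 100 Hz high-pass -> 0.98 s / 75% overlap segmentation ->
#' log-mel patches.
#'
#' @param audio an `audio_signal` (any rate / channel count).
#' @param fb optional precomputed mel filterbank.
#' @return a `mel_patch_set`: list with `patches` (array K x 96 x 64),
#'   `label`, `source_id`, `K`.
#' @export
patches_from_audio <- function(audio, fb = NULL) {
  if (is.null(fb)) fb <- mel_filterbank()
  std <- highpass(standardize(audio))
  wins <- segment_windows(std)
  K <- length(wins)
  patches <- array(NA_real_, dim = c(K, 96, PP_N_MEL))
  for (k in seq_len(K)) patches[k, , ] <- logmel(wins[[k]], fb = fb)
  structure(list(patches = patches, K = K, label = audio$label,
                 source_id = audio$source_id),
            class = "mel_patch_set")
}

#' @export
print.mel_patch_set <- function(x, ...) {
  cat(sprintf("<mel_patch_set> %d patch(es) of 96 x %d%s\n", x$K, PP_N_MEL,
              if (is.na(x$label)) "" else paste0(", label=", x$label)))
  invisible(x)
}

#' Preprocess every recording in a manifest
#'
#' @param manifest data.frame with `path` and `class` columns, or CSV path.
#' @return list of `mel_patch_set`, one per manifest row, with
#'   `source_id` set to the file's base name.
#' @export
patches_from_manifest <- function(manifest) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  fb <- mel_filterbank()
  lapply(seq_len(nrow(manifest)), function(i) {
    sig <- read_wav(manifest$path[i])
    sig$label <- manifest$class[i]
    sig$source_id <- basename(manifest$path[i])
    patches_from_audio(sig, fb = fb)
  })
}
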