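# Transfer functions from impulse responses, the relative transfer
# function (dB magnitude quotient against a reference path), fractional-
# octave Savitzky-Golay smoothing, and band summaries.

#' Transfer function of an impulse response
#'
#' Discrete Fourier transform of the zero-padded IR, returned one-sided
#' (DC excluded from the reported grid but retained for exact inversion).
#'
#' @param ir an `impulse_response`.
#' @param n_fft FFT length, at least `length(ir)`; default next power of
#'   two at or above twice the IR length.
#' @return a `transfer_function` with fields `freqs_hz`, `values`
#'   (complex, one-sided), `fs`, `n_fft`.
#' @export
tf_from_ir <- function(ir, n_fft = NULL) {
  stopifnot(inherits(ir, "impulse_response"))
  n <- length(ir$samples)
  if (is.null(n_fft)) n_fft <- 2^ceiling(log2(2 * n))
  n_fft <- as.integer(n_fft)
  if (n_fft < n) stop("n_fft must be at least the IR length")
  spec <- stats::fft(c(ir$samples, numeric(n_fft - n)))
  half <- n_fft %/% 2
  structure(
    list(freqs_hz = (1:half) * ir$fs / n_fft,
         values = spec[2:(half + 1)],
         dc = spec[1], fs = ir$fs, n_fft = n_fft),
    class = "transfer_function"
  )
}

#' @export
print.transfer_function <- function(x, ...) {
  cat(sprintf("<transfer_function> %d bins, %.1f-%.1f Hz (n_fft %d @ %g Hz)\n",
              length(x$freqs_hz), x$freqs_hz[1], max(x$freqs_hz), x$n_fft, x$fs))
  invisible(x)
}

#' Invert a transfer function back to its (zero-padded) impulse response
#'
#' @param tf a `transfer_function` from [tf_from_ir()].
#' @return numeric vector of length `n_fft`.
#' @export
ir_from_tf <- function(tf) {
  half <- tf$n_fft %/% 2
  full <- c(tf$dc, tf$values, Conj(rev(tf$values[1:(half - 1)])))
  Re(stats::fft(full, inverse = TRUE)) / tf$n_fft
}

#' Relative transfer function in dB
#'
#' `delta_db[i] = 20 log10(|H_proto[i]| / |H_ref[i]|)` on a shared
#' frequency grid. Bins where the reference magnitude falls below
#' `floor_rel` times its maximum are masked (set `NA`), never fabricated.
#'
#' @param tf_proto,tf_ref `transfer_function` objects on identical grids.
#' @param floor_rel relative reference-magnitude floor for masking.
#' @return a `relative_tf` with fields `freqs_hz`, `delta_db`, `smoothed`,
#'   `bandwidth_octaves`.
#' @export
relative_tf <- function(tf_proto, tf_ref, floor_rel = 1e-8) {
  stopifnot(inherits(tf_proto, "transfer_function"),
            inherits(tf_ref, "transfer_function"))
  if (length(tf_proto$freqs_hz) != length(tf_ref$freqs_hz) ||
      any(tf_proto$freqs_hz != tf_ref$freqs_hz))
    stop("transfer functions are on different frequency grids")
  mag_p <- Mod(tf_proto$values)
  mag_r <- Mod(tf_ref$values)
  masked <- mag_r < floor_rel * max(mag_r)
  delta <- ifelse(masked, NA_real_, db(mag_p / mag_r))
  structure(
    list(freqs_hz = tf_proto$freqs_hz, delta_db = delta,
         smoothed = FALSE, bandwidth_octaves = NA_real_),
    class = "relative_tf"
  )
}

#' @export
print.relative_tf <- function(x, ...) {
  cat(sprintf("<relative_tf> %d bins, %s\n", length(x$freqs_hz),
              if (x$smoothed) sprintf("smoothed (1/%g octave)",
                                      1 / x$bandwidth_octaves) else "unsmoothed"))
  invisible(x)
}

#' Fractional-octave Savitzky-Golay smoothing of a relative TF
#'
#' The dB curve is resampled onto a log-spaced grid (`points_per_octave`
#' points per octave), smoothed with a Savitzky-Golay filter whose window
#' spans the requested relative bandwidth, and interpolated back to the
#' original grid. This makes "relative bandwidth" well defined on a log
#' axis. Constants and (log-frequency) ramps pass unchanged.
#'
#' @param rtf an unsmoothed `relative_tf`.
#' @param bandwidth_oct smoothing bandwidth in octaves (default 1/6).
#' @param polyorder Savitzky-Golay polynomial order (default 2).
#' @param points_per_octave density of the working log grid (default 48).
#' @return a smoothed `relative_tf`; masked bins stay masked.
#' @export
smooth_fractional_octave <- function(rtf, bandwidth_oct = 1 / 6,
                                     polyorder = 2, points_per_octave = 48) {
  stopifnot(inherits(rtf, "relative_tf"), bandwidth_oct > 0)
  if (rtf$smoothed) stop("relative TF is already smoothed")
  ok <- !is.na(rtf$delta_db)
  f <- rtf$freqs_hz[ok]
  v <- rtf$delta_db[ok]
  n_oct <- log2(max(f) / min(f))
  n_grid <- ceiling(n_oct * points_per_octave) + 1L
  win <- round(bandwidth_oct * points_per_octave)
  if (win %% 2 == 0) win <- win + 1L
  win <- max(win, polyorder + 3 - (polyorder %% 2))
  if (n_grid < win)
    stop("too few frequency points for the smoothing window")
  lf <- seq(log2(min(f)), log2(max(f)), length.out = n_grid)
  on_grid <- stats::approx(log2(f), v, xout = lf)$y
  sm <- signal::sgolayfilt(on_grid, p = polyorder, n = win)
  back <- stats::approx(lf, sm, xout = log2(rtf$freqs_hz), rule = 2)$y
  out <- rtf
  out$delta_db <- ifelse(is.na(rtf$delta_db), NA_real_, back)
  out$smoothed <- TRUE
  out$bandwidth_octaves <- bandwidth_oct
  out
}

#' Band-averaged relative transfer function
#'
#' Arithmetic mean of `delta_db` over the (unmasked) bins inside
#' `[f_lo, f_hi]`; the summary used to report a channel's average
#' attenuation.
#'
#' @param rtf a `relative_tf`.
#' @param f_lo,f_hi band edges in Hz.
#' @return mean level in dB.
#' @export
band_average <- function(rtf, f_lo = 100, f_hi = 7500) {
  stopifnot(inherits(rtf, "relative_tf"), f_lo < f_hi)
  sel <- rtf$freqs_hz >= f_lo & rtf$freqs_hz <= f_hi & !is.na(rtf$delta_db)
  if (!any(sel)) stop("no unmasked bins in the requested band")
  mean(rtf$delta_db[sel])
}

#' Export a relative TF as a data frame
#'
#' @param rtf a `relative_tf`.
#' @return data.frame with columns `freq_hz`, `delta_db`.
#' @export
rtf_as_data_frame <- function(rtf) {
  data.frame(freq_hz = rtf$freqs_hz, delta_db = rtf$delta_db)
}
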