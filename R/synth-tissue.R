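# Synthetic diathermy-like tissue sounds. The generative model is
# band-limited noise (4th-order Butterworth bandpass around a class-specific
# center frequency) amplitude-modulated by a Poisson train of exponentially
# decaying bursts, over a broadband pink-noise floor; the idle class is pink
# noise only. This mimics the crackle-plus-hiss character of electrosurgical
# sound without claiming acoustic realism.

#' Specify a synthetic tissue-sound class
#'
#' @param class_name one of `"liver"`, `"muscle"`, `"fat"`, `"fascia"`,
#'   `"idle"`.
#' @param center_freq_hz center of the class band (Hz).
#' @param bandwidth_hz bandpass width (Hz).
#' @param burst_rate_hz mean Poisson rate of crackle bursts; 0 for idle.
#' @param burst_decay_s exponential decay time of each burst (s).
#' @param noise_floor_db RMS level of the broadband pink-noise floor, dBFS.
#' @param level_db RMS level of the band-limited burst component, dBFS.
#' @param duration_range_s length-2 vector, admissible durations (s).
#' @return a `tissue_sound_spec`.
#' @export
tissue_sound_spec <- function(class_name, center_freq_hz, bandwidth_hz,
                              burst_rate_hz, burst_decay_s = 0.03,
                              noise_floor_db = -60, level_db = -20,
                              duration_range_s = c(0.76, 5.17)) {
  class_name <- match.arg(class_name, c("liver", "muscle", "fat", "fascia", "idle"))
  stopifnot(center_freq_hz > 0, bandwidth_hz > 0, burst_rate_hz >= 0,
            burst_decay_s > 0, length(duration_range_s) == 2L,
            duration_range_s[1] > 0,
            duration_range_s[1] <= duration_range_s[2])
  if (center_freq_hz + bandwidth_hz / 2 >= 8000)
    stop("class band must lie below 8 kHz (the mel range upper edge)")
  if (class_name == "idle" && burst_rate_hz != 0)
    stop("idle class must have burst_rate_hz = 0")
  structure(
    list(class_name = class_name, center_freq_hz = center_freq_hz,
         bandwidth_hz = bandwidth_hz, burst_rate_hz = burst_rate_hz,
         burst_decay_s = burst_decay_s, noise_floor_db = noise_floor_db,
         level_db = level_db, duration_range_s = duration_range_s),
    class = "tissue_sound_spec"
  )
}

#' Default class specifications for the five-class problem
#'
#' Class centers (liver 600 Hz, muscle 1500 Hz, fat 3000 Hz, fascia 5000 Hz)
#' are spaced to remain distinguishable after 64-band mel pooling; burst
#' rates differ per class so temporal texture also carries information.
#' Idle is a pink-noise floor with durations up to `idle_max_s`.
#'
#' @param idle_max_s maximum idle duration in seconds (default 20; the
#'   long-pause regime this emulates runs to minutes, but balancing logic
#'   is unaffected by the cap).
#' @return named list of `tissue_sound_spec` objects.
#' @export
default_tissue_specs <- function(idle_max_s = 20) {
  list(
    liver  = tissue_sound_spec("liver",  600, 400, burst_rate_hz = 10),
    muscle = tissue_sound_spec("muscle", 1500, 600, burst_rate_hz = 14),
    fat    = tissue_sound_spec("fat",    3000, 800, burst_rate_hz = 8),
    fascia = tissue_sound_spec("fascia", 5000, 1000, burst_rate_hz = 12),
    idle   = tissue_sound_spec("idle",   1000, 1000, burst_rate_hz = 0,
                               duration_range_s = c(1, idle_max_s))
  )
}

# Evaluate an expression with a local RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Pink (1/f) noise of unit RMS: white noise through the Kellet 3-pole
# economy pinking approximation.
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  b0 <- stats::filter(0.0555179 * w, 0.99765, method = "recursive")
  b1 <- stats::filter(0.0750759 * w, 0.96300, method = "recursive")
  b2 <- stats::filter(0.1538520 * w, 0.57000, method = "recursive")
  p <- as.numeric(b0 + b1 + b2 + 0.1848 * w)
  p / sqrt(mean(p^2))
}

#' Synthesize one labelled tissue-sound signal
#'
#' Deterministic for fixed `(spec, duration_s, seed)`.
#'
#' @param spec a [tissue_sound_spec()].
#' @param duration_s duration in seconds; must lie within
#'   `spec$duration_range_s`.
#' @param seed integer RNG seed for this signal.
#' @param fs sampling rate (Hz), default 48000.
#' @return an `audio_signal` with `label = spec$class_name`.
#' @export
synth_tissue_sound <- function(spec, duration_s, seed, fs = 48000) {
  stopifnot(inherits(spec, "tissue_sound_spec"))
  rng <- spec$duration_range_s
  if (duration_s < rng[1] || duration_s > rng[2])
    stop(sprintf("duration %.3f s outside the %s range [%.2f, %.2f] s",
                 duration_s, spec$class_name, rng[1], rng[2]))
  n <- max(1L, round(duration_s * fs))
  with_seed(seed, {
    floor_amp <- undb(spec$noise_floor_db)
    sig <- floor_amp * pink_noise(n)
    if (spec$burst_rate_hz > 0) {
      lo <- spec$center_freq_hz - spec$bandwidth_hz / 2
      hi <- spec$center_freq_hz + spec$bandwidth_hz / 2
      bp <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
      carrier <- as.numeric(signal::filter(bp, stats::rnorm(n)))
      n_bursts <- stats::rpois(1, spec$burst_rate_hz * duration_s)
      env <- numeric(n)
      if (n_bursts > 0) {
        idx <- sort(sample.int(n, n_bursts, replace = TRUE))
        amp <- stats::runif(n_bursts, 0.4, 1)
        impulses <- numeric(n)
        for (k in seq_len(n_bursts)) impulses[idx[k]] <- impulses[idx[k]] + amp[k]
        r <- exp(-1 / (spec$burst_decay_s * fs))
        env <- as.numeric(stats::filter(impulses, r, method = "recursive"))
      }
      burst <- carrier * env
      b_rms <- sqrt(mean(burst^2))
      if (b_rms > 0) sig <- sig + burst * (undb(spec$level_db) / b_rms)
    }
    audio_signal(sig, fs = fs, label = spec$class_name)
  })
}
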