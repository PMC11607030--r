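test_that("tf_from_ir matches closed forms for elementary IRs", {
  unit <- impulse_response(c(1, numeric(63)), fs = 48000)
  H <- tf_from_ir(unit)
  expect_true(all(abs(Mod(H$values) - 1) < 1e-12))

  half <- impulse_response(c(0.5, numeric(63)), fs = 48000)
  Hh <- tf_from_ir(half)
  expect_equal(20 * log10(Mod(Hh$values)), rep(-6.0206, length(Hh$values)),
               tolerance = 1e-4)

  two_tap <- impulse_response(c(1, 1), fs = 48000)
  Ht <- tf_from_ir(two_tap, n_fft = 8)
  # |H(f)| = 2 |cos(pi f / fs)|; at 12 kHz this is sqrt(2)
  i12k <- which(Ht$freqs_hz == 12000)
  expect_equal(Mod(Ht$values[i12k]), sqrt(2), tolerance = 1e-12)
  expect_equal(Mod(Ht$values), 2 * abs(cos(pi * Ht$freqs_hz / 48000)),
               tolerance = 1e-12)
})

test_that("tf_from_ir validates n_fft and inverts exactly", {
  ir <- impulse_response(stats::rnorm(100), fs = 48000)
  expect_error(tf_from_ir(ir, n_fft = 64), "at least the IR length")
  H <- tf_from_ir(ir)
  back <- ir_from_tf(H)
  expect_equal(back[1:100], ir$samples, tolerance = 1e-10)
  expect_lt(max(abs(back[-(1:100)])), 1e-10)
})

test_that("relative_tf reproduces scalar quotients and is antisymmetric", {
  set.seed(3)
  ir_a <- impulse_response(stats::rnorm(128), fs = 48000)
  ir_b <- impulse_response(stats::rnorm(128), fs = 48000)
  Ha <- tf_from_ir(ir_a); Hb <- tf_from_ir(ir_b)

  self <- relative_tf(Ha, Ha)
  expect_true(all(self$delta_db[!is.na(self$delta_db)] == 0))

  ir_half <- impulse_response(0.5 * ir_a$samples, fs = 48000)
  expect_equal(relative_tf(tf_from_ir(ir_half), Ha)$delta_db,
               rep(-6.0206, length(Ha$values)), tolerance = 1e-4)

  ab <- relative_tf(Ha, Hb); ba <- relative_tf(Hb, Ha)
  ok <- !is.na(ab$delta_db) & !is.na(ba$delta_db)
  expect_equal(ab$delta_db[ok], -ba$delta_db[ok], tolerance = 1e-10)

  Hc <- tf_from_ir(ir_a, n_fft = 512)
  expect_error(relative_tf(Ha, Hc), "different frequency grids")
})

test_that("relative TF of a designed channel matches the profile", {
  p <- default_channel_profile("tube")
  rtf <- relative_tf(tf_from_ir(synth_adapter_ir(p)),
                     tf_from_ir(synth_adapter_ir(default_channel_profile("reference"))))
  i1k <- which.min(abs(rtf$freqs_hz - 1000))
  expect_lt(abs(rtf$delta_db[i1k] - profile_gain_db(p, rtf$freqs_hz[i1k])), 2)
})

test_that("fractional-octave smoothing preserves constants and log-ramps", {
  freqs <- exp(seq(log(100), log(7500), length.out = 400))
  flat <- structure(list(freqs_hz = freqs, delta_db = rep(-9.4, 400),
                         smoothed = FALSE, bandwidth_octaves = NA_real_),
                    class = "relative_tf")
  sm <- smooth_fractional_octave(flat)
  expect_true(sm$smoothed)
  expect_equal(sm$delta_db, flat$delta_db, tolerance = 1e-9)
  expect_error(smooth_fractional_octave(sm), "already smoothed")

  ramp <- flat
  ramp$delta_db <- -3 * log2(freqs / 100)  # linear in log2(f)
  smr <- smooth_fractional_octave(ramp)
  interior <- freqs > 150 & freqs < 5000
  expect_equal(smr$delta_db[interior], ramp$delta_db[interior],
               tolerance = 1e-6)
})

test_that("smoothing attenuates noise on a known ramp", {
  freqs <- exp(seq(log(100), log(7500), length.out = 600))
  truth <- -3 * log2(freqs / 100)
  noisy <- truth + withr::with_seed(9, stats::rnorm(600, sd = 3))
  rtf <- structure(list(freqs_hz = freqs, delta_db = noisy,
                        smoothed = FALSE, bandwidth_octaves = NA_real_),
                   class = "relative_tf")
  sm <- smooth_fractional_octave(rtf)
  rms_before <- sqrt(mean((noisy - truth)^2))
  rms_after <- sqrt(mean((sm$delta_db - truth)^2))
  expect_lt(rms_after, 0.5 * rms_before)
  tv <- function(v) sum(abs(diff(v)))
  expect_lte(tv(sm$delta_db), tv(noisy))
})

test_that("band averages are means over the requested band", {
  freqs <- exp(seq(log(100), log(7500), length.out = 300))
  rtf <- structure(list(freqs_hz = freqs, delta_db = rep(-3, 300),
                        smoothed = FALSE, bandwidth_octaves = NA_real_),
                   class = "relative_tf")
  expect_equal(band_average(rtf, 200, 5000), -3)

  step <- rtf
  step$delta_db <- ifelse(freqs < 1000, -10, -20)
  v <- band_average(step, 500, 2000)
  expect_gt(v, -20); expect_lt(v, -10)
  expect_error(band_average(step, 7600, 8000), "no unmasked bins")
})

test_that("the dual-channel design averages -9.4 dB against the reference", {
  rtf <- relative_tf(
    tf_from_ir(synth_adapter_ir(default_channel_profile("dual_channel"))),
    tf_from_ir(synth_adapter_ir(default_channel_profile("reference"))))
  expect_lt(abs(band_average(rtf, 100, 7500) - (-9.4)), 0.5)
})
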