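test_that("convolution reproduces hand-computed sums and the identity", {
  f <- audio_signal(c(1, 2, 3), fs = 48000)
  delta <- impulse_response(1, fs = 48000)
  expect_equal(convolve_signal(f, delta)$samples, c(1, 2, 3))

  g <- impulse_response(c(1, 1), fs = 48000)
  f2 <- audio_signal(c(1, 2), fs = 48000)
  expect_equal(convolve_signal(f2, g, trim = FALSE)$samples, c(1, 3, 2))
  expect_equal(convolve_signal(f2, g, trim = TRUE)$samples, c(1, 3))
})

test_that("the FFT convolution path agrees with independent oracles", {
  set.seed(5)
  x <- stats::rnorm(48000)
  ir <- synth_adapter_ir(default_channel_profile("tube"))
  y <- convolve_signal(audio_signal(x, 48000), ir, trim = FALSE,
                       normalize = FALSE)$samples
  oracle <- stats::convolve(x, rev(ir$samples), type = "open")
  expect_lt(max(abs(y - oracle)) / max(abs(oracle)), 1e-9)

  xs <- stats::rnorm(50)
  hs <- stats::rnorm(7)
  expect_equal(laparosound:::fft_convolve(xs, hs), conv_direct(xs, hs),
               tolerance = 1e-12)
})

test_that("convolution is linear in the signal and associative", {
  set.seed(6)
  f <- audio_signal(stats::rnorm(300), fs = 48000)
  g <- impulse_response(stats::rnorm(20), fs = 48000)
  a5 <- convolve_signal(audio_signal(5 * f$samples, 48000), g,
                        trim = FALSE, normalize = FALSE)
  a1 <- convolve_signal(f, g, trim = FALSE, normalize = FALSE)
  expect_equal(a5$samples, 5 * a1$samples, tolerance = 1e-10)

  g1 <- stats::rnorm(12); g2 <- stats::rnorm(9)
  left <- conv_direct(conv_direct(f$samples, g1), g2)
  right <- conv_direct(f$samples, conv_direct(g1, g2))
  expect_lt(max(abs(left - right)), 1e-8)
})

test_that("identity convolution conserves energy and labels", {
  sig <- synth_tissue_sound(default_tissue_specs()$muscle, 1.0, seed = 4)
  out <- convolve_signal(sig, synth_adapter_ir(default_channel_profile("reference")),
                         normalize = FALSE)
  expect_equal(sum(out$samples^2), sum(sig$samples^2), tolerance = 1e-12)
  expect_equal(out$label, "muscle")
})

test_that("dataset convolution preserves rows and labels and records provenance", {
  manifest <- tiny_manifest(n_per_class = 2, seed = 3)
  out_dir <- withr::local_tempdir()
  ir <- synth_adapter_ir(default_channel_profile("dual_channel"))
  out <- convolve_dataset(manifest, ir, out_dir)
  expect_equal(nrow(out), nrow(manifest))
  expect_equal(out$class, manifest$class)
  expect_true(all(out$ir_name == "dual_channel"))
  expect_true(all(file.exists(out$path)))
  expect_true(file.exists(file.path(out_dir, "manifest.csv")))

  bad <- manifest
  bad$path[1] <- file.path(out_dir, "missing.wav")
  expect_error(convolve_dataset(bad, ir, withr::local_tempdir()), "unreadable")
})

test_that("identity-IR dataset convolution is a no-op with normalization off", {
  manifest <- tiny_manifest(n_per_class = 2, seed = 8)
  out <- convolve_dataset(manifest, synth_adapter_ir(default_channel_profile("reference")),
                          withr::local_tempdir(), normalize = FALSE)
  for (i in seq_len(nrow(manifest))) {
    a <- read_wav(manifest$path[i])$samples
    b <- read_wav(out$path[i])$samples
    expect_lt(max(abs(a - b)), 1e-9)
  }
})

test_that("broadband level change through a flat channel matches its band gain", {
  # white-noise inputs through the flat -9.4 dB channel: output/input RMS
  # in dB should sit at the band-averaged gain (Parseval)
  dir_in <- withr::local_tempdir()
  set.seed(21)
  paths <- character(5)
  for (i in 1:5) {
    paths[i] <- file.path(dir_in, sprintf("wn_%d.wav", i))
    write_wav(audio_signal(stats::rnorm(48000, sd = 0.05), 48000), paths[i])
  }
  manifest <- data.frame(path = paths, class = "idle", duration_s = 1,
                         seed = 1:5)
  ir <- synth_adapter_ir(default_channel_profile("dual_channel"))
  out <- convolve_dataset(manifest, ir, withr::local_tempdir(),
                          normalize = FALSE)
  ratios <- vapply(seq_len(5), function(i) {
    20 * log10(sqrt(mean(read_wav(out$path[i])$samples^2)) /
               sqrt(mean(read_wav(manifest$path[i])$samples^2)))
  }, numeric(1))
  expect_lt(abs(mean(ratios) - (-9.4)), 1.5)
})
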