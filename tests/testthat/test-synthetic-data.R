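test_that("tissue sound synthesis is deterministic and respects duration bounds", {
  sp <- default_tissue_specs()$liver
  a <- synth_tissue_sound(sp, 1.0, seed = 1)
  b <- synth_tissue_sound(sp, 1.0, seed = 1)
  expect_identical(a$samples, b$samples)
  expect_equal(a$fs, 48000)
  expect_equal(a$label, "liver")
  expect_false(identical(a$samples, synth_tissue_sound(sp, 1.0, seed = 2)$samples))
  expect_error(synth_tissue_sound(sp, 0.5, seed = 1), "outside")
  expect_error(synth_tissue_sound(sp, 10, seed = 1), "outside")
})

test_that("idle signals sit at the configured noise-floor level", {
  sp <- tissue_sound_spec("idle", 1000, 1000, burst_rate_hz = 0,
                          noise_floor_db = -60, duration_range_s = c(1, 20))
  s <- synth_tissue_sound(sp, 2.0, seed = 7)
  expect_lt(abs(20 * log10(sqrt(mean(s$samples^2))) - (-60)), 3)
})

test_that("non-idle classes concentrate energy around their center frequency", {
  for (cls in c("liver", "muscle", "fat", "fascia")) {
    sp <- default_tissue_specs()[[cls]]
    s <- synth_tissue_sound(sp, 1.5, seed = 3)
    pw <- stats::spec.pgram(stats::ts(s$samples, frequency = 48000),
                            spans = c(51, 51), taper = 0, plot = FALSE)
    peak_hz <- pw$freq[which.max(pw$spec)]
    expect_gt(peak_hz, sp$center_freq_hz - sp$bandwidth_hz / 2)
    expect_lt(peak_hz, sp$center_freq_hz + sp$bandwidth_hz / 2)
    # spectral centroid of the band-limited component stays near the center
    centroid <- sum(pw$freq * pw$spec) / sum(pw$spec)
    expect_lt(abs(centroid - sp$center_freq_hz), sp$bandwidth_hz)
  }
})

test_that("synthetic adapter IRs hit their designed breakpoint gains", {
  for (nm in c("reference", "dual_channel", "luer_lock", "tube")) {
    p <- default_channel_profile(nm)
    ir <- synth_adapter_ir(p, fs = 48000)
    expect_true(all(is.finite(ir$samples)))
    expect_equal(length(ir$samples), p$ir_length_samples)
    achieved <- laparosound:::fir_gain_db(ir$samples, 48000, p$breakpoints[, 1])
    expect_lt(max(abs(achieved - p$breakpoints[, 2])), 2)
  }
})

test_that("the reference profile is an identity channel", {
  ir <- synth_adapter_ir(default_channel_profile("reference"))
  f <- exp(seq(log(100), log(7500), length.out = 200))
  dev <- laparosound:::fir_gain_db(ir$samples, 48000, f)
  expect_lt(max(abs(dev)), 0.1)
})

test_that("the tube profile reaches deep attenuation at 1 kHz", {
  ir <- synth_adapter_ir(default_channel_profile("tube"))
  g <- laparosound:::fir_gain_db(ir$samples, 48000, c(100, 1000))
  expect_lte(g[2] - g[1], -35)
})

test_that("unattainable profiles and bad inputs are rejected", {
  expect_error(channel_profile("x", cbind(c(200, 100), c(0, 0))),
               "strictly increasing")
  p <- channel_profile("hf", cbind(c(100, 30000), c(0, 0)))
  expect_error(synth_adapter_ir(p, fs = 48000), "Nyquist")
  expect_error(synth_adapter_ir(default_channel_profile("tube"), fs = 8000),
               "16 kHz")
})

test_that("make_dataset writes a complete, deterministic, in-range manifest", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- make_dataset(4, seed = 11, out_dir = d1)
  expect_equal(nrow(m1), 20)
  expect_equal(unname(table(m1$class)["liver"]), 4)
  expect_true(all(file.exists(m1$path)))

  m2 <- make_dataset(4, seed = 11, out_dir = d2)
  expect_equal(m2$duration_s, m1$duration_s)
  expect_equal(m2$seed, m1$seed)
  for (i in seq_len(nrow(m1)))
    expect_identical(read_wav(m1$path[i])$samples, read_wav(m2$path[i])$samples)

  m3 <- make_dataset(10, seed = 42, out_dir = withr::local_tempdir())
  non_idle <- m3[m3$class != "idle", ]
  expect_true(all(non_idle$duration_s >= 0.76 & non_idle$duration_s <= 5.17))
  expect_true(all(m3$duration_s[m3$class == "idle"] <= 20))
})

test_that("default synthetic classes are separable above chance by a linear probe", {
  specs <- default_tissue_specs()
  fb <- mel_filterbank()
  X <- NULL; y <- c()
  for (cls in names(specs)) {
    for (s in 1:6) {
      sig <- synth_tissue_sound(specs[[cls]], 1.5, seed = 100 + s,
                                fs = 16000)
      ps <- patches_from_audio(sig, fb = fb)
      X <- rbind(X, colMeans(pool_patch_features(ps)))
      y <- c(y, cls)
    }
  }
  # pairwise distances between class-mean patch features strictly positive
  cm <- do.call(rbind, lapply(unique(y), function(cl)
    colMeans(X[y == cl, , drop = FALSE])))
  dd <- as.matrix(dist(cm))
  expect_true(all(dd[upper.tri(dd)] > 0))
  # leave-one-out nearest-centroid probe beats chance (0.2)
  pred <- vapply(seq_along(y), function(i) {
    cm_i <- do.call(rbind, lapply(unique(y), function(cl) {
      sel <- y == cl; sel[i] <- FALSE
      colMeans(X[sel, , drop = FALSE])
    }))
    unique(y)[which.min(colSums((t(cm_i) - X[i, ])^2))]
  }, character(1))
  expect_gt(mean(pred == y), 0.2)
})
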