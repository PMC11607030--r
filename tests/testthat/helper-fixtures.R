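# Shared fixtures and independent oracles, all built in code.

# Direct O(MN) linear convolution (oracle for the FFT path).
conv_direct <- function(f, g) {
  M <- length(f); N <- length(g)
  y <- numeric(M + N - 1)
  for (n in seq_along(y)) {
    j <- max(1, n - N + 1):min(n, M)
    y[n] <- sum(f[j] * g[n - j + 1])
  }
  y
}

# Direct circular convolution of h (zero-padded) with x.
circ_conv_direct <- function(x, h) {
  P <- length(x)
  hh <- c(h, numeric(P - length(h)))
  y <- numeric(P)
  for (n in seq_len(P)) {
    idx <- ((n - seq_len(P)) %% P) + 1L
    y[n] <- sum(hh * x[idx])
  }
  y
}

# Brute-force circular autocorrelation at every lag.
circ_autocorr_direct <- function(x) {
  P <- length(x)
  vapply(0:(P - 1), function(k) sum(x * x[((seq_len(P) - 1 + k) %% P) + 1]),
         numeric(1))
}

# Pure sine as an audio_signal.
tone <- function(freq, dur_s, fs, amp = 1) {
  n <- round(dur_s * fs)
  audio_signal(amp * sin(2 * pi * freq * (0:(n - 1)) / fs), fs = fs)
}

# Linearly separable toy features: class k centered at offset k * sep.
toy_features <- function(n_per_class, d = 16, n_classes = 2, sep = 6,
                         seed = 1, ir_name = "reference", prefix = "toy") {
  set.seed(seed)
  X <- NULL; y <- c(); src <- c()
  for (k in seq_len(n_classes)) {
    Xi <- matrix(stats::rnorm(n_per_class * d), n_per_class, d)
    Xi[, 1] <- Xi[, 1] + k * sep
    X <- rbind(X, Xi)
    y <- c(y, rep(paste0("class", k), n_per_class))
    src <- c(src, paste0(prefix, "_c", k, "_", seq_len(n_per_class)))
  }
  structure(list(X = X, y = y, source_id = src, ir_name = ir_name),
            class = "feature_set")
}

# Small manifest of synthetic recordings written to a temp dir.
tiny_manifest <- function(n_per_class = 4, seed = 7,
                          dir = withr::local_tempdir(.local_envir = parent.frame())) {
  make_dataset(n_per_class, seed = seed, out_dir = dir)
}
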