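# Shared fixtures. Expensive objects are built lazily and cached for the
# whole run.

.fixture_env <- new.env(parent = emptyenv())

# 5 MHz quartz reference device for the Sauerbrey-form arithmetic
quartz_spec <- function() {
  resonatorSpec(f0_hz = 5e6, area_cm2 = 1, rho_q = 2.648, mu_q = 2.947e11)
}

# a fully specified device usable by every operation
full_spec <- function() {
  resonatorSpec(f0_hz = 8500, q = 27.6, diameter_mm = 5, rho_g_cm3 = 1.78,
                thickness_um = 28, rho_q = 2.648, mu_q = 2.947e11)
}

# random complete resonator specs for property loops
random_specs <- function(n, seed = 42) {
  ptfm:::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      resonatorSpec(f0_hz = runif(1, 1e3, 1e7),
                    area_cm2 = runif(1, 0.05, 2),
                    q = runif(1, 5, 500),
                    rho_g_cm3 = runif(1, 1, 8),
                    thickness_um = runif(1, 5, 500),
                    rho_q = runif(1, 1, 8),
                    mu_q = runif(1, 1e10, 1e12))
    })
  })
}

# balanced K-class confusion matrix with a prescribed diagonal total;
# errors are spread as evenly as possible and placed on the next class
balanced_cm <- function(diag_total, per_class = 500L, k = 10L) {
  errs <- per_class * k - diag_total
  base <- errs %/% k
  extra <- errs %% k
  counts <- matrix(0L, k, k)
  for (i in seq_len(k)) {
    e <- base + as.integer(i <= extra)
    counts[i, i] <- per_class - e
    if (e > 0) counts[i, (i %% k) + 1L] <- e
  }
  new("ConfusionMatrix", counts = counts, class_labels = as.numeric(0:(k - 1)))
}

# the well-separated synthetic benchmark: 250 segments/class, spectrally
# disjoint classes (separation_scale 50), 30 dB SNR, stratified 60/20/20
benchmark_dataset <- function() {
  if (is.null(.fixture_env$bench)) {
    ds <- buildDataset(pvdfSpec(), n_per_class = 250, seed = 7,
                       separation_scale = 50)
    .fixture_env$bench <- splitDataset(ds, seed = 7)
  }
  .fixture_env$bench
}

# tiny two-tone toy problem: pure 2 kHz vs 6 kHz tones at 30 dB SNR,
# returned as featurised arrays for a given architecture
two_tone_toy <- function(n_per_class = 75L, seed = 5, snr_db = 30) {
  key <- sprintf("toy_%d_%d", n_per_class, seed)
  if (is.null(.fixture_env[[key]])) {
    fs <- 48000; n <- 4800
    tt <- (seq_len(n) - 1) / fs
    ptfm:::with_seed(seed, {
      sig <- sapply(seq_len(2L * n_per_class), function(i) {
        f <- if (i <= n_per_class) 2000 else 6000
        s <- sin(2 * pi * f * tt + runif(1, 0, 2 * pi))
        s + rnorm(n, sd = sqrt(mean(s^2) / 10^(snr_db / 10)))
      })
      .fixture_env[[key]] <- list(
        wav = sig, y = rep(1:2, each = n_per_class), fs = fs)
    })
  }
  .fixture_env[[key]]
}

# featurise a plain waveform matrix (samples x segments) for one arch
featurize_matrix <- function(wav, fs, arch, frame = 48L, T = 48L,
                             stride = T) {
  B <- ncol(wav); n <- nrow(wav)
  if (arch == "cnn") {
    x <- array(0, dim = c(n, B, 2L))
    for (j in seq_len(B)) x[, j, ] <- dualChannelInput(wav[, j], fs = fs)
  } else if (arch == "lstm") {
    steps <- n %/% frame
    x <- array(0, dim = c(steps, 2L * frame, B))
    for (j in seq_len(B)) {
      dc <- dualChannelInput(wav[, j], fs = fs)
      x[, , j] <- cbind(t(matrix(dc[, 1], nrow = frame)),
                        t(matrix(dc[, 2], nrow = frame)))
    }
  } else {
    np <- floor((n - T) / stride) + 1L
    x <- array(0, dim = c(np, T, B))
    for (j in seq_len(B)) {
      x[, , j] <- patchify(wav[, j], T = T, stride = stride)$patches
    }
  }
  x
}
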