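# Driven-resonator signal generator.

test_that("loaded resonance shifts down linearly and monotonically", {
  sp <- pvdfSpec()
  expect_equal(loadedResonance(sp, 0), 8500)
  # oracle: 8500 - 8500 * (1e-6 / (pi * 0.25^2)) / (2 * 1.78 * 28e-4)
  expect_equal(loadedResonance(sp, 1), 8495.6567, tolerance = 1e-7)
  fr <- loadedResonance(sp, 0:9)
  expect_true(all(diff(fr) < 0))
  expect_lt(fr[10], fr[2])
})

test_that("amplitude response has unit DC gain, peak Q, width fr/Q", {
  sp <- pvdfSpec()
  expect_equal(amplitudeResponse(sp, 0), 1)
  expect_equal(amplitudeResponse(sp, 8500, fr = 8500), sp@Q)
  # dense-grid half-power width around the peak
  f <- seq(7500, 9500, by = 0.05)
  g <- amplitudeResponse(sp, f, fr = 8500)
  half <- max(g) / sqrt(2)
  above <- range(f[g >= half])
  width <- diff(above)
  expect_equal(width, 8500 / sp@Q, tolerance = 0.05)
  expect_equal(width, 308, tolerance = 0.05)
})

test_that("segment synthesis is deterministic and correctly sized", {
  sp <- pvdfSpec()
  a <- synthSegment(sp, delta_m = 3, seed = 21)
  b <- synthSegment(sp, delta_m = 3, seed = 21)
  expect_identical(a@samples, b@samples)
  expect_length(a@samples, 4800)
  expect_identical(a@label, 3)
  d <- synthSegment(sp, delta_m = 3, seed = 22)
  expect_false(identical(a@samples, d@samples))
  expect_lte(max(abs(a@samples)), 1)
})

test_that("noiseless spectrum peaks at the bin nearest the loaded resonance", {
  sp <- pvdfSpec()
  for (m in c(0, 5)) {
    seg <- synthSegment(sp, delta_m = m, noise = noiseSpec(Inf), seed = 4)
    sf <- fftMagnitude(seg)
    fr <- loadedResonance(sp, m)
    expect_equal(which.max(sf$magnitudes), round(fr / sf$bin_hz) + 1L)
  }
})

test_that("zero-amplitude excitation yields pure noise", {
  sp <- pvdfSpec()
  seg <- synthSegment(sp, excitationSpec(amplitude = 0), delta_m = 2,
                      seed = 8)
  tt <- (seq_along(seg@samples) - 1) / seg@fs
  fr <- loadedResonance(sp, 2)
  fit <- summary(stats::lm(seg@samples ~ sin(2 * pi * fr * tt) +
                             cos(2 * pi * fr * tt)))
  expect_lt(fit$r.squared, 0.01)
})

test_that("synthesis rejects Nyquist violations and bad durations", {
  sp <- pvdfSpec()
  expect_error(synthSegment(sp, excitationSpec(frequency_hz = 30000),
                            fs = 48000), "Nyquist")
  expect_error(synthSegment(sp, duration = -0.1), "duration")
})

test_that("square and triangle drives carry the expected harmonics", {
  sp <- pvdfSpec()
  # drive far below resonance so several harmonics survive
  seg <- synthSegment(sp, excitationSpec("square", frequency_hz = 1000),
                      noise = noiseSpec(Inf), seed = 2)
  sf <- fftMagnitude(seg)
  mags <- sf$magnitudes
  at <- function(f_hz) mags[round(f_hz / sf$bin_hz) + 1L]
  # odd harmonics present, even absent
  expect_gt(at(1000), 50 * at(2000))
  expect_gt(at(3000), 50 * at(4000))
  tri <- synthSegment(sp, excitationSpec("triangle", frequency_hz = 1000),
                      noise = noiseSpec(Inf), seed = 2)
  mt <- fftMagnitude(tri)$magnitudes
  expect_gt(mt[101], 50 * mt[201])
})

test_that("realised SNR tracks the requested level within 1 dB", {
  sp <- pvdfSpec()
  target <- 30
  est <- vapply(1:100, function(s) {
    seg <- synthSegment(sp, delta_m = 2, noise = noiseSpec(target), seed = s)
    tt <- (seq_along(seg@samples) - 1) / seg@fs
    fr <- loadedResonance(sp, 2)
    fit <- stats::lm(seg@samples ~ sin(2 * pi * fr * tt) +
                       cos(2 * pi * fr * tt))
    p_sig <- mean(stats::fitted(fit)^2)
    p_noise <- mean(stats::residuals(fit)^2)
    10 * log10(p_sig / p_noise)
  }, numeric(1))
  expect_lt(abs(mean(est) - target), 1)
})

test_that("pink noise option shifts noise energy toward low frequencies", {
  sp <- pvdfSpec()
  white <- synthSegment(sp, excitationSpec(amplitude = 0),
                        noise = noiseSpec(20, pink_fraction = 0), seed = 3)
  pink <- synthSegment(sp, excitationSpec(amplitude = 0),
                       noise = noiseSpec(20, pink_fraction = 1), seed = 3)
  low_share <- function(seg) {
    m2 <- fftMagnitude(seg)$magnitudes^2
    sum(m2[2:240]) / sum(m2[-1]) # below 2.4 kHz vs all
  }
  expect_gt(low_share(pink), 2 * low_share(white))
})

test_that("dominant frequency is monotone in the class label", {
  sp <- pvdfSpec()
  freqs <- vapply(0:9, function(m) {
    seg <- synthSegment(sp, delta_m = m, noise = noiseSpec(Inf),
                        duration = 1, seed = 1)
    as.numeric(dominantFrequency(seg))
  }, numeric(1))
  expect_true(all(diff(freqs) < 0))
})

test_that("dataset construction is balanced, shuffled and reproducible", {
  sp <- pvdfSpec()
  ds <- buildDataset(sp, classes = 0:9, n_per_class = 5, seed = 13)
  expect_equal(dim(ds), c(4800L, 50L))
  expect_equal(as.vector(table(massLabels(ds))), rep(5L, 10))
  expect_false(all(massLabels(ds) == rep(0:9, each = 5))) # randomised order
  ds2 <- buildDataset(sp, classes = 0:9, n_per_class = 5, seed = 13)
  expect_identical(SummarizedExperiment::assay(ds, "waveform"),
                   SummarizedExperiment::assay(ds2, "waveform"))
  ds3 <- buildDataset(sp, classes = 0:9, n_per_class = 5, seed = 14)
  expect_false(identical(SummarizedExperiment::assay(ds, "waveform"),
                         SummarizedExperiment::assay(ds3, "waveform")))
  expect_error(buildDataset(sp, classes = c(1, 1, 2), n_per_class = 2),
               "duplicate")
  # any single segment is reproducible in isolation from its stored seed
  cd <- SummarizedExperiment::colData(ds)
  i <- 17L
  seg <- synthSegment(sp, delta_m = cd$label_ug[i], seed = cd$seed[i])
  expect_identical(seg@samples,
                   SummarizedExperiment::assay(ds, "waveform")[, i])
})

test_that("getSegment round-trips a column with its label", {
  ds <- buildDataset(pvdfSpec(), classes = c(0, 4), n_per_class = 2, seed = 2)
  seg <- getSegment(ds, 3)
  expect_s4_class(seg, "AcousticSegment")
  expect_identical(seg@label, massLabels(ds)[3])
  expect_identical(seg@samples,
                   SummarizedExperiment::assay(ds, "waveform")[, 3])
})
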