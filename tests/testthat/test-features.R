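cfg_small <- stft_config(sample_rate = 8000, n_fft = 256L, hop = 128L)

test_that("Hz/Mel conversion is exact, monotone and invertible", {
  expect_identical(hz_to_mel(0), 0)
  expect_equal(hz_to_mel(700), 2595 * log10(2), tolerance = 1e-12)
  f <- c(50, 1000, 8000)
  expect_lt(max(abs(mel_to_hz(hz_to_mel(f)) - f) / f), 1e-9)
  g <- seq(0, 11025, length.out = 500)
  expect_true(all(diff(hz_to_mel(g)) > 0))
  expect_error(hz_to_mel(-1), "non-negative")
})

test_that("STFT agrees with a naive per-frame DFT oracle", {
  set.seed(5)
  x <- rnorm(8000, sd = 0.2)  # 1 s at the small test rate
  got <- stft_power(audio_signal(x, 8000), cfg_small)
  want <- oracle_stft_power(x, cfg_small$n_fft, cfg_small$hop)
  expect_identical(dim(unclass(got)), dim(want))
  expect_lt(max(abs(got - want)) / max(want), 1e-6)
})

test_that("STFT framing, zeros and tone localization behave", {
  n <- 5000
  z <- stft_power(audio_signal(rep(0, n), 8000), cfg_small)
  expect_equal(ncol(z), 1 + n %/% cfg_small$hop)
  expect_true(all(z == 0))

  # tone at an exact bin center: k * sr / n_fft with k = 32 -> 1000 Hz
  s <- tone(32 * 8000 / 256, 1, 8000)
  sp <- stft_power(s, cfg_small)
  interior <- 3:(ncol(sp) - 3)
  expect_true(all(apply(sp[, interior], 2, which.max) == 33))

  expect_error(stft_power(tone(440, 1, 22050), cfg_small), "resample")
})

test_that("triangular filterbanks are well formed on both scales", {
  fb_lin <- make_filterbank("linear", 1L, cfg_small, fmin = 0, fmax = 4000)
  expect_equal(fb_lin$center_frequencies, 2000)
  peak_bin <- which.max(fb_lin$weights[1, ])
  expect_equal((peak_bin - 1) * 8000 / 256, 2000, tolerance = 8000 / 256)

  fb <- make_filterbank("mel", 40L, cfg_small)
  centers_mel <- hz_to_mel(fb$center_frequencies)
  expect_lt(diff(range(diff(centers_mel))), 1e-6)
  expect_true(all(fb$weights >= 0))

  # single contiguous support with one peak per row
  for (i in c(1, 20, 40)) {
    w <- fb$weights[i, ]
    supp <- which(w > 0)
    expect_true(all(diff(supp) == 1))
    d <- diff(w[supp])
    expect_lte(sum(diff(sign(d)) < 0), 1)
  }

  # every bin between the first and last center is covered
  bin_hz <- (0:(256 / 2)) * 8000 / 256
  inside <- bin_hz > fb$center_frequencies[1] &
    bin_hz < fb$center_frequencies[40]
  expect_true(all(colSums(fb$weights)[inside] > 0))

  expect_error(make_filterbank("mel", 10L, cfg_small, fmax = 6000),
               "Nyquist")
})

test_that("Mel spectrogram honors floor, localization and scale invariance", {
  z <- mel_spectrogram(audio_signal(rep(0, 4000), 8000), cfg_small,
                       n_mels = 32L)
  expect_equal(max(z) - min(z), 0)

  s <- tone(1000, 0.8, 8000)
  m <- mel_spectrogram(s, cfg_small, n_mels = 32L)
  fb <- make_filterbank("mel", 32L, cfg_small)
  expect_equal(which.max(rowMeans(m)),
               which.min(abs(fb$center_frequencies - 1000)))

  # max-referenced dB is gain-invariant (up to the additive floor, which
  # only perturbs cells near the -110 dB floor by hundredths of a dB)
  s2 <- audio_signal(2 * s$samples, 8000)
  expect_lt(max(abs(mel_spectrogram(s2, cfg_small, 32L) - m)), 0.05)
})

test_that("cepstra follow the orthonormal DCT convention", {
  # DCT of a constant log-band vector: c * sqrt(n) then zeros
  n <- 32
  d <- canivox:::dct_matrix(n)
  v <- d %*% rep(2.5, n)
  expect_equal(v[1], 2.5 * sqrt(n), tolerance = 1e-9)
  expect_lt(max(abs(v[-1])), 1e-9)
  # orthonormality
  expect_equal(d %*% t(d), diag(n), tolerance = 1e-9)

  # white noise: coefficient-0 row dominates in mean absolute value
  set.seed(9)
  w <- audio_signal(rnorm(8000, sd = 0.3), 8000)
  mf <- mfcc(w, cfg_small, n_mels = 32L, n_coeffs = 13L)
  ro <- rowMeans(abs(mf))
  expect_identical(which.max(ro), 1L)

  expect_error(mfcc(w, cfg_small, n_mels = 32L, n_coeffs = 64L),
               "must not exceed")
})

test_that("time-shifting a stationary signal by one hop shifts columns", {
  sr <- 8000; hop <- cfg_small$hop
  long <- tone(500, 1, sr)$samples
  n0 <- 6000
  x1 <- audio_signal(long[1:n0], sr)
  x2 <- audio_signal(long[(hop + 1):(hop + n0)], sr)
  m1 <- mfcc(x1, cfg_small, 32L, 13L)
  m2 <- mfcc(x2, cfg_small, 32L, 13L)
  interior <- 4:(ncol(m2) - 4)
  expect_lt(max(abs(m1[, interior + 1L] - m2[, interior])), 1e-6)
})

test_that("LFCC mirrors MFCC but on a linear frequency axis", {
  # all-zero signal: every frame sees the same floor-derived cepstrum
  # (coefficient 0 carries the floor, higher coefficients vanish)
  z <- lfcc(audio_signal(rep(0, 4000), 8000), cfg_small, n_filters = 32L,
            n_coeffs = 13L)
  expect_equal(max(abs(z - z[, 1])), 0)
  expect_lt(max(abs(z[-1, ])), 1e-9)

  # the linear bank devotes more filters to the top of the spectrum,
  # i.e. finer high-frequency resolution than the mel bank
  fb_mel <- make_filterbank("mel", 32L, cfg_small)
  fb_lin <- make_filterbank("linear", 32L, cfg_small)
  expect_gt(sum(fb_lin$center_frequencies > 3000),
            sum(fb_mel$center_frequencies > 3000))
  # and its filter spacing at high frequency is narrower
  expect_lt(diff(tail(fb_lin$center_frequencies, 2)),
            diff(tail(fb_mel$center_frequencies, 2)))
})

test_that("feature images are normalized, resized and conventional", {
  m <- mel_spectrogram(tone(800, 1, 8000), cfg_small, 32L)
  img <- to_image(m)
  expect_identical(dim(unclass(img)), c(256L, 256L))
  expect_gte(min(img), 0)
  expect_lte(max(img), 1)

  const <- structure(base::matrix(3.3, 10, 10), kind = "mel_db",
                     class = c("feature_matrix", "matrix"))
  expect_true(all(to_image(const) == 0.5))

  ramp <- base::matrix(seq(0, 1, length.out = 256 * 256), 256, 256)
  expect_lt(max(abs(to_image(ramp) - ramp)), 1e-9)

  expect_error(to_image(base::matrix(numeric(0), 0, 0)), "empty")
})

test_that("feature extraction is deterministic", {
  s <- tone(700, 0.5, 8000)
  expect_identical(unclass(mfcc(s, cfg_small, 32L, 13L)),
                   unclass(mfcc(s, cfg_small, 32L, 13L)))
  expect_identical(unclass(mel_spectrogram(s, cfg_small, 32L)),
                   unclass(mel_spectrogram(s, cfg_small, 32L)))
})
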