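# Shared fixtures and independent oracles. Oracles are deliberately
# written as plain brute-force loops, independent of the package's
# vectorized implementations.

tone <- function(freq, duration = 1, sr = 22050, amplitude = 1) {
  audio_signal(amplitude * sin(2 * pi * freq * (0:(round(duration * sr) - 1)) / sr),
               sr)
}

# Per-frame RMS by an explicit loop (no cumulative sums).
oracle_frame_rmse <- function(x, K, hop) {
  n_frames <- (length(x) - K) %/% hop + 1
  vapply(seq_len(n_frames), function(t) {
    fr <- x[((t - 1) * hop + 1):((t - 1) * hop + K)]
    s <- 0
    for (v in fr) s <- s + v * v
    sqrt(s / K)
  }, numeric(1))
}

# Naive O(n^2) DFT of one frame.
oracle_dft_power <- function(frame) {
  n <- length(frame)
  k <- 0:(n %/% 2)
  w <- exp(-2i * pi * outer(k, 0:(n - 1)) / n)
  Mod(w %*% frame)^2
}

# Naive STFT: explicit centered reflection padding, frame loop, Hamming
# taper, direct O(n^2) DFT (the transform matrix is built once and applied
# per frame).
oracle_stft_power <- function(x, n_fft, hop) {
  p <- n_fft %/% 2
  n <- length(x)
  pad <- c(rev(x[2:(p + 1)]), x, rev(x[(n - p):(n - 1)]))
  win <- 0.54 - 0.46 * cos(2 * pi * (0:(n_fft - 1)) / (n_fft - 1))
  w <- exp(-2i * pi * outer(0:(n_fft %/% 2), 0:(n_fft - 1)) / n_fft)
  n_frames <- 1 + n %/% hop
  out <- matrix(0, n_fft %/% 2 + 1, n_frames)
  for (t in seq_len(n_frames)) {
    fr <- pad[((t - 1) * hop + 1):((t - 1) * hop + n_fft)] * win
    out[, t] <- Mod(w %*% fr)^2
  }
  out
}

# Spectral peak of a signal via a zero-padded DFT with parabolic
# interpolation (independent frequency estimator).
dominant_frequency <- function(signal) {
  x <- signal$samples
  nfft <- 2^ceiling(log2(length(x)) + 2)
  sp <- Mod(fft(c(x * (0.5 - 0.5 * cos(2 * pi * seq_along(x) / length(x))),
                  rep(0, nfft - length(x)))))[1:(nfft %/% 2)]
  k <- which.max(sp)
  if (k > 1 && k < length(sp)) {
    a <- sp[k - 1]; b <- sp[k]; cc <- sp[k + 1]
    k <- k + 0.5 * (a - cc) / (a - 2 * b + cc)
  }
  (k - 1) * signal$sample_rate / nfft
}

# A deterministic stand-in classifier for pipeline-contract tests that
# need controllable confidences without training: probabilities follow a
# logistic in the image's top-vs-bottom brightness asymmetry, so
# `sharpness` dials confidence up or down.
stub_model <- function(feature_kind = "mel_db", sharpness = 6) {
  m <- build_compact_cnn(feature_kind = feature_kind, seed = 0L)
  m$fit <- list(sharpness = sharpness)
  class(m) <- c("stub_model", class(m))
  m
}

predict.stub_model <- function(object, image, ...) {
  half <- nrow(image) %/% 2
  d <- mean(image[seq_len(half), ]) - mean(image[(half + 1):nrow(image), ])
  p <- 1 / (1 + exp(-object$fit$sharpness * d * 50))
  probs <- c(bark = p, howl = 1 - p)
  structure(list(probabilities = probs,
                 predicted_label = names(probs)[which.max(probs)],
                 confidence = max(probs)),
            class = "canivox_prediction")
}
registerS3method("predict", "stub_model", predict.stub_model,
                 envir = environment(predict.stub_model))
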