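#' Short-time Fourier transform configuration
#'
#' Defaults follow the spectrogram configuration used throughout the
#' package: 22,050 Hz sample rate, 2048-point FFT, hop 512 (75% overlap),
#' Hamming taper.
#'
#' @param sample_rate Sample rate in Hz.
#' @param n_fft FFT size in samples; must be a power of two.
#' @param hop Hop between frame starts in samples; must not exceed `n_fft`.
#' @param window Taper name; only `"hamming"` is supported.
#' @return An object of class `stft_config`.
#' @export
stft_config <- function(sample_rate = 22050, n_fft = 2048L, hop = 512L,
                        window = "hamming") {
  n_fft <- as.integer(n_fft); hop <- as.integer(hop)
  if (bitwAnd(n_fft, n_fft - 1L) != 0L || n_fft < 2L)
    stop("`n_fft` must be a power of two")
  if (hop > n_fft || hop < 1L) stop("`hop` must lie in [1, n_fft]")
  if (!identical(window, "hamming")) stop("unsupported window: ", window)
  structure(list(sample_rate = sample_rate, n_fft = n_fft, hop = hop,
                 window = window),
            class = "stft_config")
}

new_feature_matrix <- function(values, kind, config, n_bands_or_coeffs) {
  structure(values, kind = kind, config = config,
            n_bands_or_coeffs = n_bands_or_coeffs,
            class = c("feature_matrix", "matrix"))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix kind=%s> %d x %d (bands/coeffs x frames)\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  invisible(x)
}

#' Convert frequency in Hz to the Mel scale
#'
#' `m = 2595 * log10(1 + f / 700)`, the perceptual frequency mapping used
#' for the Mel filterbank; strictly increasing in `f`.
#'
#' @param f Frequency in Hz, `f >= 0` (vectorized).
#' @return Mel values.
#' @export
hz_to_mel <- function(f) {
  if (any(f < 0)) stop("frequency must be non-negative")
  2595 * log10(1 + f / 700)
}

#' Convert Mel values back to Hz
#'
#' Exact inverse of [hz_to_mel()].
#'
#' @param m Mel values, `m >= 0` (vectorized).
#' @return Frequency in Hz.
#' @export
mel_to_hz <- function(m) {
  if (any(m < 0)) stop("mel value must be non-negative")
  700 * (10^(m / 2595) - 1)
}

hamming_window <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))

# Frame a signal (centered, reflection padding) into an n_fft x n_frames
# matrix; n_frames = 1 + floor(N / hop).
frame_signal <- function(x, n_fft, hop) {
  n <- length(x)
  p <- n_fft %/% 2L
  if (n < n_fft)
    stop("signal shorter than one FFT frame (", n, " < ", n_fft, ")")
  pad <- c(rev(x[2:(p + 1L)]), x, rev(x[(n - p):(n - 1L)]))
  n_frames <- 1L + n %/% hop
  starts <- (seq_len(n_frames) - 1L) * hop
  idx <- outer(seq_len(n_fft), starts, `+`)
  matrix(pad[idx], nrow = n_fft)
}

#' Power spectrogram by short-time Fourier transform
#'
#' The signal is cut into overlapping frames (centered framing with
#' reflection padding, so the frame count is `1 + floor(N / hop)`), each
#' frame is tapered with a Hamming window to limit spectral leakage, and
#' the squared magnitude of its DFT is kept for bins `0 .. n_fft/2`.
#'
#' @param signal An [audio_signal] whose sample rate matches `config`.
#' @param config An [stft_config].
#' @return A `feature_matrix` of kind `"stft_power"` with `n_fft/2 + 1`
#'   rows and one column per frame.
#' @export
stft_power <- function(signal, config = stft_config()) {
  stopifnot(inherits(signal, "audio_signal"), inherits(config, "stft_config"))
  if (signal$sample_rate != config$sample_rate)
    stop("signal sample rate (", signal$sample_rate,
         ") does not match config (", config$sample_rate,
         "); resample with resample_signal() first")
  frames <- frame_signal(signal$samples, config$n_fft, config$hop)
  frames <- frames * hamming_window(config$n_fft)
  spec <- mvfft(frames)[seq_len(config$n_fft %/% 2L + 1L), , drop = FALSE]
  new_feature_matrix(Mod(spec)^2, "stft_power", config,
                     config$n_fft %/% 2L + 1L)
}

#' Build a triangular filterbank on the Mel or linear frequency scale
#'
#' `n_filters + 2` edge points are spaced equally on the chosen scale
#' between `fmin` and `fmax`; filter i rises linearly from edge i to its
#' peak at edge i+1 and falls to edge i+2. Triangles are peak-normalized
#' (height 1), not area-normalized.
#'
#' @param scale `"mel"` (perceptual spacing) or `"linear"` (equal Hz
#'   spacing, used for LFCCs).
#' @param n_filters Number of triangular filters.
#' @param config An [stft_config] (supplies FFT bin frequencies).
#' @param fmin,fmax Band edges in Hz; `fmax` must not exceed Nyquist.
#' @return An object of class `filterbank`: list with `weights`
#'   (`n_filters` x `n_fft/2 + 1`), `center_frequencies` (Hz), `scale`.
#' @export
make_filterbank <- function(scale = c("mel", "linear"), n_filters = 128L,
                            config = stft_config(), fmin = 0,
                            fmax = config$sample_rate / 2) {
  scale <- match.arg(scale)
  n_filters <- as.integer(n_filters)
  if (n_filters < 1L) stop("`n_filters` must be >= 1")
  if (fmin < 0 || fmin >= fmax) stop("need 0 <= fmin < fmax")
  if (fmax > config$sample_rate / 2)
    stop("`fmax` (", fmax, " Hz) exceeds Nyquist (",
         config$sample_rate / 2, " Hz)")

  edges_hz <- if (scale == "mel") {
    mel_to_hz(seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_filters + 2L))
  } else {
    seq(fmin, fmax, length.out = n_filters + 2L)
  }
  n_bins <- config$n_fft %/% 2L + 1L
  bin_hz <- (seq_len(n_bins) - 1L) * config$sample_rate / config$n_fft

  w <- matrix(0, n_filters, n_bins)
  for (i in seq_len(n_filters)) {
    lo <- edges_hz[i]; ce <- edges_hz[i + 1L]; hi <- edges_hz[i + 2L]
    rise <- (bin_hz - lo) / (ce - lo)
    fall <- (hi - bin_hz) / (hi - ce)
    w[i, ] <- pmax(0, pmin(rise, fall))
  }
  structure(list(weights = w, center_frequencies = edges_hz[2:(n_filters + 1L)],
                 scale = scale, config = config),
            class = "filterbank")
}

DB_FLOOR_EPS <- 1e-10

#' Mel spectrogram in max-referenced decibels
#'
#' The power spectrogram is projected through a triangular Mel filterbank
#' and converted to decibels, `10 * log10(x + 1e-10)`, referenced to the
#' matrix maximum (the loudest cell maps to 0 dB), so the result is
#' invariant to rescaling the input amplitude.
#'
#' @param signal An [audio_signal] at `config$sample_rate`.
#' @param config An [stft_config].
#' @param n_mels Number of Mel bands (default 128).
#' @return A `feature_matrix` of kind `"mel_db"` with `n_mels` rows.
#' @export
mel_spectrogram <- function(signal, config = stft_config(), n_mels = 128L) {
  p <- stft_power(signal, config)
  fb <- make_filterbank("mel", n_mels, config)
  s <- fb$weights %*% unclass(p)
  db <- 10 * log10(s + DB_FLOOR_EPS)
  new_feature_matrix(db - max(db), "mel_db", config, n_mels)
}

# Orthonormal type-II DCT matrix (n x n); row k+1 holds
# c_k * cos(pi * (j + 1/2) * k / n), c_0 = sqrt(1/n), c_k = sqrt(2/n).
dct_matrix <- function(n) {
  k <- 0:(n - 1)
  j <- 0:(n - 1)
  d <- cos(pi * outer(k, j + 0.5) / n)
  d * c(sqrt(1 / n), rep(sqrt(2 / n), n - 1))
}

cepstra <- function(signal, config, scale, n_filters, n_coeffs, kind) {
  if (n_coeffs > n_filters)
    stop("`n_coeffs` (", n_coeffs, ") must not exceed the filter count (",
         n_filters, ")")
  p <- stft_power(signal, config)
  fb <- make_filterbank(scale, n_filters, config)
  log_s <- log(pmax(fb$weights %*% unclass(p), DB_FLOOR_EPS))
  d <- dct_matrix(n_filters)[seq_len(n_coeffs), , drop = FALSE]
  new_feature_matrix(d %*% log_s, kind, config, n_coeffs)
}

#' Mel-frequency cepstral coefficients
#'
#' Natural-log Mel-band energies (floored at 1e-10) are decorrelated per
#' frame by an orthonormal type-II discrete cosine transform; the first
#' `n_coeffs` coefficients are kept.
#'
#' @param signal An [audio_signal] at `config$sample_rate`.
#' @param config An [stft_config].
#' @param n_mels Number of Mel filters (default 128).
#' @param n_coeffs Number of cepstral coefficients kept (default 40).
#' @return A `feature_matrix` of kind `"mfcc"` with `n_coeffs` rows.
#' @export
mfcc <- function(signal, config = stft_config(), n_mels = 128L,
                 n_coeffs = 40L) {
  cepstra(signal, config, "mel", n_mels, n_coeffs, "mfcc")
}

#' Linear-frequency cepstral coefficients
#'
#' Identical construction to [mfcc()] but the triangular filters are spaced
#' equally in Hz, retaining proportionally more high-frequency detail.
#'
#' @param signal An [audio_signal] at `config$sample_rate`.
#' @param config An [stft_config].
#' @param n_filters Number of linear filters (default 128, mirroring the
#'   Mel configuration).
#' @param n_coeffs Number of cepstral coefficients kept (default 40).
#' @return A `feature_matrix` of kind `"lfcc"` with `n_coeffs` rows.
#' @export
lfcc <- function(signal, config = stft_config(), n_filters = 128L,
                 n_coeffs = 40L) {
  cepstra(signal, config, "linear", n_filters, n_coeffs, "lfcc")
}

# 1-D linear interpolation of each row/column onto a new grid.
resize_bilinear <- function(m, out_rows, out_cols) {
  interp_cols <- function(mat, n_out) {
    n_in <- ncol(mat)
    if (n_in == 1L) return(mat[, rep(1L, n_out), drop = FALSE])
    xs <- seq(1, n_in, length.out = n_out)
    t(apply(mat, 1L, function(r) approx(seq_len(n_in), r, xout = xs)$y))
  }
  m <- interp_cols(m, out_cols)
  t(interp_cols(t(m), out_rows))
}

#' Render a feature matrix as a fixed-size normalized image
#'
#' Min-max normalizes the matrix to \[0, 1\] and resizes it to
#' `size` x `size` pixels by bilinear interpolation. Constant matrices map
#' to all-0.5 by convention.
#'
#' @param matrix A non-empty `feature_matrix` (or plain matrix).
#' @param size Output side length in pixels (default 256).
#' @return A `feature_image`: `size` x `size` matrix in \[0, 1\] with
#'   attribute `source_kind`.
#' @export
to_image <- function(matrix, size = 256L) {
  if (length(matrix) == 0L) stop("empty feature matrix")
  kind <- attr(matrix, "kind") %||% "unknown"
  m <- unclass(matrix)
  attributes(m) <- list(dim = dim(m))
  rng <- range(m)
  m <- if (rng[1] == rng[2]) {
    base::matrix(0.5, nrow(m), ncol(m))
  } else {
    (m - rng[1]) / (rng[2] - rng[1])
  }
  img <- resize_bilinear(m, size, size)
  img <- pmin(pmax(img, 0), 1)
  structure(img, source_kind = kind, class = c("feature_image", "matrix"))
}

#' @export
print.feature_image <- function(x, ...) {
  cat(sprintf("<feature_image %dx%d from %s>\n", nrow(x), ncol(x),
              attr(x, "source_kind")))
  invisible(x)
}

#' Export a feature matrix as CSV
#'
#' Rows are frequency bands or cepstral coefficient indices, columns time
#' frames.
#'
#' @param matrix A `feature_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(matrix, path) {
  utils::write.table(unclass(matrix), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
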