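#' Read a WAV file as a mono audio signal
#'
#' Reads RIFF/WAVE files containing PCM 16/24/32-bit or IEEE float32/float64
#' samples with one or two channels. Stereo is reduced to mono by the
#' arithmetic channel mean. Integer PCM codes are rescaled to \[-1, 1) by the
#' full-scale divisor of the bit depth (e.g. 16-bit code 32767 becomes
#' 32767/32768).
#'
#' @param path Path to a readable `.wav` file.
#' @return An [audio_signal].
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  readBin(con, "integer", 1L, size = 4L, endian = "little")  # chunk size
  wave <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id_raw <- readBin(con, "raw", 4L)
    if (length(id_raw) < 4L) break
    id <- rawToChar(id_raw)
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (id == "fmt ") {
      body <- readBin(con, "raw", size + size %% 2L)
      fmt <- list(
        format       = sum(as.integer(body[1:2]) * c(1, 256)),
        channels     = sum(as.integer(body[3:4]) * c(1, 256)),
        sample_rate  = sum(as.integer(body[5:8]) * c(1, 256, 65536, 16777216)),
        bits         = sum(as.integer(body[15:16]) * c(1, 256))
      )
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2L) readBin(con, "raw", 1L)
    } else {
      readBin(con, "raw", size + size %% 2L)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("malformed WAV (no fmt chunk): ", path)
  if (is.null(data_raw)) stop("malformed WAV (no data chunk): ", path)

  x <- decode_wav_samples(data_raw, fmt$format, fmt$bits)
  if (fmt$channels == 2L) {
    x <- (x[seq(1L, length(x), by = 2L)] + x[seq(2L, length(x), by = 2L)]) / 2
  } else if (fmt$channels != 1L) {
    stop("unsupported channel count: ", fmt$channels)
  }
  audio_signal(x, fmt$sample_rate)
}

# Decode the raw data chunk to numeric samples in [-1, 1].
decode_wav_samples <- function(raw, format, bits) {
  if (format == 1L) {  # integer PCM
    if (bits == 16L) {
      readBin(raw, "integer", length(raw) / 2L, size = 2L,
              signed = TRUE, endian = "little") / 32768
    } else if (bits == 24L) {
      b <- as.integer(raw)
      n <- length(b) / 3L
      v <- b[seq(1L, by = 3L, length.out = n)] +
           b[seq(2L, by = 3L, length.out = n)] * 256 +
           b[seq(3L, by = 3L, length.out = n)] * 65536
      v[v >= 8388608] <- v[v >= 8388608] - 16777216
      v / 8388608
    } else if (bits == 32L) {
      readBin(raw, "integer", length(raw) / 4L, size = 4L,
              endian = "little") / 2147483648
    } else {
      stop("unsupported PCM bit depth: ", bits)
    }
  } else if (format == 3L) {  # IEEE float
    if (bits == 32L) {
      readBin(raw, "numeric", length(raw) / 4L, size = 4L, endian = "little")
    } else if (bits == 64L) {
      readBin(raw, "numeric", length(raw) / 8L, size = 8L, endian = "little")
    } else {
      stop("unsupported float bit depth: ", bits)
    }
  } else {
    stop("unsupported WAV encoding (format tag ", format,
         "); only PCM and IEEE float are supported")
  }
}

#' Write a mono audio signal as an IEEE float32 WAV file
#'
#' `read_wav(write_wav(x, p))` reproduces the samples within float32
#' precision and the sample rate exactly.
#'
#' @param signal An [audio_signal] with at least one sample.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path) {
  stopifnot(inherits(signal, "audio_signal"))
  if (length(signal$samples) == 0L) stop("refusing to write a zero-length signal")
  sr <- as.integer(round(signal$sample_rate))
  n <- length(signal$samples)
  data_bytes <- 4L * n

  con <- file(path, "wb")
  on.exit(close(con))
  wr_int <- function(v, size) writeBin(as.integer(v), con, size = size,
                                       endian = "little")
  writeChar("RIFF", con, eos = NULL)
  wr_int(4L + (8L + 18L) + (8L + 4L) + (8L + data_bytes), 4L)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  wr_int(18L, 4L)
  wr_int(3L, 2L)                 # IEEE float
  wr_int(1L, 2L)                 # mono
  wr_int(sr, 4L)
  wr_int(sr * 4L, 4L)            # byte rate
  wr_int(4L, 2L)                 # block align
  wr_int(32L, 2L)                # bits per sample
  wr_int(0L, 2L)                 # cbSize
  writeChar("fact", con, eos = NULL)
  wr_int(4L, 4L)
  wr_int(n, 4L)
  writeChar("data", con, eos = NULL)
  wr_int(data_bytes, 4L)
  writeBin(signal$samples, con, size = 4L, endian = "little")
  invisible(path)
}

#' Resample an audio signal by band-limited polyphase filtering
#'
#' Uses a polyphase FIR anti-aliasing resampler; the total duration is
#' preserved within one sample period and pure tones below both Nyquist
#' limits keep their frequency. Linear interpolation is deliberately not
#' used: cepstral features downstream are sensitive to imaging artifacts.
#'
#' @param signal An [audio_signal].
#' @param target_rate Desired sample rate in Hz (positive integer).
#' @return An [audio_signal] at `target_rate`.
#' @export
resample_signal <- function(signal, target_rate) {
  stopifnot(inherits(signal, "audio_signal"))
  if (length(target_rate) != 1L || !is.finite(target_rate) || target_rate <= 0)
    stop("`target_rate` must be a single positive number")
  sr <- signal$sample_rate
  if (target_rate == sr) return(signal)
  p <- round(target_rate)
  q <- round(sr)
  if (abs(p - target_rate) > 1e-9 || abs(q - sr) > 1e-9)
    stop("resampling requires integer sample rates")
  g <- gcd_int(p, q)
  y <- signal::resample(signal$samples, p / g, q / g)
  audio_signal(as.numeric(y), target_rate)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Peak-normalize an audio signal
#'
#' Scales the signal so that `max(abs(samples)) == 1` while preserving
#' relative sample ratios. An all-zero signal is returned unchanged with a
#' warning.
#'
#' @param signal An [audio_signal].
#' @return A peak-normalized [audio_signal].
#' @export
peak_normalize <- function(signal) {
  stopifnot(inherits(signal, "audio_signal"))
  peak <- if (length(signal$samples)) max(abs(signal$samples)) else 0
  if (peak == 0) {
    warning("all-zero signal; returned unchanged")
    return(signal)
  }
  audio_signal(signal$samples / peak, signal$sample_rate)
}
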