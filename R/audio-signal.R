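#' Construct an audio signal
#'
#' The universal carrier between all processing stages: a finite sequence of
#' real amplitude samples (nominally in \[-1, 1\]) together with its sample
#' rate in Hz.
#'
#' @param samples Numeric vector of amplitudes; all values must be finite.
#' @param sample_rate Samples per second (Hz), a single positive number.
#' @return An object of class `audio_signal` with elements `samples` and
#'   `sample_rate`.
#' @examples
#' x <- audio_signal(sin(2 * pi * 440 * seq(0, 1, by = 1 / 8000)), 8000)
#' duration_seconds(x)
#' @export
audio_signal <- function(samples, sample_rate) {
  samples <- as.numeric(samples)
  if (length(sample_rate) != 1L || !is.finite(sample_rate) || sample_rate <= 0)
    stop("`sample_rate` must be a single positive number")
  if (length(samples) && !all(is.finite(samples)))
    stop("all samples must be finite")
  structure(list(samples = samples, sample_rate = as.numeric(sample_rate)),
            class = "audio_signal")
}

#' Duration of an audio signal in seconds
#'
#' @param signal An [audio_signal].
#' @return `length(samples) / sample_rate`, exactly.
#' @export
duration_seconds <- function(signal) {
  stopifnot(inherits(signal, "audio_signal"))
  length(signal$samples) / signal$sample_rate
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %d samples @ %g Hz (%.3f s), peak %.4f\n",
              length(x$samples), x$sample_rate,
              duration_seconds(x),
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

#' @export
length.audio_signal <- function(x) length(x$samples)
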