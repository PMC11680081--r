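#' Frame-wise root-mean-square energy
#'
#' Slides a length-`frame_length` window across the signal in steps of `hop`
#' samples and computes, for each frame t,
#' `sqrt(mean(s[t*hop + 1 .. t*hop + K]^2))` (0-based frame indexing).
#' Frames that would overrun the signal are not emitted, so the number of
#' frames is `floor((N - K) / hop) + 1`.
#'
#' @param signal An [audio_signal] of length at least `frame_length`.
#' @param frame_length Frame size K in samples (default 1024). The frame
#'   length bounds how far a detected boundary can sit from the true onset,
#'   so the segmentation default is shorter than the spectrogram frame.
#' @param hop Hop between frame starts in samples (default 512).
#' @return A `frame_energy_series`: list with `energies`, `frame_length`,
#'   `hop`, `sample_rate`.
#' @export
frame_rmse <- function(signal, frame_length = 1024L, hop = 512L) {
  stopifnot(inherits(signal, "audio_signal"))
  frame_length <- as.integer(frame_length); hop <- as.integer(hop)
  if (frame_length < 1L || hop < 1L) stop("frame_length and hop must be >= 1")
  n <- length(signal$samples)
  if (n < frame_length)
    stop("signal shorter than one frame (", n, " < ", frame_length,
         "); pad or reject it")
  n_frames <- (n - frame_length) %/% hop + 1L
  cs <- c(0, cumsum(signal$samples^2))
  starts <- (seq_len(n_frames) - 1L) * hop  # 0-based start samples
  energies <- sqrt((cs[starts + frame_length + 1L] - cs[starts + 1L]) /
                     frame_length)
  structure(list(energies = pmax(energies, 0), frame_length = frame_length,
                 hop = hop, sample_rate = signal$sample_rate),
            class = "frame_energy_series")
}

#' @export
print.frame_energy_series <- function(x, ...) {
  cat(sprintf("<frame_energy_series> %d frames (K=%d, hop=%d) @ %g Hz\n",
              length(x$energies), x$frame_length, x$hop, x$sample_rate))
  invisible(x)
}

#' Choose an energy threshold for endpoint detection
#'
#' Three policies: `manual` returns `value` unchanged; `relative` returns
#' `value * max(energies)`; `noise_floor` returns
#' `median(energies) + value * IQR(energies)`, a robust floor estimate for
#' recordings that are mostly silence.
#'
#' @param energy A `frame_energy_series` from [frame_rmse()].
#' @param mode One of `"manual"`, `"relative"`, `"noise_floor"`.
#' @param value Policy parameter: the threshold itself (manual), a fraction
#'   of the peak energy in (0, 1\] (relative), or an IQR multiplier > 0
#'   (noise_floor).
#' @return A single threshold in amplitude units.
#' @export
auto_threshold <- function(energy, mode = c("relative", "manual", "noise_floor"),
                           value = 0.05) {
  stopifnot(inherits(energy, "frame_energy_series"))
  mode <- match.arg(mode)
  if (length(energy$energies) < 1L) stop("need at least one frame")
  if (!is.numeric(value) || length(value) != 1L || value <= 0)
    stop("`value` must be a single positive number")
  switch(mode,
    manual = value,
    relative = {
      if (value > 1) stop("relative `value` must lie in (0, 1]")
      value * max(energy$energies)
    },
    noise_floor = median(energy$energies) + value * IQR(energy$energies)
  )
}

#' Detect voiced segments by energy thresholding
#'
#' Maximal runs of frames with energy strictly above `threshold` become
#' candidate segments; runs separated by a below-threshold gap shorter than
#' `max_gap` seconds are merged; candidates shorter than `min_duration`
#' seconds are discarded. Each segment spans from the first frame's start
#' sample to the last frame's start sample plus the frame length (half-open
#' sample interval, 0-based).
#'
#' @param energy A `frame_energy_series`.
#' @param threshold Energy threshold (amplitude units), > 0.
#' @param min_duration Minimum kept segment duration in seconds (default
#'   0.10).
#' @param max_gap Below-threshold gaps shorter than this (seconds) are
#'   bridged so one bark train stays one segment (default 0.15).
#' @return A data.frame of class `segment_table` with columns
#'   `start_sample`, `end_sample` (half-open), `start_time`, `end_time`,
#'   `duration`; zero rows when nothing exceeds the threshold.
#' @export
detect_endpoints <- function(energy, threshold, min_duration = 0.10,
                             max_gap = 0.15) {
  stopifnot(inherits(energy, "frame_energy_series"))
  if (threshold <= 0) stop("`threshold` must be > 0")
  if (min_duration < 0 || max_gap < 0)
    stop("`min_duration` and `max_gap` must be >= 0")
  sr <- energy$sample_rate
  K <- energy$frame_length
  hop <- energy$hop
  above <- energy$energies > threshold
  if (!any(above)) return(empty_segment_table())

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(first = starts[r$values], last = ends[r$values])

  # samples spanned by a run of frames [first, last] (1-based frame ids)
  run_start <- (runs$first - 1L) * hop
  run_end <- (runs$last - 1L) * hop + K

  # merge runs whose separating gap is shorter than max_gap
  merged_start <- run_start[1]; merged_end <- run_end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  if (nrow(runs) > 1L) {
    for (i in 2:nrow(runs)) {
      gap <- (run_start[i] - merged_end) / sr
      if (gap < max_gap) {
        merged_end <- run_end[i]
      } else {
        out_s <- c(out_s, merged_start); out_e <- c(out_e, merged_end)
        merged_start <- run_start[i]; merged_end <- run_end[i]
      }
    }
  }
  out_s <- c(out_s, merged_start); out_e <- c(out_e, merged_end)

  keep <- (out_e - out_s) / sr >= min_duration
  seg <- data.frame(start_sample = out_s[keep], end_sample = out_e[keep])
  seg$start_time <- seg$start_sample / sr
  seg$end_time <- seg$end_sample / sr
  seg$duration <- seg$end_time - seg$start_time
  class(seg) <- c("segment_table", "data.frame")
  seg
}

empty_segment_table <- function() {
  seg <- data.frame(start_sample = numeric(0), end_sample = numeric(0),
                    start_time = numeric(0), end_time = numeric(0),
                    duration = numeric(0))
  class(seg) <- c("segment_table", "data.frame")
  seg
}

#' Segment a recording with the package's default policy
#'
#' Convenience wrapper tying [frame_rmse()], [auto_threshold()] and
#' [detect_endpoints()] together. The threshold is the chosen policy's
#' value, but never below `silence_floor` (amplitude RMS): relative
#' thresholds are scale-free and would degenerate to ~0 on a signal-free
#' recording, so frames quieter than the floor are never voiced. The
#' default floor of 0.02 assumes the recording is peak-normalized (as the
#' analysis pipeline guarantees) and sits well above an isolated
#' environment's noise floor yet far below any vocalization.
#'
#' @param signal An [audio_signal].
#' @param threshold_mode,threshold_value Threshold policy, see
#'   [auto_threshold()].
#' @param silence_floor Absolute minimum threshold (amplitude RMS).
#' @param min_duration,max_gap Hysteresis in seconds, see
#'   [detect_endpoints()].
#' @param frame_length,hop Energy framing in samples.
#' @return A `segment_table` (possibly empty) with the applied threshold
#'   stored in the `threshold` attribute.
#' @export
segment_recording <- function(signal, threshold_mode = "relative",
                              threshold_value = 0.05, silence_floor = 0.02,
                              min_duration = 0.10, max_gap = 0.15,
                              frame_length = 1024L, hop = 512L) {
  energy <- frame_rmse(signal, frame_length, hop)
  thr <- max(auto_threshold(energy, threshold_mode, threshold_value),
             silence_floor)
  segs <- detect_endpoints(energy, thr, min_duration, max_gap)
  attr(segs, "threshold") <- thr
  segs
}

#' Cut detected segments out of a signal
#'
#' @param signal An [audio_signal].
#' @param segments A `segment_table` from [detect_endpoints()] (half-open,
#'   0-based sample intervals).
#' @return A list of [audio_signal] clips, sample values copied verbatim.
#' @export
extract_segments <- function(signal, segments) {
  stopifnot(inherits(signal, "audio_signal"), is.data.frame(segments))
  n <- length(signal$samples)
  lapply(seq_len(nrow(segments)), function(i) {
    s <- segments$start_sample[i]; e <- segments$end_sample[i]
    if (s < 0 || e > n || s >= e)
      stop(sprintf("segment %d [%d, %d) out of bounds for signal of length %d",
                   i, s, e, n))
    audio_signal(signal$samples[(s + 1):e], signal$sample_rate)
  })
}

#' Export segments as CSV or annotation-tool label rows
#'
#' `format = "csv"` writes `start_time,end_time,duration`;
#' `format = "labels"` writes tab-separated `start<TAB>end<TAB>label` rows
#' as used by common audio-annotation tools.
#'
#' @param segments A `segment_table`.
#' @param path Output file path.
#' @param format `"csv"` or `"labels"`.
#' @param label Label text used in `"labels"` format (default `"voiced"`);
#'   recycled across rows.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path, format = c("csv", "labels"),
                           label = "voiced") {
  format <- match.arg(format)
  if (format == "csv") {
    write.csv(segments[, c("start_time", "end_time", "duration")], path,
              row.names = FALSE)
  } else {
    df <- data.frame(start = segments$start_time, end = segments$end_time,
                     label = rep_len(label, nrow(segments)))
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
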