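#' Estimate the mean pitch of a clip by normalized autocorrelation
#'
#' Frames of 2048 samples (hop 512) are scanned; in each frame the
#' normalized autocorrelation is maximized over lags corresponding to
#' \[`fmin`, `fmax`\]. A frame is voiced when the peak exceeds the voicing
#' threshold (0.5); among local maxima within 90% of the global peak the
#' smallest lag is chosen (guarding against octave-down errors) and
#' refined by parabolic interpolation. The mean fundamental over voiced
#' frames is returned, or `NA` when no frame is voiced.
#'
#' @param clip An [audio_signal] at least two periods of `fmin` long.
#' @param fmin,fmax Pitch search range in Hz (default 100-2000).
#' @param frame_length,hop Analysis framing in samples.
#' @param voicing_threshold Normalized-correlation threshold for a frame
#'   to count as voiced.
#' @return Mean fundamental in Hz, or `NA_real_` if unvoiced.
#' @export
estimate_pitch <- function(clip, fmin = 100, fmax = 2000,
                           frame_length = 2048L, hop = 512L,
                           voicing_threshold = 0.5) {
  stopifnot(inherits(clip, "audio_signal"))
  if (fmin >= fmax) stop("need fmin < fmax")
  sr <- clip$sample_rate
  x <- clip$samples
  if (length(x) < 2 * sr / fmin)
    stop("clip shorter than two periods of fmin")
  frame_length <- min(frame_length, length(x))
  lag_min <- max(2L, floor(sr / fmax))
  lag_max <- min(frame_length - 2L, ceiling(sr / fmin))
  starts <- seq(1L, length(x) - frame_length + 1L, by = hop)

  pitches <- numeric(0)
  for (s in starts) {
    fr <- x[s:(s + frame_length - 1L)]
    fr <- fr - mean(fr)
    if (sum(fr^2) == 0) next
    r <- frame_nacf(fr, lag_min, lag_max)
    r_max <- max(r)
    if (!is.finite(r_max) || r_max < voicing_threshold) next
    # local maxima within 90% of the global peak; take the smallest lag
    n <- length(r)
    is_peak <- c(FALSE, r[2:(n - 1)] >= r[1:(n - 2)] &
                        r[2:(n - 1)] >= r[3:n], FALSE)
    cand <- which(is_peak & r >= 0.9 * r_max)
    if (!length(cand)) cand <- which.max(r)
    j <- cand[1]
    lag <- lag_min + j - 1L
    # parabolic refinement
    if (j > 1L && j < n) {
      denom <- r[j - 1] - 2 * r[j] + r[j + 1]
      if (denom < 0) lag <- lag + 0.5 * (r[j - 1] - r[j + 1]) / denom
    }
    pitches <- c(pitches, sr / lag)
  }
  if (!length(pitches)) NA_real_ else mean(pitches)
}

# Normalized autocorrelation of one frame over a lag range.
frame_nacf <- function(fr, lag_min, lag_max) {
  n <- length(fr)
  cs <- c(0, cumsum(fr^2))
  vapply(lag_min:lag_max, function(l) {
    a <- fr[1:(n - l)]; b <- fr[(1 + l):n]
    den <- sqrt((cs[n - l + 1] - cs[1]) * (cs[n + 1] - cs[l + 1]))
    if (den == 0) 0 else sum(a * b) / den
  }, numeric(1))
}

#' Whole-segment root-mean-square energy
#'
#' The frame energy statistic applied with a single frame spanning the
#' entire clip.
#'
#' @param clip A non-empty [audio_signal].
#' @return A single non-negative RMS value.
#' @export
segment_energy <- function(clip) {
  stopifnot(inherits(clip, "audio_signal"))
  if (!length(clip$samples)) stop("empty clip")
  sqrt(mean(clip$samples^2))
}

#' Fully automatic vocalization analysis of a recording
#'
#' Runs the complete offline system: the recording is resampled to the
#' model's rate and peak-normalized, voiced segments are detected by
#' frame-energy endpoint detection, each segment is featurized and
#' classified, and segments whose top class probability falls below
#' `reject_threshold` are labeled `"environmental"`. Per segment the
#' label, confidence, duration, mean pitch and RMS energy are reported,
#' plus per-class counts and total durations.
#'
#' @param recording A non-empty [audio_signal].
#' @param model A trained `canivox_model`.
#' @param reject_threshold Minimum classification confidence in \[0, 1\]
#'   for a bark/howl label (default 0.70).
#' @param threshold_mode,threshold_value,silence_floor Energy threshold
#'   policy, see [segment_recording()].
#' @param min_duration,max_gap Endpoint-detection hysteresis in seconds,
#'   see [detect_endpoints()].
#' @param frame_length,hop Energy framing in samples.
#' @param stft An [stft_config] used for feature extraction.
#' @param source Optional source identity string recorded in the summary.
#' @return An `analysis_summary`: list with `segments` (data.frame ordered
#'   by start time: `segment`, `label`, `confidence`, `start_time`,
#'   `end_time`, `duration`, `mean_pitch`, `rms_energy`), `totals`
#'   (per-class `count` and `total_duration`, including environmental),
#'   `source`, `config`.
#' @export
analyze <- function(recording, model, reject_threshold = 0.70,
                    threshold_mode = "relative", threshold_value = 0.05,
                    silence_floor = 0.02, min_duration = 0.10,
                    max_gap = 0.15, frame_length = 1024L, hop = 512L,
                    stft = stft_config(), source = "recording") {
  stopifnot(inherits(recording, "audio_signal"),
            inherits(model, "canivox_model"))
  if (!length(recording$samples)) stop("empty recording")
  if (reject_threshold < 0 || reject_threshold > 1)
    stop("`reject_threshold` must lie in [0, 1]")

  if (recording$sample_rate != stft$sample_rate)
    recording <- resample_signal(recording, stft$sample_rate)
  if (max(abs(recording$samples)) > 0)
    recording <- peak_normalize(recording)

  segs <- segment_recording(recording, threshold_mode, threshold_value,
                            silence_floor, min_duration, max_gap,
                            frame_length, hop)
  clips <- extract_segments(recording, segs)

  is_baseline <- startsWith(model$architecture %||% "", "baseline_")
  rows <- lapply(seq_along(clips), function(i) {
    clip <- clips[[i]]
    fm <- featurize_clip(clip, model$feature_kind, stft)
    # CNN-family models consume fixed-size images; classical baselines
    # pool the raw feature matrix exactly as they did in training
    pred <- predict(model, if (is_baseline) fm else to_image(fm))
    label <- if (pred$confidence >= reject_threshold)
      pred$predicted_label else "environmental"
    pitch <- tryCatch(estimate_pitch(clip), error = function(e) NA_real_)
    data.frame(segment = i, label = label, confidence = pred$confidence,
               start_time = segs$start_time[i], end_time = segs$end_time[i],
               duration = segs$duration[i], mean_pitch = pitch,
               rms_energy = segment_energy(clip))
  })
  segments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(segment = integer(0), label = character(0),
               confidence = numeric(0), start_time = numeric(0),
               end_time = numeric(0), duration = numeric(0),
               mean_pitch = numeric(0), rms_energy = numeric(0))

  classes <- c(model$class_order, "environmental")
  totals <- data.frame(
    class = classes,
    count = vapply(classes, function(cl) sum(segments$label == cl),
                   numeric(1)),
    total_duration = vapply(classes, function(cl)
      sum(segments$duration[segments$label == cl]), numeric(1)),
    row.names = NULL)

  structure(list(segments = segments, totals = totals, source = source,
                 config = list(reject_threshold = reject_threshold,
                               threshold_mode = threshold_mode,
                               threshold_value = threshold_value,
                               silence_floor = silence_floor,
                               min_duration = min_duration,
                               max_gap = max_gap,
                               frame_length = frame_length, hop = hop,
                               sample_rate = stft$sample_rate,
                               n_fft = stft$n_fft, stft_hop = stft$hop,
                               feature_kind = model$feature_kind,
                               architecture = model$architecture)),
            class = "analysis_summary")
}

#' @export
print.analysis_summary <- function(x, ...) {
  cat(render_report(x, "text"))
  invisible(x)
}

#' Serialize an analysis summary
#'
#' Deterministic rendering as canonical JSON, CSV (one row per segment),
#' or human-readable text listing each segment and the per-class totals.
#'
#' @param summary An `analysis_summary` from [analyze()].
#' @param format `"json"`, `"csv"` or `"text"`.
#' @param path Optional output file; when given, the document is written
#'   there as well.
#' @return The document as a single character string.
#' @export
render_report <- function(summary, format = c("json", "csv", "text"),
                          path = NULL) {
  stopifnot(inherits(summary, "analysis_summary"))
  format <- match.arg(format)
  doc <- switch(format,
    json = as.character(jsonlite::toJSON(unclass(summary),
                                         auto_unbox = TRUE, digits = NA,
                                         dataframe = "columns", na = "null",
                                         pretty = TRUE)),
    csv = {
      con <- textConnection("out", "w", local = TRUE)
      write.csv(summary$segments, con, row.names = FALSE)
      close(con)
      paste0(paste(out, collapse = "\n"), "\n")
    },
    text = {
      lines <- c(sprintf("Vocalization analysis: %s", summary$source),
                 sprintf("segments: %d", nrow(summary$segments)))
      for (i in seq_len(nrow(summary$segments))) {
        s <- summary$segments[i, ]
        lines <- c(lines, sprintf(
          "  #%d %-13s %7.3f-%7.3f s (%.3f s)  conf %.3f  pitch %s  energy %.4f",
          s$segment, s$label, s$start_time, s$end_time, s$duration,
          s$confidence,
          if (is.na(s$mean_pitch)) "   n/a" else sprintf("%6.1f Hz",
                                                         s$mean_pitch),
          s$rms_energy))
      }
      lines <- c(lines, "per-class totals:")
      for (i in seq_len(nrow(summary$totals))) {
        tt <- summary$totals[i, ]
        lines <- c(lines, sprintf("  %-13s count %3d  total %.3f s",
                                  tt$class, tt$count, tt$total_duration))
      }
      paste0(paste(lines, collapse = "\n"), "\n")
    })
  if (!is.null(path)) writeLines(doc, path, sep = "")
  doc
}
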