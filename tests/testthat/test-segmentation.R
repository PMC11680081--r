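test_that("frame RMS energy matches hand arithmetic and closed forms", {
  x <- audio_signal(rep(0.5, 64), 8000)
  e <- frame_rmse(x, 4, 4)
  expect_equal(e$energies, rep(0.5, 16))
  expect_equal(length(e$energies), (64 - 4) %/% 4 + 1)

  e2 <- frame_rmse(audio_signal(c(3, 4, 0, 0), 8000), 4, 4)
  expect_equal(e2$energies, 2.5)

  # one full period of a sinusoid: RMS = A / sqrt(2)
  A <- 0.8
  per <- audio_signal(A * sin(2 * pi * (0:1023) / 1024), 8000)
  expect_equal(frame_rmse(per, 1024, 1024)$energies, A / sqrt(2),
               tolerance = 1e-6)

  expect_error(frame_rmse(audio_signal(1:3 / 10, 8000), 4, 4), "pad or reject")
})

test_that("frame RMS energy agrees with a brute-force loop oracle", {
  set.seed(42)
  for (n in c(5000, 100000)) {
    x <- rnorm(n, sd = 0.3)
    for (cfg in list(c(1024, 512), c(2048, 512), c(100, 37))) {
      got <- frame_rmse(audio_signal(x, 22050), cfg[1], cfg[2])$energies
      want <- oracle_frame_rmse(x, cfg[1], cfg[2])
      expect_equal(length(got), length(want))
      expect_lt(max(abs(got - want)) / max(want), 1e-9)
    }
  }
})

test_that("energy is homogeneous of degree one in the signal", {
  set.seed(7)
  x <- rnorm(10000)
  e1 <- frame_rmse(audio_signal(x, 22050))$energies
  e2 <- frame_rmse(audio_signal(3.5 * x, 22050))$energies
  expect_equal(e2, 3.5 * e1, tolerance = 1e-12)
})

test_that("threshold policies behave as documented", {
  e <- frame_rmse(audio_signal(rep(0.5, 4096), 8000))
  expect_identical(auto_threshold(e, "manual", 0.02), 0.02)

  e$energies <- c(rep(0.1, 5), 2.5)
  expect_equal(auto_threshold(e, "relative", 0.1), 0.25)

  # noise_floor via direct order statistics (type-7 quantiles)
  vals <- c(rep(0.01, 90), rep(1.0, 10))
  e$energies <- vals
  srt <- sort(vals)
  q <- function(p) {
    h <- (length(srt) - 1) * p + 1
    lo <- floor(h)
    srt[lo] + (h - lo) * (srt[min(lo + 1, length(srt))] - srt[lo])
  }
  expect_equal(auto_threshold(e, "noise_floor", 3),
               q(0.5) + 3 * (q(0.75) - q(0.25)))

  expect_error(auto_threshold(e, "relative", 1.5), "0, 1")
  expect_error(auto_threshold(e, "relative", -1), "positive")
})

test_that("endpoint detection matches a brute-force frame scan", {
  sr <- 8000; K <- 64L; hop <- 32L
  mk_energy <- function(vals) {
    structure(list(energies = vals, frame_length = K, hop = hop,
                   sample_rate = sr),
              class = "frame_energy_series")
  }
  # all silent
  expect_identical(nrow(detect_endpoints(mk_energy(rep(0.01, 50)), 0.5)), 0L)

  # frames 11..21 (1-based) above threshold: segment [10*hop, 20*hop + K)
  vals <- rep(0.01, 40); vals[11:21] <- 1
  seg <- detect_endpoints(mk_energy(vals), 0.5, min_duration = 0,
                          max_gap = 0)
  expect_equal(seg$start_sample, 10 * hop)
  expect_equal(seg$end_sample, 20 * hop + K)

  # two bursts: gap longer than max_gap stays split, shorter merges
  vals <- rep(0.01, 60); vals[6:10] <- 1; vals[31:35] <- 1
  gap_sec <- ((30 * hop) - (9 * hop + K)) / sr
  split <- detect_endpoints(mk_energy(vals), 0.5, min_duration = 0,
                            max_gap = gap_sec * 0.9)
  expect_identical(nrow(split), 2L)
  merged <- detect_endpoints(mk_energy(vals), 0.5, min_duration = 0,
                             max_gap = gap_sec * 1.1)
  expect_identical(nrow(merged), 1L)
  expect_equal(merged$start_sample, 5 * hop)
  expect_equal(merged$end_sample, 34 * hop + K)

  # min_duration discards short candidates
  vals <- rep(0.01, 60); vals[6:7] <- 1
  dur <- (6 * hop + K - 5 * hop) / sr
  expect_identical(nrow(detect_endpoints(mk_energy(vals), 0.5,
                                         min_duration = dur * 1.01)), 0L)
})

test_that("detected segments are disjoint, sorted and long enough", {
  set.seed(11)
  for (rep_i in 1:5) {
    vals <- runif(200) > 0.6
    e <- structure(list(energies = ifelse(vals, 1, 0.01) * runif(200, 0.9, 1.1),
                        frame_length = 1024L, hop = 512L,
                        sample_rate = 22050),
                   class = "frame_energy_series")
    seg <- detect_endpoints(e, 0.5, min_duration = 0.1, max_gap = 0.05)
    if (nrow(seg) > 1) {
      expect_true(all(diff(seg$start_sample) > 0))
      expect_true(all(seg$start_sample[-1] >= seg$end_sample[-nrow(seg)]))
    }
    expect_true(all(seg$duration >= 0.1))
  }
})

test_that("segment extraction copies sample ranges verbatim", {
  x <- audio_signal(seq(0, 1, length.out = 1000), 8000)
  seg <- data.frame(start_sample = c(0, 100, 500),
                    end_sample = c(100, 500, 1000))
  clips <- extract_segments(x, seg)
  expect_identical(clips[[2]]$samples, x$samples[101:500])
  expect_identical(unlist(lapply(clips, `[[`, "samples")), x$samples)

  whole <- extract_segments(x, data.frame(start_sample = 0,
                                          end_sample = 1000))[[1]]
  expect_identical(whole$samples, x$samples)
  expect_error(extract_segments(x, data.frame(start_sample = 900,
                                              end_sample = 1100)),
               "out of bounds")
})

test_that("synthetic events are recovered with small boundary error", {
  events <- list()
  onset <- 0.5
  set.seed(3)
  for (i in 1:8) {
    if (i %% 2) {
      ev <- event_spec("bark", onset = onset, duration = 0.08,
                       fundamental = 600, amplitude = 0.8, pulse_count = 3,
                       gap = 0.08)
    } else {
      ev <- event_spec("howl", onset = onset, duration = 1.2,
                       fundamental = 450, amplitude = 0.6)
    }
    events[[i]] <- ev
    onset <- onset + event_total_duration(ev) + runif(1, 0.7, 1.0)
  }
  rec <- synth_recording(events, onset + 0.5, noise_floor = 0.005, seed = 1)
  segs <- segment_recording(rec$signal)
  expect_equal(nrow(segs), nrow(rec$truth))
  hop <- 512
  for (i in seq_len(nrow(rec$truth))) {
    err_s <- abs(segs$start_sample[i] - rec$truth$start_sample[i])
    err_e <- abs(segs$end_sample[i] - rec$truth$end_sample[i])
    expect_lte(err_s, 2 * hop)
    expect_lte(err_e, 2 * hop)
  }
})

test_that("segments export as CSV and annotation label rows", {
  seg <- detect_endpoints(structure(list(energies = c(0.01, 1, 1, 0.01),
                                         frame_length = 64L, hop = 32L,
                                         sample_rate = 8000),
                                    class = "frame_energy_series"),
                          0.5, min_duration = 0)
  p <- withr::local_tempfile(fileext = ".csv")
  write_segments(seg, p)
  got <- read.csv(p)
  expect_identical(names(got), c("start_time", "end_time", "duration"))
  p2 <- withr::local_tempfile(fileext = ".txt")
  write_segments(seg, p2, "labels", label = "voiced")
  row <- strsplit(readLines(p2)[1], "\t")[[1]]
  expect_identical(length(row), 3L)
  expect_identical(row[3], "voiced")
})
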