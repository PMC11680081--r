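# canivox

Automatic segmentation and classification of canine vocalizations.

`canivox` is an R package for bioacoustics and animal-behavior
researchers who collect long audio recordings of dogs and need the
vocal events in them found, labeled and summarized without manual
review. It implements a fully automatic offline analysis system:

1. **Segmentation** — voiced regions are detected by frame-wise
   root-mean-square energy,
   RMSE(t) = sqrt( (1/K) Σₖ s(k)² ) over frames of K samples,
   with endpoint detection (threshold, gap-merging, minimum duration).
2. **Feature extraction** — each segment is transformed by a short-time
   Fourier transform (Hamming window, FFT 2048, hop 512 at 22,050 Hz)
   into a 128-band Mel spectrogram (m = 2595·log10(1 + f/700)), MFCCs or
   LFCCs (40 orthonormal-DCT coefficients over 128 triangular bands),
   rendered as a 256×256 normalized image.
3. **Classification** — a compact convolutional network (four 3×3 conv
   blocks, 16/32/64/128 channels, ReLU, max pooling, global average
   pooling, dropout 0.5, softmax) trained from scratch with Adam;
   classical baselines (SVM, k-NN, random forest, naive Bayes) on pooled
   features share the same split and metrics contract.
4. **Rejection and reporting** — segments whose top class probability
   falls below a confidence threshold are labeled *environmental*; the
   report lists each segment's label, confidence, duration, mean pitch
   (normalized autocorrelation) and RMS energy, plus per-class counts
   and total durations.

An evaluation layer provides confusion matrices, per-class
precision/recall/F1 with macro and weighted averages, and a one-way
ANOVA for comparing classifier families, and a seeded synthetic
bark/howl generator makes every stage testable with no external data.

## Worked example

Train a classifier on a seeded synthetic corpus and analyze a synthetic
recording containing a howl, a bark train, and an environmental noise
burst:

```r
library(canivox)

corpus <- synth_corpus(n_bark = 20, n_howl = 20, seed = 1)
cfg    <- train_config("mel_db", seed = 1L)
model  <- fit_baseline(corpus, "mel_db", "tree_ensemble", cfg)

events <- list(
  event_spec("howl",  onset = 0.5, duration = 1.4,  fundamental = 520,
             amplitude = 0.8),
  event_spec("bark",  onset = 3.0, duration = 0.08, fundamental = 700,
             amplitude = 0.7, pulse_count = 4, gap = 0.09),
  event_spec("noise", onset = 5.0, duration = 0.6,  amplitude = 0.5))
rec <- synth_recording(events, total_duration = 6.5,
                       noise_floor = 0.005, seed = 2)

summary <- analyze(rec$signal, model, reject_threshold = 0.75,
                   source = "demo")
cat(render_report(summary, "text"))
```

```
Vocalization analysis: demo
segments: 3
  #1 howl            0.488-  1.927 s (1.440 s)  conf 0.994  pitch  520.0 Hz  energy 0.5395
  #2 bark            2.972-  3.599 s (0.627 s)  conf 1.000  pitch    n/a  energy 0.0925
  #3 environmental   4.969-  5.619 s (0.650 s)  conf 0.700  pitch    n/a  energy 0.1369
per-class totals:
  bark          count   1  total 0.627 s
  howl          count   1  total 1.440 s
  environmental count   1  total 0.650 s
```

All three events are found within ~50 ms of their true boundaries. The
howl is labeled with confidence 0.994 and its fundamental recovered at
520 Hz; the bark train is kept as one segment (gap merging) and, being a
percussive pulse train, reports no stable pitch; the noise burst only
musters 0.700 confidence and is rejected as environmental sound. The
per-class totals are what a veterinarian reads: how often and how long
the animal barked and howled.

To train the convolutional network instead:

```r
cfg   <- train_config("mel_db", epochs = 100L, seed = 0L,
                      early_stop_patience = 10L)
split <- split_dataset(corpus, cfg)
cnn   <- build_compact_cnn(feature_kind = "mel_db", seed = 0L)
cnn   <- train_model(cnn, corpus[split$train], cfg)
save_model(cnn, "cnn-mel.rds")
```

A command-line wrapper with `synth`, `segment`, `featurize`, `train`,
`evaluate` and `analyze` subcommands is installed at
`system.file("scripts", "canivox", package = "canivox")`.

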