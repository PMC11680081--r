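---
title: "Methods: automatic segmentation and classification of canine vocalizations"
author: "canivox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automatic segmentation and classification of canine vocalizations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the system

Bioacoustic recordings of dogs are long, and the behaviorally interesting
material — barks and howls — occupies a small fraction of them. `canivox`
implements a fully automatic offline analysis system: a raw recording is
segmented into voiced regions by frame energy, each region is converted
into a spectral image, a classifier assigns it to *bark* or *howl*, and
regions the classifier is not confident about are set aside as
*environmental* sound. The system reports, per segment, the label,
confidence, duration, mean pitch and RMS energy, and per class the count
and total duration — the quantities a veterinarian or ethologist actually
reads.

```{r}
library(canivox)
model <- load_model("cnn-mel.rds")
summary <- analyze(read_wav("kennel-recording.wav"), model)
render_report(summary, "text")
```

## Segmentation by frame energy

The detection statistic is the root-mean-square energy of a frame of
$K$ samples starting at hop multiple $t$:

$$\mathrm{RMSE}(t) \;=\; \sqrt{\tfrac{1}{K} \textstyle\sum_{k = tH}^{tH+K-1} s(k)^2},$$

where $s(k)$ is the $k$-th sample and $H$ the hop. Frames whose energy
exceeds a threshold are voiced; maximal voiced runs become segments, runs
separated by a sub-threshold gap shorter than `max_gap` (default 0.15 s)
are merged so that one bark train stays one segment, and candidates
shorter than `min_duration` (default 0.10 s) are dropped. A segment spans
from its first frame's start sample to its last frame's start plus $K$
(half-open, 0-based).

Two framing choices deserve justification:

* **Energy frame length $K = 1024$, hop $H = 512$** (46 ms / 23 ms at
  22,050 Hz, 50% overlap). The frame length bounds how far a detected
  boundary can sit from a true onset: a loud event is picked up as soon
  as a frame overlaps it by a handful of samples, so the onset bias is
  close to $K$ in the worst case. With $K = 1024$ that worst case stays
  within two hops, which is what the segmentation recovery tests assert.
  A longer frame (e.g. the 2048-sample spectrogram frame) would double
  that bias for no detection benefit; keeping the hop at 512 leaves the
  energy frames on the same hop grid as the spectrogram.
* **Threshold policy.** `auto_threshold()` offers `manual` (a fixed
  value, appropriate for the isolated, low-noise environments the system
  targets), `relative` (a fraction of the peak frame energy; the default
  is 0.05) and `noise_floor` (median + multiple of the IQR, robust when
  most of a recording is silence). A purely relative threshold
  degenerates on a recording that contains *no* signal — five percent of
  the noise peak is still noise — so the convenience wrapper
  `segment_recording()` additionally imposes an absolute *silence floor*
  of 0.02 RMS (on the peak-normalized scale the pipeline guarantees):
  frames quieter than that are never voiced. The floor sits an order of
  magnitude above the 0.005 noise floor of an isolated environment and
  an order of magnitude below any vocalization frame.

## The feature stack

All features start from a short-time Fourier transform with the fixed
configuration: 22,050 Hz sample rate, 2048-point FFT, hop 512, Hamming
taper. Recordings at other rates are resampled on ingest with a
polyphase FIR resampler (band-limited; linear interpolation is avoided
because cepstra are sensitive to imaging artifacts). Framing is centered
with reflection padding, so a signal of $N$ samples yields
$1 + \lfloor N/H \rfloor$ frames.

* **Mel spectrogram** — the power spectrogram is projected through 128
  triangular filters whose edges are equally spaced in Mel,
  $m = 2595\,\log_{10}(1 + f/700)$, between 0 Hz and Nyquist. Triangles
  are peak-normalized (height 1), not area-normalized. The band image is
  converted to decibels, $10\log_{10}(x + 10^{-10})$, referenced to the
  matrix maximum, which makes it invariant to input gain.
* **MFCC** — natural-log Mel-band energies (floored at $10^{-10}$) are
  decorrelated per frame by an orthonormal type-II DCT; the first 40
  coefficients are kept. The orthonormal scaling gives the convenient
  identity that a constant log-band vector $c$ maps to coefficient
  $c\sqrt{n}$ followed by zeros, which the tests exploit.
* **LFCC** — identical construction with 128 *linearly* spaced filters
  (mirroring the Mel configuration; the linear bank retains
  proportionally more high-frequency detail).
* **Feature images** — classifiers consume fixed 256×256 renderings:
  per-image min–max normalization to $[0,1]$ followed by bilinear
  resizing. A constant matrix maps to all-0.5 by convention. Per-image
  (rather than per-dataset) normalization was chosen so that inference
  on a single segment needs no dataset statistics.

## The classifier

The default classifier is a compact convolutional network trained from
scratch:

* a fixed (non-learned) 4×4 average-pooling stem on the 256×256 input —
  feature images are smooth at full resolution, and pooling to 64×64
  loses nothing measurable while cutting the convolution cost sixteenfold,
  which is what makes CPU-only training practical;
* four convolution blocks (3×3 kernels, 'same' padding, ReLU, 2×2 max
  pooling) with 16/32/64/128 channels;
* global average pooling, a 128-unit dense layer with dropout 0.5, and a
  softmax output.

Training minimizes categorical cross-entropy with Adam (default learning
rate $10^{-3}$), batch size 32, on an 80/20 split with a fixed random
state. The split is unstratified by default (a stratified option
exists). The epoch default of 700 matches the experiment design the
package reproduces; desk-scale runs instead pass `epochs = 100` with
early stopping (patience 10 on a 15% validation split), which converges
on the synthetic corpus in well under a hundred epochs. Every stochastic
ingredient — split, initialization, shuffling, dropout — is funneled
through one integer seed, so runs are bit-reproducible.

Deeper backbones (AlexNet-class and beyond) are treated as pluggable
architecture identifiers behind the same train/predict contract;
reproducing their pretrained weights is out of scope, and the
comparisons the package supports are architecture-level.

The classical baselines (SVM with RBF kernel, k-nearest neighbors,
random forest, Gaussian naive Bayes) consume the same features pooled to
a fixed-length vector — the per-row mean and standard deviation of the
feature matrix — standardized by training statistics. They share the
split machinery so comparisons against the CNN are paired.

## Evaluation layer

`classification_report()` computes per-class precision, recall, F1 and
support from a confusion matrix, overall accuracy, and macro (unweighted)
and weighted (support-weighted) averages. Metrics with a zero
denominator are reported as 0 and flagged — never silently dropped.
Published two-decimal tables are matched with half-up rounding
(`round_half_up()`), applied only in comparison harnesses, never inside
the metrics.

`one_way_anova()` implements the textbook between/within decomposition
($F = \mathrm{MSB}/\mathrm{MSW}$) with the p-value from the upper tail
of the F distribution. Applied to the bundled nine-model benchmark
(27 weighted-average F1 scores, three feature sets per model) it yields
$F(8, 18) = 5.05$, $p \approx 0.002$ — the packaged regression test for
the evaluation layer. The repeated-measures structure of that benchmark
(the same test set under three feature sets) is deliberately ignored:
the one-way analysis is what the package implements, and the limitation
is acknowledged here rather than corrected.

## The automatic pipeline

`analyze()` chains the stages and adds the rejection rule: a segment
keeps its predicted label only when the classifier's top probability
reaches `reject_threshold`; otherwise it is labeled *environmental*.
The default threshold is 0.70: with a two-class softmax, a threshold at
0.5 would never reject anything, while 0.70 demands a clear margin and
gives the environmental path real behavior. Confidence here means the
maximum class probability — the only per-segment quantity the classifier
exposes.

Mean pitch is estimated by normalized autocorrelation (frames of 2048
samples, hop 512, search range 100–2000 Hz, voicing threshold 0.5 on the
normalized peak). Among local maxima within 90% of the global peak the
smallest lag wins — the standard guard against octave-down errors on
harmonic stacks — and the chosen lag is refined by parabolic
interpolation. Unvoiced segments report `NA`. Segment energy is the RMS
statistic applied with one frame spanning the whole segment.

## The synthetic-recording generator

Real annotated canine corpora are small and not redistributable, so the
package ships a seeded generator used by every test:

* **barks** — trains of 2–6 pulses, each 0.05–0.10 s long with
  0.06–0.10 s gaps; a pulse is an exponentially decaying harmonic stack
  (fundamental 400–900 Hz, 3–5 harmonics) plus a band-limited noise
  burst, with a sub-5 ms attack;
* **howls** — continuous harmonic stacks of 1.0–2.5 s, fundamental
  300–700 Hz, with a slow sinusoidal pitch glide of 5–25 Hz and gentle
  amplitude envelope;
* **recordings** — events mixed at their onsets over a Gaussian noise
  floor of amplitude 0.005 (the isolated-environment assumption);
  isolated corpus clips get a fainter 0.002 floor.

These ranges are *fixtures, not biology*: they are loosely matched to
published canine acoustics and chosen so that the two classes are
separable in principle (a single duration threshold already reaches 95%
on a 200-clip corpus — verified by test — so a classifier clearing 90%
is demonstrating learning, not luck). What passing tests on this
generator shows is that the machinery — segmentation arithmetic, feature
conventions, training loop, rejection plumbing — is correct and
reproducible. What it does not show is field performance: real kennels
add reverberation, overlapping animals, broadband transients and breed
variability that the generator deliberately omits.

## Numerical conventions and degenerate inputs

* dB/log floors at $10^{-10}$; all feature matrices are finite by
  construction.
* Argmax ties in predictions break toward the earlier class in the
  model's class order.
* All-zero signals: peak normalization warns and returns the input;
  spectrogram matrices become a uniform floor; `to_image()` maps
  constants to 0.5; `analyze()` returns a valid empty summary.
* Zero-length signals and sub-frame signals are rejected with
  instructive errors rather than padded silently.
* WAV I/O: integer PCM is scaled by the full-scale divisor of its bit
  depth (16-bit code 32767 reads as 32767/32768); stereo is averaged to
  mono; writing is always mono float32.

## Problem sizes used by the test suite

The packaged tests run at sizes chosen to exercise every code path while
staying desk-friendly: the classifier acceptance run uses a 120-clip
corpus (60 per class, seed 0, Mel features, at most 100 epochs with
early stopping); segmentation recovery uses one 20-event recording plus
a 10 s event-free recording; DSP oracle comparisons use one-second
clips at the full 2048-point configuration. The same quantities are
recomputed from scratch by `scripts/acceptance.R`.

## Known limitations

* The segmentation is a bare energy detector by design; it is not a
  noise-robust VAD and will fail in farm-level noise.
* The rejection rule equates confidence with softmax probability, which
  is uncalibrated; the 0.70 default is a policy, not a probability
  statement.
* k-NN probabilities are neighbor-vote fractions; with two classes this
  is exact, beyond two it splits the remainder uniformly.
* The real-time variant of the system is out of scope; only offline
  analysis of complete files is provided.
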