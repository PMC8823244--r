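---
title: "Detecting mouse ultrasonic vocalizations with a hybrid CNN-BiLSTM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mouse ultrasonic vocalizations with a hybrid CNN-BiLSTM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usvdetect)
```

## The problem

Mice communicate with ultrasonic vocalizations (USVs): brief
frequency-modulated whistles, mostly between 30 and 110 kHz and tens of
milliseconds long. Detecting them in long recordings is tedious by hand and
brittle with classical image-processing detectors, because calls are sparse
(well under 1% of recorded time in typical home-cage sessions), the band is
contaminated by electrical humming and broadband clicks, and the
signal-to-noise ratio varies widely. `usvdetect` implements a detector that
couples a convolutional stage, which judges each instant from its local
spectro-temporal neighborhood, with a recurrent stage that reads the whole
segment in both directions, so each frame is classified in the context of
roughly a second of surrounding audio.

## Signal representation

Audio is expected at 250 kHz sampling (lower-rate files are resampled on
read). `melspec()` converts a waveform to a log-Mel spectrogram with

* 124 Mel-spaced triangular bands covering 1–125 kHz,
* a hop of `ceiling(rate / 332)` samples, i.e. ~332 frames per second
  (about 3 ms per frame; exactly 332 frames for one second at 250 kHz),
* a 1024-sample Hann analysis window (FFT 1024), and
* dB compression `10 log10(power + 1e-10)`, so silence is exactly −100 dB.

The Mel spacing compresses the upper band: frequency resolution is finer at
40 kHz than at 110 kHz, which is the usual trade-off for this detector
family — temporal precision is high, upper-frequency-boundary precision is
not.

The window (4.1 ms) is longer than the hop (3.0 ms), so *labeling* frames by
"analysis window touches a call" would smear each call outward by more than
one frame. Frame labels and interval reconstruction therefore both use the
non-overlapping hop tiling — frame *t* owns `[t, t+1)/frame_rate` — which
makes `labels_to_frames()` followed by `track_to_detections()` recover every
interval to within one frame period per edge. That property is tested on
random tables.

Narrow Mel bands near 1 kHz can fall between FFT bin centers; such a band is
given unit weight at the nearest bin so no band is silently dead.

## Model

Each frame is processed together with its 25 preceding and following frames
(a 124×51 context window):

1. **1-D branch.** Two frequency-axis convolutions (kernel 7, channels
   1→4→1, ReLU between) over the window's mid column accentuate candidate
   call energy at each band.
2. **2-D branch.** Two 2-D convolutions (5×3 kernels in frequency×time,
   channels 1→4→1, ReLU between) over the whole window, averaged over the
   window's time extent, summarize the surrounding noise context.
3. **Frequency mask.** The branch outputs are multiplied elementwise and
   passed through a sigmoid, yielding a per-frame vector of 124 values in
   [0, 1] — the probability that each band belongs to a call. The mask
   serves three purposes: it is the classifier input, it provides the
   per-call frequency bounds, and it drives denoising.
4. **Sequence classifier.** A single-layer bidirectional LSTM (48 hidden
   units per direction) reads the mask columns across a segment (332 frames
   by default), and a fully connected softmax layer classifies every frame
   as call or background. Training minimizes class-weighted cross entropy.

Convolutions are zero-padded along frequency but *valid* (unpadded) along
time, with the input padded by 25 silence columns per segment side. A
frame's mask column therefore depends on exactly its own 51-frame context:
running `cnn_mask()` window by window and running the convolutional stage
over the whole spectrogram give identical columns to machine precision
(tested), and inference cost drops by the window width.

### Numerical and initialization choices

* Input maps are normalized as `(x + 60) / 20` before the network; the
  constants are fixed in the config, not fitted.
* Weights are Glorot-uniform with a seeded RNG; LSTM forget gates start
  open (bias 1).
* The 1-D branch's output bias starts at 1 and the 2-D branch's at 0. The
  mask then starts at exactly 0.5 everywhere while the product still passes
  gradient through the 2-D branch; with both biases at zero the product of
  two near-zero branches has vanishing gradient and training stalls.
* Mask columns are shifted by −0.5 before the LSTM. Mask values live in
  [0, 1]; feeding all-positive inputs to an LSTM forces correlated weight
  updates and, in our ablations, left weighted training stuck at the
  best-constant-prediction loss for hundreds of optimizer steps, while the
  centered variant converged within an epoch or two.
* Layer sizes are deliberately small (about 67k parameters) so that the
  reference corpus trains in a few minutes on one CPU core; all sizes are
  config-exposed and scale up cleanly.

## Training

USV recordings are extremely imbalanced, so `condense_segments()` keeps only
short clips (1–20 s) of consecutive calls separated by less than 1 s,
splitting over-long chains at their largest internal gap, padding each clip
with 0.1 s of context, and guaranteeing that clips never overlap and every
call lands in exactly one clip. `assemble_dataset()` adds call-free noise
clips, converts everything to fixed-length frame segments, and measures the
USV frame prevalence; the loss weights default to inverse prevalence (a 25%
USV / 75% background mix gives weights 0.75/0.25).

Optimization is Adam (default learning rate 3e-3, batch 8 segments, at most
10 epochs for the reference corpus), with an 80/20 clip-level
train/validation split; the best-validation-F1 parameters are kept and
optionally checkpointed. Fine-tuning restarts from a checkpoint whose
architecture must match.

Training-time map augmentations are implemented and config-exposed:
frequency-axis shift (default ±15 bands), affine value jitter (offset
−50..+10 a.u., gain −3..+3 a.u., where a.u. are the dB-like units of the
feature maps and the gain maps to a factor `10^(g/20)`), and random
horizontal/vertical line injection imitating humming and impulse noise.
Gaussian and salt-and-pepper pixel noise exist but default off. Their
purpose is robustness across recording chains and noise regimes unseen in
training. `train_config()` defaults to *no* augmentation: the synthetic
reference corpus already contains humming, impulses and noise-floor
variation, and at the 10-epoch desk scale the full-strength jitter keeps
the optimizer from converging at all. Switch augmentation on when training
for heterogeneous real recordings.

## Post-processing and denoising

`track_to_detections()` turns the per-frame probability track into
intervals: threshold (default 0.5), merge gaps shorter than 10 ms, drop
detections shorter than 5 ms — both defaults sit well below typical call
statistics (median duration ~50 ms) and are config-exposed since the
matching rules of any given study may differ. `freq_bounds()` reads each
detection's frequency extent off the mask (bands whose within-interval mean
mask exceeds 0.5, converted to Hz via the band edges — lower edge for the
low bound, upper edge for the high bound, a deliberately conservative
choice). `denoise()` is exactly the elementwise product
`spectrogram × mask × track` and nothing else; apply it to `mel_power()`
(linear energies) to extract clean syllables.

## Evaluation

`match_detections()` scores detections against truth with a four-way
taxonomy: the first detection overlapping a truth call is a true positive
(`USV`); later detections on the same call are `Partial` re-tags (counted
once, by default neither credit nor penalty — a flag can turn them into
false positives); one detection spanning several calls is `Multi` (one true
positive; the extra covered calls are consumed, not double-counted);
detections overlapping nothing are false positives and untouched truths are
misses. Alarm-call (`AC`) annotations are excluded before matching and
detections lying only on them are set aside. Any nonzero temporal overlap
counts by default; a minimum intersection-over-union is config-exposed
because the "same call" criterion in manually scored studies is ultimately
subjective. Recall, precision and F1 follow the standard formulas, with F1
defined as 0 when precision + recall is 0.

Signal-to-noise ratios use the magnitude `mean(x²)` of raw samples: locally,
`R_i = (M_sig+bg,i − M_bg,i)/M_bg,i` against the mean of the two flanking
call-free stretches; globally, pooled call samples against pooled background.
`R = 0` means the call segment is no louder than its surroundings, and the
ratio is scale-invariant (both properties tested).

## The synthetic corpus

`synth_recording()` generates what the detector assumes: FM whistle
syllables (up/down sweeps, arcs, one-jump shapes; 30–110 kHz) grouped into
calls, over Gaussian background noise, continuous humming tones (5, 20 and
45 kHz) and Poisson-timed broadband clicks. Call amplitude is calibrated
against the package's own `local_snr()` so the realized median local SNR
hits a target, closing the loop with the evaluation definition. Ground
truth is exact by construction and is verified against an independent
band-limited energy detector in the tests.

The reference corpus is 400 one-second call clips plus 100 noise-only clips
at target local SNR 2. Clips are call-dense (2–5 syllables of 30–90 ms with
30–80 ms gaps), emulating the condensed training mix this detector family
is trained on (roughly a quarter of frames contain call energy); syllable
statistics sit inside the observed range of adult mouse calls while
guaranteeing that every sampled plan fits a one-second clip. Held-out
evaluation uses 100 fresh clips at the same SNR, plus 25 clips at each of
SNR 2, 1, 0.5 and 0.1 for the degradation curve.

What passing on this corpus shows — and what it does not: the pipeline
learns, localizes and scores synthetic whistles over the modeled noise
archetypes end to end. Real recordings add reverberation, overlapping
animals, harmonics, alarm calls and unmodeled transients; performance
figures from the synthetic corpus do not transfer to real data, and a model
for real use should be trained (or fine-tuned) on labeled recordings with
augmentation enabled.

## Known limitations

* Upper frequency bounds inherit the Mel grid's coarse high-frequency
  resolution.
* The mask is trained only implicitly — labels carry no frequency
  information — so nothing forces its values toward 1 on call bands. On the
  desk-scale corpus the learned mask separates call bands from background
  but stays at or below 0.5, leaving default-threshold frequency bounds
  absent (`NA`); longer training, a lower `mask_threshold`, or per-band
  supervision would be needed for reliable bounds.
* The detector emits call intervals and bounds only; syllable
  classification, clustering and syntax analysis are out of scope.
* The matching taxonomy rewards one detection spanning many calls with a
  single true positive and no misses; with a degenerate always-on detector
  this inflates event F1, so frame-level validation F1 is reported during
  training alongside event metrics.
* Checkpoints use R serialization and are not portable to other frameworks.
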