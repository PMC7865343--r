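---
title: "Gait phase recognition from IMU time series: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gait phase recognition from IMU time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gaitphase)
```

This vignette is the package's own account of the science it implements:
the labeling model, the input representation, the classifier, the
evaluation statistics, and — importantly — what the synthetic data
generator does and does not establish.

## 1. The labeling model

The ground truth for supervised gait-phase recognition comes from a
pressure plate under a treadmill belt: the total vertical force during one
step rises at heel strike, shows two maxima (weight acceptance and push-off)
separated by a minimum (single support), and is exactly zero while the foot
swings. Five classes tile each gait cycle, in fixed order:

| phase | interval (0-based, half-open) |
|-------|-------------------------------|
| IC    | `[contact, contact + ic_stretch)` |
| LR    | `[contact + ic_stretch, first force peak)` |
| MS    | `[first peak, inter-peak minimum)` |
| TS    | `[minimum, toe-off)` |
| SW    | `[toe-off, next contact)` |

Two modeling points deserve justification:

* **IC stretching.** Initial contact is an instantaneous event, not an
  interval. Treating it as a class of one frame would make the dataset
  hopelessly unbalanced, so the class is stretched over `ic_stretch` frames
  (default 10, ≈ 83 ms at 120 Hz — chosen so the five classes are roughly
  comparable in mass on ~1 s cycles). The *first* frame of each IC run is
  still exactly the contact event, so event-level timing is recoverable.
  The exact stretch used in the original study is not documented; the
  parameter is exposed.
* **The frame-to-phase map.** Published descriptions name the five phases
  and say that force extrema delimit them, but never write down the exact
  map. The map above (contact→peak1 split into IC+LR, peak1→valley = MS,
  valley→toe-off = TS, zero force = SW) is the reading most consistent with
  the colored-region figure convention, and it is configurable: frames
  before the first contact and after the last toe-off are labeled SW (also
  an undocumented corner; swing is the only defensible default since force
  is zero there).

**Event detection** (`detect_step_events`) finds stance intervals as
contiguous runs of force above a contact threshold (default 2% of the trace
maximum), then locates the two maxima and the interior minimum on a
moving-average smoothed copy (default width 5 frames — measured force
curves are not perfectly smooth) and refines each extremum by one frame
against the raw trace. The refinement makes noiseless curves exact while
keeping the noise robustness of the smoothed search; on the generator's
default force noise every event is recovered within ±1 frame (a property
test over seeds). Stances shorter than `2 * smooth_window` are discarded as
artifacts; a stance without two separable maxima (e.g. a shuffle or a
partial step) is flagged *unlabelable* with a warning rather than silently
mislabeled, and its frames stay out of the training labels.

**Synchronization** (`align_streams`) crops both streams at their trigger
frames and truncates to the common length; a rate mismatch is resampled by
linear interpolation only when explicitly enabled. The declared
synchronization bound (16 ms: about one frame of trigger uncertainty plus
one frame of sampling jitter) travels with the result — it is the reason
the evaluation offers tolerance accuracies at 1–3 frames.

## 2. Input representation

Windows of `window_len = 50` frames × 70 columns (10 IMUs × 7 channels)
slide with shift 1. The window's label is the phase of its **last** frame:
the classifier is causal, predicting the *current* phase from the
immediately preceding 417 ms, which is what an online application needs.
(The alternative, center labeling, is available via `label_frame`.)

Channels are ordered **by device** (all 7 channels of one IMU adjacent) by
default; `by_measurement` (all ax, then all ay, ...) is a pure column
permutation used to study how spatial adjacency in the 2D convolution
affects the result.

Training must not see one subject after another (Adam would overfit the
current subject), yet full frame-level shuffling would destroy temporal
context. The compromise: the stream is cut into fixed-length **sequences**
that are shuffled as units. One published description calls a sequence
"4 s (480 data points)" while elsewhere 480 is "the number of windows in
one sample"; these are incompatible (480 raw frames yield 431 windows).
This package defines a sequence as **480 windows built from 529 consecutive
raw frames**, which keeps the observed optimum of the LSTM-width experiment
(width = windows per sequence) self-consistent; the raw-frames reading
remains available behind `mode = "frames"`. A related published
inconsistency — "half the sequence length (=215)" where 480/2 = 240, and a
stated LSTM width of half the sequence against an experiment concluding
the full length is best — is resolved in favor of the experiment's
conclusion: `lstm_units` defaults to the windows-per-sequence count.

The leave-one-subject-out split isolates one subject entirely; remaining
subjects' sequences are shuffled and partitioned 66/34 into train/test with
10% of train as validation. Shuffling permutes whole sequences only, and a
test asserts no train/val sequence belongs to the unseen subject.

## 3. The classifier

Six convolutions (first kernel 6×6, then 3×3; zero padding; filter counts
non-decreasing, default 16,16,32,32,64,64), max-pooling 2×2 / 3×3 / 2×2
after conv layers 2, 4, 6. On a 50×70 window the pooled grid is
50→25→8→4 by 70→35→11→5, so the flattened feature vector feeding the LSTMs
has `4·5·F₆` entries. (A published remark puts the last conv output at
"7×9", which no standard floor/ceil pooling arithmetic reproduces from
50×70 with the stated pools; the stated pools win and the remark is treated
as an inconsistency.) Two LSTM layers run over the window axis of each
sequence; LSTM state is reset between sequences — sequences are shuffled,
so no cross-sequence dependency can be intended. The dense head
(1024/256/5 by default) is applied at **every** sequence step, so each
window yields a softmax row and frame-level evaluation is possible.

Filter counts per layer are not documented anywhere ("increases for deeper
layers" is the only constraint); the defaults honor monotonicity. L2
coefficient (1e-4) and Adam learning rate (1e-3) are likewise undocumented
defaults. Glorot-uniform initialization and dropout 0.2 on LSTM and dense
layers follow the stated design.

No deep-learning framework is available in the target environment, so the
network is implemented from first principles: im2col+GEMM convolution and
max-pooling (forward and backward) in RcppArmadillo, BPTT through the LSTM
stack, softmax/cross-entropy, inverted dropout and Adam in R. The test
suite checks 25 randomly sampled parameters of the full stack against
central finite differences (relative error < 5e-4); training is
reproducible bit-for-bit under fixed seeds on a fixed BLAS.

Numerical conventions worth recording: `same` padding places
`floor((k-1)/2)` rows/columns before and the remainder after (the
TensorFlow convention — visible only for the even 6×6 kernel); pooling uses
floor division and drops trailing rows; argmax ties in prediction break
toward the lowest class index; softmax is max-stabilized; the forget-gate
bias starts at 1.

## 4. Evaluation statistics

* **Tolerance accuracy**: a prediction at frame *t* is accepted at
  tolerance *k* iff the true stream holds the predicted class within
  ±*k* frames of *t*. Symmetric, because "missing the real class by 8 ms"
  has no stated direction. At *k* = 0 it reduces to plain accuracy, and it
  is non-decreasing in *k* (property-tested against brute force).
* **Misprediction offsets**: for each wrong frame, the distance to the
  nearest frame where the true stream holds the predicted class, in ms
  (1000/120 ≈ 8.33 ms per frame; reports also print the conventional
  rounded "8 ms"). This per-frame reading makes the offset distribution
  computable for every misprediction; a per-event variant would require an
  event matching that published material does not define. Predictions of a
  class absent from the stream are reported separately, never dropped.
  These two definitions interlock: tolerance-*k* accuracy equals plain
  accuracy plus the error mass with offset ≤ *k* — an identity the
  acceptance suite asserts on real model output.
* **Certainty rejection**: the maximum softmax entry is the rejection
  score; predictions with certainty ≤ threshold become *unknown*. No
  temperature scaling or calibration is applied — deliberately: thresholds
  are set operationally, and softmax output is not a correctness
  probability. The report conserves counts (retained + unknown = total;
  unknown splits exactly into formerly-correct and formerly-wrong) and
  marks the all-rejected case explicitly instead of dividing by zero.
* **LOOCV**: one model per held-out subject. The summary's `sd` uses the
  population (1/n) convention — the convention under which the published
  summary of the per-subject table reproduces (0.015853 vs the printed
  0.01586; the sample sd would be 0.016626). The sample value is also
  returned.
* **Activation heatmap**: mean absolute activation of the last conv layer
  (before the final pool), averaged over windows and filters, min–max
  normalized (a constant map is defined as all-zeros) and bilinearly
  upsampled to the input resolution so column bands align with sensors. A
  test plants information in only the thigh sensors and checks the heat
  concentrates there.

## 5. The synthetic generator: what it states and what it cannot show

The study's recordings were never deposited, so the generator emulates the
*stated* conditions: 11 subjects, 120 Hz, ~1 s gait cycles (per-subject
cycle length ~ N(1.0 s, 0.05 s)), stance occupying 60% of the cycle, a
two-bump stance force curve (raised cosines of heights 1.0/0.95 centered at
25% and 75% of stance, half-width chosen so force is strictly positive
across stance with an interior minimum near 50%), exactly zero swing force,
and a shared trigger (frame 0 by default; a configurable pressure-side
offset exercises the alignment code).

IMU channels are two-harmonic sinusoids of the cycle phase,
`a₁ sin(2πφ+ψ₁) + a₂ sin(4πφ+ψ₂)`, with amplitudes and phases fixed per
sensor-channel from the config seed, right-side sensors half a cycle out of
phase, multiplied by per-subject log-normal channel gains (sd 0.10) and
corrupted with Gaussian noise (sd 0.05 against order-1 amplitudes ≈ a
clean laboratory signal). Barometric channels drift slowly and carry no
phase information. Force noise default is 0.005 of the unit bump height —
small plate noise; at this level events are recovered within ±1 frame,
matching the synchronization-limited precision the labeling can claim at
120 Hz anyway. Amplitudes are arbitrary units: sensor spans (±8 g,
±250°/s) are documented, but per-channel value distributions of real
walking are not, and the classifier is scale-sensitive only through
learned weights.

A trailing gait cycle whose stance does not complete before the recording
ends is emitted as quiet standing (zero force, zero motion, SW label) —
the generator never produces a half-bump that the event detector would
have to reject.

**What a green test establishes.** The generator's phases are decodable
from any window by construction (the waveforms are deterministic functions
of φ), so end-to-end learning tests prove the pipeline — labeling,
windowing, training, evaluation — is wired correctly and that the network
can extract temporal phase from multi-channel windows under subject-level
amplitude and cadence variation. **What it does not establish**: real-data
accuracy. Real gait has within-subject cycle variability, non-stationary
waveforms, soft-tissue artifacts, sensor drift and genuinely ambiguous
transitions; none of this is emulated. The published real-data numbers
(95.24% test, >92% unseen) are therefore *not* reproduction targets; the
synthetic analogue at reduced scale reaches ~0.89–0.93 on a held-out
subject across seeds, with the same qualitative signature (errors
concentrated within ≤2 frames of transitions, tolerance accuracy ≥0.97 at
2 frames, rejection raising retained accuracy).

## 6. Scale of the shipped experiments

The acceptance run trains 10+1 subjects × 20 s at filter counts
(2,2,4,4,8,8), LSTM width 32, dense 32/16, sequences of 120 windows, 10
epochs — about 5 minutes on one CPU. These are *scale* reductions (fewer
parameters, less data than the 60 s generator default), not changes to the
stated world; topology, rates, phases, noise and split fractions are the
defaults above. At this scale single-run unseen accuracy fluctuates by a
few points across seeds; the fixed stated-world run in the acceptance
suite clears 0.90 and the variability is reported rather than averaged
away.

## 7. Known limitations

* Only total vertical force is modeled for labeling; per-region pressure
  distributions (and hence swing sub-phases) are out of scope, as is any
  eight-period segmentation.
* The CLI covers simulate/label/windows/run/loocv/sweep with JSON configs;
  real-time streaming inference is out of scope.
* Window sets and model checkpoints persist via `saveRDS` (no HDF5 binding
  in the target environment).
* The greedy sweep optimizes one parameter at a time by design; no grid
  search.
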