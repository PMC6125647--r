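---
title: "Detecting atrial fibrillation from ECG scalograms: methods and design"
author: "fibriwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting atrial fibrillation from ECG scalograms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibriwave)
```

## The detection problem

Atrial fibrillation (AF) replaces the organized atrial depolarization of
normal sinus rhythm (NSR) with disorganized activity: the P wave preceding
each QRS complex disappears, continuous low-amplitude fibrillatory
"f-waves" (typically 4--10 Hz) take its place, and the ventricular response
becomes irregularly irregular, so RR intervals vary strongly from beat to
beat. fibriwave implements a detector that classifies *five-beat* stretches
of single-lead ECG as AF or non-AF by feeding time--frequency images of the
beats to a 2D convolutional neural network, so that both the atrial
signature (f-waves vs. P waves, a spectral feature) and the ventricular
signature (RR irregularity, a temporal feature) are visible to one
classifier at once.

The pipeline has four stages: wavelet denoising, proportional beat
segmentation, continuous-wavelet-transform (CWT) scalogram construction,
and CNN classification. R-peak locations and per-beat rhythm labels are
assumed given (as database annotations provide them); QRS detection is out
of scope.

## Dyadic wavelet denoising

The signal is decomposed with the translation-invariant (à trous) dyadic
wavelet transform over $J = 7$ scales using the orthonormal db4 filter
pair $(h, g)$:

$$S_{2^j} f(n) = \sum_k h_k\, S_{2^{j-1}} f(n - 2^{j-1} k), \qquad
  W_{2^j} f(n) = \sum_k g_k\, S_{2^{j-1}} f(n - 2^{j-1} k),$$

with $S_{2^0} f$ the input: at level $j$ the filters are dilated by
inserting $2^{j-1}-1$ zeros between taps, and no decimation takes place,
so every series keeps the input length. At 250 Hz the detail scales
cover the octaves 62.5--125, 31.25--62.5, 15.63--31.25, 7.81--15.63,
3.91--7.81, 1.95--3.91 and 0.98--1.95 Hz (`bandEdges()`); the three finest
scales are zeroed before reconstruction, removing high-frequency noise
above roughly 15.6 Hz.

Two design choices deserve note.

*Storage as multiresolution components.* `dyadicDecompose()` runs the
recursion above but stores, per scale, the **synthesis contribution** of
its coefficients in the sample domain: `details(dec)[[j]]` is the part of
the signal reconstructed from $W_{2^j}$ alone and
`approximations(dec)[[j]]` the part below it, so the components telescope
(`A_j = A_{j+1} + D_{j+1}`) and sum exactly to the input. This is the
multiresolution-analysis view familiar from the MODWT literature. It has
two concrete advantages over storing raw recursion outputs: zeroing all
detail scales returns exactly the deepest smooth (for raw coefficients the
synthesis cascade of $S_{2^J}$ differs substantially from $S_{2^J}$
itself), and the per-scale energies are directly comparable across scales
(raw undecimated details gain a factor of $2^j$ in their pass band, which
misattributes tone energy to neighboring octaves). Reconstruction with a
set of zeroed scales — the sum of the retained components — is
algebraically identical to running the inverse recursion with those $W$
series zeroed.

*Boundary handling.* Filtering is circular (periodic extension) at the
signal's native length. The orthonormal analysis/synthesis pair is then
exactly invertible for any length: the perfect-reconstruction test
demands a relative $L_2$ error below $10^{-8}$ and observes $\sim
10^{-16}$.

Zeroing scales 1--3 removes the 15.63--125 Hz band, which also attenuates
some QRS sharpness; this is the stated procedure and the zeroed set is
configurable (`zeroScales`).

## Proportional segmentation into five-beat instances

Each beat's analysis window starts at two thirds of the *previous* RR
interval, $\mathrm{start} = r_{i-1} + \lfloor 2 (r_i - r_{i-1}) / 3
\rfloor$, and spans a fixed 1.2 s (300 samples at 250 Hz), so that one
window contains the beat's full P/f--QRS--T content regardless of rate.
Flooring keeps starts on the sample grid; the first beat (no previous RR)
is skipped and windows that would overrun the record are dropped. Because
the length is fixed while RR varies, windows may overlap at high rates or
leave gaps at low ones — for NSR at 60 bpm and 250 Hz (RR ≈ 250 samples
< 300) consecutive windows *always* overlap, which is intended: a fast,
irregular rhythm puts a second QRS inside the window and the classifier
sees exactly that.

Windows are grouped into non-overlapping blocks of five consecutive beats
(a sliding stride-1 mode exists for augmentation, off by default). A
block becomes a labeled instance only when its five beat labels are
unanimous; mixed blocks — rhythm transitions — and rhythms outside the
binary task (e.g. atrial flutter) are discarded. All sample indices are
0-based, the convention of WFDB-style annotation files.

## CWT scalograms

Each 300-sample window is transformed with the CWT of the db5 wavelet,

$$W_{a,b} f = \frac{1}{\sqrt{|a|}} \int f(t)\, \psi\!\left(\frac{t -
b}{a}\right) dt,$$

evaluated by FFT correlation at every shift $b$, with symmetric (tiled
reflection) boundary extension. The db5 mother wavelet has no closed
form; it is materialized by cascade refinement (a delta passed once
through the high-pass synthesis step, then repeatedly through the
upsampled low-pass refinement), giving samples over its compact support
of $2N - 1 = 9$ time units, mean-subtracted and $L_2$-normalized.

Scales follow `nScales` (default 128) log-spaced center frequencies
between `freqMin` = 0.5 and `freqMax` = 30 Hz via $a = f_c \cdot
\mathrm{fs} / f$. After denoising the signal is essentially band-limited
below 15.6 Hz, so this grid covers the P/T/f-wave band and the retained
QRS energy with headroom. The center frequency $f_c$ is defined as the
peak of $\sqrt{f}\,|\hat\psi(f)|$ — the response maximum under the
transform's $1/\sqrt{a}$ amplitude normalization — rather than the raw
spectral argmax. On a log-spaced scale grid the $\sqrt{a}$ weighting
shifts a tone's maximal-response row by a constant number of bins
(measured: 3--4 bins toward lower frequency with the raw argmax); the
weighted definition removes that bias, and the package's localization
tests require the maximal-energy row to sit within one bin of a test
tone's frequency.

Coefficient *magnitudes* are used (the published patterns display a
density), the time axis is resized from 300 to 128 columns by linear
interpolation (not cropping), and each pattern is min--max normalized to
$[0, 1]$ individually, making patterns amplitude-invariant across
subjects; an all-constant pattern maps to zeros. Five per-beat patterns
stack into the $(128, 128, 5)$ network input.

## The network

```{r trace}
shapeTrace(cnnSpec())
```

Four valid-padding, stride-1 convolutional layers (32 kernels each, sizes
10, 10, 8, 4) with 2×2 max-pooling after the second and fourth, three
dropout layers, a flatten layer, and fully connected layers of 256 and 1
neurons. Valid padding with stride 1 is the only convention that
reproduces the published trace — spatial sizes 128 → 119 → 110 → 55 → 48
→ 45 → 22, flatten length $22 \cdot 22 \cdot 32 = 15488$ — so it is
fixed. The parameter budget is dominated by the 15488 × 256 first dense
layer. The hidden activation is the logistic function
$\beta = 1/(1+e^{-\alpha})$ by default, with relu available by flag
(deep sigmoid stacks train slowly); the output unit is always a single
sigmoid. Pooling is max (an average mode exists behind a flag; the
architecture's own layer naming says max even though the general
background text describes averaging, so max is the default).

Training is plain SGD with momentum 0.8, learning rate 0.001, weight
decay $10^{-6}$ and 50 epochs by default, minimizing binary cross-entropy
on the sigmoid output — the canonical loss for this head; the source
architecture names no loss. Dropout rates (0.25, 0.25, 0.5), batch size
128 and Glorot-uniform initialization are likewise unstated upstream and
exposed in `cnnSpec()` / `trainConfig()`. Every stochastic element
(initialization, shuffling, dropout) draws from one seeded RNG stream, so
a fixed seed reproduces training bit for bit on single-threaded BLAS.
The convolution and pooling primitives are implemented in C++ (im2col +
BLAS dgemm) and are verified in the test suite against brute-force
convolution and finite-difference gradients.

## Evaluation protocol

Instances are subsampled to equal class counts and split **by record**:
records are shuffled (seeded), then packed greedily per class into the
training side until the 4:1 instance-count quota is best approached — no
record contributes to both sides, which prevents within-subject leakage.
With single-instance records the proportion is exact (100 000 instances
→ 80 000 / 20 000). Metrics are the standard four, in percent:
sensitivity TP/(TP+FN), specificity TN/(TN+FP), positive predictive value
TP/(TP+FP) and accuracy (TP+TN)/total, with AF positive. A metric whose
denominator is zero is reported as `NA` (undefined) with a warning, never
coerced to 0 or 100. On a class-balanced test set Acc = (Se+Sp)/2
algebraically, which the tests exercise.

## Synthetic ECG: what it emulates and what it does not

The generator exists so every stage is testable without a database
download. Each beat is a sum of Gaussian bumps placed relative to its R
peak (P: 0.15 mV, σ 25 ms, at R−160 ms; Q/S: −0.1 mV, σ 8 ms; R: 1.0 mV,
σ 12 ms; T: 0.3 mV, σ 60 ms at R+300 ms). NSR draws RR intervals from a
Gaussian with CV 0.04 (default 70 bpm); AF from a lognormal with CV 0.2
(default 95 bpm) — long-tailed, matching the irregular ventricular
response — omits the P bump, and adds a continuous f-wave component of
three sinusoids with frequencies drawn uniformly in 4--10 Hz, amplitude
0.08 mV and slowly drifting random phases. Additive artifacts default to
0.2 mV baseline wander at 0.3 Hz, 0.05 mV white noise and 0.03 mV mains
at 50 Hz, chosen to exercise both the zeroed 15.6--125 Hz bands and
sub-1 Hz leakage. All of these are stand-in parameters — the source
study used a real database and states no data distributions — and every
one is configurable.

What passing tests on this material *do* show: the transform chain
preserves and localizes the discriminative bands; the segmentation
geometry is exact; the network can learn the AF/non-AF decision from
scalograms under a record-disjoint protocol. What they do *not* show:
performance on real ECG, whose morphology variation (ectopy, conduction
abnormalities, electrode artifacts, rhythm transitions within five
beats) the bump model does not attempt; published database figures are
not reproducible from synthetic data, and the package makes no claim
about them.

## The reference study configuration

`afStudyConfig()` fixes the package's own end-to-end evaluation: 50
synthetic subjects (25 per class), 200 s each at 250 Hz (long enough
that the slower NSR class yields over 1000 five-beat instances), 2000
balanced instances split 4:1 by record, and training for 8 epochs. To
keep one full run in single-digit minutes on a single core it uses
64×64 patterns (64 scales over the same 0.5--30 Hz band) and a
width-reduced network — 6 kernels per convolutional layer, 64 dense
neurons, relu activations, learning rate 0.01, batch 32. These sizes are
the package's choice of demonstration scale; the default `cnnSpec()` /
`cwtConfig()` remain the full (128, 128, 5), 32-kernel architecture.
`scripts/acceptance.R` runs exactly this study and writes its four
metrics as JSON.

## Numerical notes and limitations

* Degenerate inputs: constant CWT patterns normalize to zero; zero
  learning rate leaves parameters exactly unchanged; classification ties
  (`p == threshold`) go to AF, documented in `classifyProbs()`.
* The localization tests use tones of 1024 samples; inside a single
  300-sample window a 2 Hz tone completes only 2.4 cycles and boundary
  effects dominate its scale attribution, which is physical, not a bug.
* Zeroing scales 1--3 discards the clean QRS energy above 15.63 Hz as
  well as noise (~0.05 mV RMS for the default 12 ms R bump). This
  distortion floor means denoising only reduces the error against the
  clean signal when the broadband noise level exceeds roughly that
  floor; the SNR-improvement test therefore runs at 0.1 mV noise.
* `balancedSplit()` rejects pools where a record would need to sit on
  both sides of the split (possible only when one record holds both
  classes); reconciling such records with exact balance is left to the
  caller, e.g. by excluding them.
* Per-pattern min--max normalization discards absolute amplitude; if
  amplitude is diagnostic in an application, a global normalization
  would be the variant to add.
* Training determinism assumes single-threaded BLAS; multi-threaded
  GEMM may reorder reductions.
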