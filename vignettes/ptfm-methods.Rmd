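---
title: "Acoustic mass sensing with a piezoelectric thin-film microbalance: models and methods"
author: "ptfm package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acoustic mass sensing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptfm)
```

## The sensing problem

A piezoelectric thin-film microbalance (PTFM) is a resonant mass sensor: a
poled PVDF diaphragm driven by an alternating field oscillates at its
fundamental resonance, and mass adsorbing on the sensing surface lowers
that resonance. The platform this package models replaces laboratory
frequency-readout instrumentation with a commodity audio capture chain --
the vibrating film emits sound, a 48 kHz microphone records it, and
classifiers assign each 0.1 s recording to one of ten mass-load classes
(0-9 micrograms). A linear calibration of frequency shift against mass
then turns shift measurements into quantitative mass estimates.

The package has three coupled layers: closed-form physics, a synthetic
acoustic-signal generator, and the classification/calibration machinery.

## Frequency-mass physics

For rigid, thin, uniform loading on a quartz-like resonator the shift
follows the Sauerbrey relation

$$\Delta f \;=\; -\frac{2 f_0^2}{A\sqrt{\rho_q\,\mu_q}}\,\Delta m,$$

implemented by `sauerbreyShift()` with the device constants carried by a
`ResonatorSpec` (CGS internally; the API takes micrograms, millimetres and
micrometres). `theoreticalSensitivity()` returns the prefactor
$S_M = 2f_0^2/(A\sqrt{\rho_q\mu_q})$, and `empiricalSensitivity()` the
measured counterpart $S_m = -\Delta f/\Delta m$.

For the flexible PVDF film the package uses the thin-film form

$$\Delta f \;=\; -\frac{f_0}{2\rho t}\,\Delta m_A,$$

valid while the areal loading $\Delta m_A$ is much smaller than the film's
areal density $\rho t$; `filmShift()` warns once the loading reaches 10% of
$\rho t$ (the validity statement is qualitative, so a soft threshold is
used rather than an error). The formula is read so that sensitivity is
direct in $f_0$ and inverse in both $\rho$ and $t$, which the scaling-law
tests pin down. Quality-factor analysis (`qualityFactor()`,
`bandwidthFromQ()`) uses $Q = f_0/\mathrm{BW}$ with the half-power
bandwidth.

The default device, `pvdfSpec()`, is a 28 um PVDF film on a 5 mm circular
active region resonating at 8.5 kHz with $Q = 27.6$ (half-power bandwidth
308 Hz). PVDF density is not a device-supplied constant; the package
default of 1.78 g/cm^3 is a standard literature value for poled
beta-phase film, and every number derived from it is a model output of
this package, not a measured property. With these constants the per-microgram
shift is about 4.34 Hz:

```{r}
loadedResonance(pvdfSpec(), 0:3)
```

## The signal generator

`synthSegment()` models the capture chain as a driven second-order
resonator in steady state. The drive waveform (sine, square or triangle)
is expanded in its Fourier harmonics up to Nyquist; each harmonic is
weighted by the resonator's magnitude response

$$|H(f)| = \Big[(1 - (f/f_r)^2)^2 + (f/(f_r Q))^2\Big]^{-1/2}$$

and phase-shifted by the corresponding response phase, with the loaded
resonance $f_r$ supplied by the thin-film physics. The deterministic part
is scaled to unit peak, additive Gaussian noise realising a target SNR (with
an optional 1/f fraction) is applied, and the result is peak-limited to
[-1, 1]. Ring-down transients are omitted: a 0.1 s window of a
continuously driven sensor is quasi-steady.

Two generator decisions were genuinely open and are worth recording:

* **Drive frequency.** The acquisition protocol tunes the generator to the
  sensor's resonance, so the default excitation (`frequency_hz = NA`)
  *tracks* the loaded resonance: the emitted tone sits at $f_r$ and the
  mass class is encoded in spectral position. This is also what makes the
  calibration pathway self-consistent -- the dominant frequency of a long
  noiseless segment equals `loadedResonance()` to well under 0.5 Hz. A
  fixed drive frequency is supported too; the class information then lives
  in the harmonic weighting by $|H|$.
* **Class separability.** With the physical constants, adjacent classes
  differ by about 4.3 Hz, below the 10 Hz resolution of a 0.1 s window, so
  classification at desk scale would hinge on subtle cues. The generator
  therefore exposes `separation_scale`, a multiplier on the mass-induced
  shift (default 1 = device physics). Benchmarks that need spectrally
  disjoint classes state the multiplier they use; it is a simulator knob,
  never a physical claim.

Noise defaults to white Gaussian at 30 dB SNR. The microphone is assumed
flat; propagation distance and enclosure acoustics are folded into the
single SNR parameter. Every segment's seed is derived from the dataset's
master seed with a counter scheme, so any segment is reproducible in
isolation; `buildDataset()` shuffles the generation order, emulating a
randomised mass-load sequence across acquisition sessions.

What the generator does *not* emulate: room reverberation, microphone
transfer functions, Bluetooth transport artifacts, temperature drift,
viscoelastic loading. A classifier that passes the synthetic benchmarks has
demonstrated that the architecture and training machinery can extract
mass-correlated spectral/temporal structure at a stated SNR -- not that it
would reach the same accuracy on real recordings.

## Featurisation

* `fftMagnitude()` -- one-sided magnitude spectrum (4800 points at 48 kHz
  give 2401 bins at 10 Hz), Parseval-consistent, with optional zero-padding
  for peak interpolation.
* `dualChannelInput()` -- the CNN/LSTM input: channel 1 is the z-scored raw
  waveform, channel 2 the magnitude spectrum linearly resampled to the
  waveform length and z-scored. Magnitude (not power or dB) is used.
  Resampling the 2401-bin spectrum onto the 4800-sample axis keeps a
  single input tensor rather than a dual-branch network. Standardisation
  uses a std floor of 1e-12 so degenerate segments map to zeros; per-segment
  z-scoring deliberately removes absolute amplitude as a cue unless the
  simulator encodes it spectrally.
* `patchify()` -- sliding-window patches for the transformer
  (single-channel; `floor((N-T)/stride)+1` windows; default `T = stride =
  48`, i.e. 100 tokens, a manageable sequence length).
* `dominantFrequency()` -- spectrum argmax refined by three-point parabolic
  interpolation; with 4x zero-padding on a 1 s window the residual bias is
  far below the 0.5 Hz tolerance the calibration pathway needs.

The LSTM consumes the dual channel cut into consecutive frames (default 48
samples per timestep, so 100 timesteps of 96 features). Feeding single
samples as timesteps would make sequences of length 4800, which is
needlessly slow for recurrent backpropagation and was not pinned down by
the platform description; the frame width is a config parameter.

## Classifier architectures

All three builders produce a `ClassifierModel` whose forward pass ends in
a softmax over the ten classes, built on the package's own
reverse-mode layer engine (im2col convolution, batch normalisation, max and
average pooling, LSTM with full backpropagation through time, transformer
encoder with multi-head self-attention, Adam). Every layer's analytic
gradient is checked against finite differences in the test suite.

* **CNN** -- `[conv -> batchnorm -> ReLU -> maxpool] x n_blocks`, then an
  average-pooling layer, dropout, one fully connected layer and softmax.
  The sweep axis is `n_blocks` (1-9). Defaults: kernel 9, 16 base channels
  doubling per block (capped at 128), pool 2, dropout 0.3. The head's
  average pool (window 4) is followed by flattening rather than a global
  average, so the head retains coarse positional information -- with
  spectrally encoded classes, where the peak sits *is* the signal.
* **LSTM** -- single LSTM layer (the sweep axis is its 20-160 memory
  blocks), dropout 0.2, one fully connected layer, softmax. Standard gate
  structure (input/forget/cell/output); forget-gate bias initialised to 1.
* **Transformer** -- linear patch projection to `d_model` (X_emb), learnable
  positional encoding added (X_pos), `L` post-norm encoder layers
  (MHSA + FFN, each with residual and layer normalisation) producing
  H_final, global average pooling over tokens (H_pooled), one fully
  connected layer, softmax. Defaults: d_model 64, 4 heads, FFN 128,
  dropout 0.1. The sweep axis is `L`.

Initialisation is Glorot-uniform and fully seeded: two builds from the same
seed are parameter-identical. Softmax temperature is 1 and argmax ties
break to the lowest class index (relevant only for pathological inputs).

## Training, evaluation, sweeps

`assignSplits()`/`splitDataset()` implement the stratified 60/20/20
train/validation/test protocol (rounded fractions, remainder to train).
Training (`trainClassifier()`) minimises cross-entropy with Adam
(defaults: lr 1e-3, batch 64, up to 50 epochs, early stopping on
validation accuracy with patience 10); Adam is used uniformly across all
three families. The best-validation parameters are returned together with
the per-epoch history. One master seed fans out to batch order and
dropout; histories are bit-reproducible.

`evaluateClassifier()` produces a `ConfusionMatrix` (rows true, columns
predicted) and `classifierMetrics()` derives accuracy, macro-recall and
macro-F1; for exactly balanced classes macro-recall equals accuracy, an
identity the tests assert on random balanced matrices. Classes absent from
a test set are excluded from macro averages with a warning.
`sweepArchitecture()` retrains across a grid of the family's sweep axis
with seeded repetitions and reports mean and sd of test accuracy; failed
runs are counted, never dropped.

### Problem sizes

The shipped tests run everything at desk scale, a deliberate package
choice so that the full suite stays fast and deterministic on a single
CPU: the separability benchmark uses 250 segments per class
(`separation_scale = 50`, 30 dB SNR, stratified 60/20/20), compact model
configurations (3-block CNN with kernel 5 and 4 base channels, pool 4;
48-unit LSTM; 2-layer transformer on 480-sample patches), and at most 10
epochs. All three families clear the suite's 95% test-accuracy bar under
those conditions with ample margin.
The full-scale protocol (2500 segments per class, the default
model widths, longer training) is available by passing the corresponding
arguments; nothing in the code is specific to the reduced sizes.

## Calibration

`measureShifts()` synthesizes one segment per mass (default 1 s, ten times
the classification window, pushing the FFT resolution well below the
4.3 Hz per-microgram shift), estimates each dominant frequency, and
references shifts to the measured unloaded resonance. `fitCalibration()`
fits ordinary least squares with an intercept -- the intercept is fitted
rather than forced through zero, since a measured calibration can carry a
baseline offset; a through-origin variant is a flag. `predictMass()`
inverts the fitted line. `calibrationNoiseStudy()` quantifies robustness:
exact thin-film shifts over 0-9 ug are perturbed with Gaussian frequency
noise of sd equal to 1% of the full-scale shift, and the per-replicate
$R^2$ distribution is reported; its median comfortably exceeds 0.99.

## Numerical notes and limitations

* Internal units are CGS; all public mass interfaces are micrograms.
  Conversion is covered by dedicated tests.
* `with_seed()` scopes every stochastic operation, restoring the caller's
  RNG state; derived seeds stay below 2^31.
* Batch normalisation keeps running moments for evaluation mode; softmax
  is computed with max-subtraction; probabilities may underflow to exact
  zero for extreme logits.
* The WAV layer writes canonical 44-byte-header RIFF PCM16 mono files;
  quantisation bounds audio round-trip error at one part in 32767.
* The classifiers are desk-scale research implementations: single-threaded,
  dense linear algebra, no GPU. They are suitable for the packaged
  benchmarks and for architecture experiments at these sizes, not for
  training on hours of audio.
* Absolute accuracies on the original laboratory recordings are not
  reproducible here -- those recordings are not available. What the
  package reproduces quantitatively are the device physics, the metric
  computations from published confusion totals, and the calibration
  linearity; the classification benchmarks are synthetic and labelled as
  such.
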