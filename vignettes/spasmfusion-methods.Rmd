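---
title: "Dual-stream EEG-EMG fusion for infantile spasm detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-stream EEG-EMG fusion for infantile spasm detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Infantile epileptic spasms syndrome (IESS, West syndrome) produces brief,
clustered spasms whose electrographic signature is a high-voltage slow wave
with superimposed spikes followed by an abrupt electrodecremental
attenuation, while the motor signature is a short proximal-muscle
contraction that lags the cortical discharge. Automated detection from
synchronized scalp EEG (25 channels) and surface EMG (4 channels, deltoid
and quadriceps bilaterally) must cope with non-stationary signals, motion
artifacts that mimic muscle bursts, and the causal, time-decaying nature of
cortico-muscular coupling. `spasmfusion` implements a dual-stream detector
for 1-s analysis windows of such recordings, together with the full
preprocessing/windowing/evaluation protocol and a synthetic cohort
generator, so that every stage is testable without clinical data.

## Architecture

Each modality passes through a **unimodal encoder**:

1. **CWT band front end.** A continuous wavelet transform with a complex
   Morlet mother wavelet (`psi(t) = pi^(-1/4) e^{i w0 t} e^{-t^2/2}`,
   `w0 = 6`) is applied per channel; coefficient magnitudes are averaged
   over `scales_per_band = 8` log-spaced center frequencies strictly inside
   each of four physiological bands (EEG: 1-4, 4-13, 13-30, 30-70 Hz; EMG:
   5-70, 70-150, 150-250, 250-500 Hz at the native rate), giving a
   `4 x C x T` scalogram. The scale-frequency map is `f = w0 / (2 pi a)`.
   The transform has no learnable parameters.
2. **ST-Conv.** A temporal convolution (kernel `1 x 25`, 4 -> 16 features),
   batch normalization and LeakyReLU (slope 0.01), then a spatial
   convolution across electrodes (kernel `13 x 1` for EEG, `3 x 1` for EMG,
   16 -> 4 features), again BN + LeakyReLU, plus a `1 x 1` residual path
   from the input. Same-padding preserves `C` and `T`. These are full (not
   depthwise-factorized) convolutions with biases: that reading reproduces
   the published ~4.4 K total parameter count exactly (2,512 + 1,872 =
   4,384), which a depthwise factorization does not.
3. **Bi-Mamba.** The flattened `T x D` sequence (`D = 4C`: 100 for EEG, 16
   for EMG) is expanded to `2E` with `E = 2D` and split into a forward and
   a backward stream. Per stream: causal depthwise convolution (kernel 4)
   with SiLU; a linear map `E -> E + 2N` producing the step size (softplus
   with a learnable bias, initialized so steps start in [0.001, 0.1]) and
   the broadcast input/output maps `B_t, C_t` (`N = 32`); the
   zero-order-hold discretized scan over the fixed diagonal
   `A = -diag(1..N)`; a learnable skip `D`; and a SiLU gate computed from
   the pre-convolution stream input. The backward stream runs on the
   reversed sequence and is re-reversed; the summed streams are projected
   back to `D`. `B_t` and `C_t` are shared (broadcast) across inner
   channels rather than per-channel: this is the reading consistent with
   the published ~0.25 M budget of the block.
4. **Projection.** Each encoder output is mapped linearly (with bias) to
   the common fused width `d_model = 128`. The architecture description
   leaves the reconciliation of the two native widths (100 vs 16) implicit;
   an explicit learned projection is this package's choice, and 128 is the
   unique clean width consistent with the published 0.23 M fusion budget.

**Cross Time-Mixing** then fuses the two `T x 128` sequences with linear
recurrent attention in both conditioning directions (EEG conditioned on
EMG, and the converse), with independent parameters per direction. Each
direction: RMSNorm (`eps = 1e-8`) on both inputs; token-shift interpolation
with **full `D x D` mixing matrices** applied as `M x_t + (I - M) x_{t-1}`
(the elementwise RWKV-style vector blend is available as
`mix_mode = "vector"`, but only the matrix reading reproduces the published
0.23 M budget: `2 x (7 x 128^2 + 2 x 128) + 4 x 128 = 230,400`);
receptance from the query stream, key/value from the context stream; the
channel-wise WKV recurrence with learnable decay `omega` and current-token
bonus `u`; a sigmoid receptance gate; and a `D x D` output projection
without bias. Fusion is `RMSNorm(x_eeg + o_eeg) + RMSNorm(x_emg + o_emg)`.

The classifier pools the fused sequence over time and applies a two-layer
MLP (`128 -> 64 -> 2`) trained with two-class softmax cross-entropy (the
two-logit realization of binary cross-entropy).

### The WKV ordering ambiguity

Written literally, the recurrence updates the decayed state *before* the
output is formed, so the current token is counted both inside the state and
through the bonus term. The RWKV convention instead keeps the state one
step behind and lets the current token enter only via the bonus. Both are
implemented (`wkv_order = "rwkv"` default, `"literal"` optional) and both
are verified against an O(T^2) direct-summation oracle; the default follows
the RWKV convention since the literal form double-counts the current token.
The recurrence is executed in log space with a running maximum, so keys of
magnitude several hundred (which overflow `exp` in real space) still give
finite outputs, and every output channel remains a convex combination of
the value history.

## Preprocessing and windowing protocol

EEG: zero-phase Butterworth band-pass 0.3-70 Hz (an order-4 high-pass and
order-4 low-pass cascade, applied forward-backward), a zero-phase 50 Hz
biquad notch with quality factor 30, then common-average re-referencing.
EMG: zero-phase band-pass 5-500 Hz. Every channel is z-scored per
recording (never pooled across recordings), after filtering. Windows are
1 s. Ictal windows start on a 0.2-s grid between `onset` and
`offset - 1 s` (inclusive, in either order), which yields all
fully-contained windows for events longer than the window and all
event-containing windows for shorter events - so a 0.4-s spasm still
contributes windows, and every window overlaps its event by at least
`min(0.5 s, duration)`. Non-ictal windows are non-overlapping 1-s tiles at
least 2 s away from every event boundary; the guard makes the two class
definitions mutually exclusive by construction. Classes are balanced by
uniform seeded subsampling of the majority; splits are by subject in an
8:1:1 ratio, so no subject contributes windows to two sets.

The exact ictal enumeration rule and the interictal guard distance are not
part of the published protocol (which specifies only the dense 0.2-s stride
and interictal sampling); both are explicit, configurable decisions here.

## Synthetic cohort generator

The generator emulates the *statistical structure the detector exploits*,
not physiology: per-channel `1/f` background (spectrally shaped white
noise), a common 50 Hz line component, and clustered spasm events. Each
event contributes (i) an EEG slow wave (1-3 Hz, amplitude `slow_gain = 3.5`
background-RMS units) under a smooth random electrode topography with
Poisson-superimposed spikes (3/s), (ii) an electrodecremental segment that
attenuates the background to `decrement_gain = 0.3` from the spike to the
event offset, and (iii) a band-limited EMG burst that rises within 30 ms,
is sustained until the event offset, then releases with `tau = 0.4 s`; the
burst onset lags the EEG spike by a truncated normal lag (mean 0.15 s,
sd 0.05 s). The electroclinical signature spans the whole annotated
interval - annotations mark the event, not dead air - so every
ictal-labeled window genuinely contains event content (with the early
implementation, where the signature occupied only the start of long events,
the silent annotated tails acted as label noise and demonstrably capped
attainable accuracy). Motion artifacts (4/min) contaminate
*both* modalities - an EMG burst morphologically similar to an ictal burst
plus a low-frequency EEG wobble without spike or decrement - so EMG alone
is a deliberately ambiguous witness of a spasm, mirroring the clinical
motivation for multimodal fusion. Event durations are uniform on
[0.4, 9.2] s and all annotations are snapped to the 0.1-s grid. The event
rate default of 3/min matches the published cohort statistics (1941 events
in 630 recording minutes).

Everything is a deterministic function of one integer seed. What passing
tests on this generator shows is that the pipeline recovers *planted*,
well-posed structure; it says nothing about hypsarrhythmic backgrounds,
montage artifacts, electrode failures, or inter-patient variability in real
recordings.

## Training protocol and desk scaling

The reference protocol is Adam at `lr = 1e-4`, batch 128, up to 100 epochs,
early stopping after 10 non-improving validation epochs ("improvement" =
strictly lower validation loss; training halts at the first epoch whose
distance from the best epoch exceeds the patience), restoring the
lowest-validation-loss state. Those are the `train_config()` defaults.

The packaged end-to-end experiments run at desk scale: 10 subjects with one
60-s recording each at 256 Hz (EMG analysis bands compressed to 5-30,
30-60, 60-90, 90-125 Hz and the EMG band-pass to 5-100 Hz, since the native
EMG bands exceed the reduced Nyquist frequency), giving roughly 550
balanced training windows. One minute per subject is the smallest size at
which each recording still contains a handful of motion artifacts - the
confound the fusion exists to resolve - so that the held-out subjects'
artifact windows are not out-of-distribution. The clinical protocol's step
budget (tens of thousands of optimizer steps) shrinks by two orders of
magnitude at this scale, so `train_preset_desk()` raises the learning rate
to `2e-3`, uses optimizer batches of 64, and caps training at 3 epochs with
patience 2; pilots of the same pipeline reached their best validation loss
within a few tens of optimizer steps, so the cap retains the converged
region. Scalogram features are standardized per band and channel with
statistics fitted on the training subjects only: raw magnitudes span orders
of magnitude across bands under a 1/f background (and the ST-Conv residual
path forwards that raw scale), which otherwise ill-conditions short
training runs. No log-compression is applied; the transform is affine. Optimizer batches of 128 are accumulated over
micro-batches of 32 windows, which bounds activation memory without
changing the gradient (up to the per-micro-batch batch-norm statistics).
Five independent runs vary only the initialization/shuffling seed, never
the subject split. Metrics are per-window; decisions are the argmax of the
two logits.

## Numerical choices

- All forward *and* backward passes are written in this package (R with
  C++ kernels for the sequential scans and convolutions); every backward
  pass is finite-difference checked in the test suite, and the two
  recurrences are additionally checked against naive oracles (dense
  matrix-exponential unrolling for the SSM scan; O(T^2) direct summation
  for WKV) to 1e-10 relative error.
- The CWT is computed by FFT convolution with the kernel truncated at five
  Gaussian standard deviations (`|t/a| <= 5`) and trapezoid-weighted
  endpoint taps; with zero boundary handling it matches direct trapezoidal
  quadrature to better than 1e-6 relative error. Reflect padding is the
  default for analysis windows.
- Batch normalization uses batch statistics during training; inference uses
  running statistics kept as a cumulative average over all training batches,
  so early-stopping comparisons across epochs are made with meaningful
  inference-mode normalization from the first epoch on.
- Initialization: Glorot-uniform matrices, zero biases, unit norm gains;
  token-shift matrices start near `0.5 I`; SSM step-size biases are drawn
  so initial steps are uniform in [0.001, 0.1]; decays `omega` start in
  [0.1, 1]. Construction is bit-reproducible from one seed.
- Degenerate inputs fail loudly: constant channels cannot be z-scored,
  scalogram bands above Nyquist are configuration errors, windows longer
  than the recording are rejected, and a metric with an empty denominator
  is reported `NA`, never 0.

## Known limitations

- The clinical headline numbers of the underlying study are not
  reproducible here: the clinical recordings are proprietary, so end-to-end
  claims are made only on the synthetic cohort, qualitatively (fusion
  should beat EMG-only; accuracy should be high on well-posed planted
  structure).
- Wall-clock cost in R is orders of magnitude above a GPU framework; the
  desk preset is sized accordingly. The sequential scans are exact, not
  fused/parallel kernels.
- EDF import is not provided; recordings enter through the package's native
  container or in memory.
- Event-level alarm post-processing (merging window decisions into event
  detections) is out of scope; all metrics are per-window.
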