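---
title: "Methods: multimodal seizure detection on a synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal seizure detection on a synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`seizpipe` implements a multimodal seizure-detection pipeline — adaptive
denoising, engineered EEG and image descriptors, and a soft-voted ensemble of
two compact convolutional classifiers — together with the synthetic data
needed to exercise it end to end. This vignette explains the models, the
parameters that matter, the synthetic-data design, and the numerical and
design choices made where more than one reading was defensible. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## Denoising models

**G-MF (signals).** Stage one smooths with a per-sample Gaussian kernel over
a window of half-width `N` (default 3, i.e. a 7-sample window); the kernel
width at sample *i* is `sigma_i = max(phi * var_i, sigma_min)`, where `var_i`
is the local population variance over the same window. Volatile stretches
receive wide kernels, quiet stretches near-delta kernels. Stage two applies a
running median of the same width. Defaults: `phi = 0.5` (dimensionless gain),
`sigma_min = 0.5` samples. Two readings of the width rule exist because a
variance (squared microvolts) is being assigned to a kernel width (samples);
the literal product rule is the default and a `sigma_mode = "sd"` variant
using `phi * sqrt(var_i)` is exposed. The discrete kernel is renormalized to
sum to one so constant signals pass through unchanged — without
renormalization the filter would not preserve the mean.

**AW-WF (images).** Per pixel, `beta * Med + (1 - beta) * Wiener`, where
`Med` is the window median and the Wiener term is `M + g (I - M)` with gain
`g = (s2 - v2) / s2`. The mixing weight
`beta = v2 / (s2 + lambda * alpha + eps)` uses the Sobel gradient magnitude
`alpha`, so edges (`alpha` large) and textured regions (`s2` large) lean on
the Wiener branch while flat noisy regions lean on the median. Defaults:
window 5, `lambda = 0.5`, `eps = 1e-8`. Numerical guards: the Wiener gain is
clamped to [0, 1] (the unclamped form amplifies noise wherever the local
variance falls below the noise floor, and is undefined at `s2 = 0`, where
the output is the local mean); `beta` is clamped to [0, 1] because the
formula can exceed 1 when `s2 + lambda * alpha + eps < v2` and convex mixing
requires it. The global noise variance defaults to the mean of the local
window variances — classic local-Wiener practice — and can be supplied
explicitly. The procedure's mean-assignment pass and the
autocorrelation-based power spectral density never enter the estimate, so
they are exposed only as `awwf_diagnostics()`.

**Boundaries.** Every windowed operation in the package uses whole-sample
reflect padding (the boundary sample is not duplicated). One consequence is
worth stating: a reflect-padded normalized-kernel smoother is row-stochastic
(each output is a weighted average) but not column-stochastic, so the *total*
intensity of a random image is preserved only up to boundary effects (about
1–2% on a 32x32 image), though constant images are preserved exactly. The
tests assert conservation at that boundary-limited tolerance.

## EEG descriptors

Welch band powers use 2-s Hann segments with 50% overlap (chosen so the
0.5-Hz-wide delta edge is resolved at the 256 Hz convention) over delta
0.5–4, theta 4–8, alpha 8–13, beta 13–30 and gamma 30–80 Hz, the gamma edge
capped at Nyquist; a band entirely above Nyquist is reported as a flagged
zero rather than an error. Temporal descriptors are Hjorth activity
(variance), mobility, complexity, line length, and zero-crossing rate per
second; mobility and complexity are defined as 0 on constant channels
(guarded divisions). Spectral roll-off defaults to the 85% point, a
conventional choice where only "a fixed percentage" is specified. The
canonical feature vector concatenates, electrode-major, 5 band powers and 5
temporal descriptors per channel, then the E-CSP block: `10 C + n_filters`
values, 252 at the 22-channel, 32-filter default. Roll-off is exposed as its
own operation but does not enter the 252-dimension layout, which is the only
arithmetic consistent with that contract.

## E-CSP

Trials are standardized against pooled resting-state statistics, squashed
through softsign (bounded in (-1, 1)) and then swish; the composition is
monotone and bounded, which damps outliers without reordering amplitudes.
Class covariances average per-trial outer products after frequency
weighting, then shrink toward the identity with `gamma1 = gamma2 = 0.1`
(enough to keep the rest covariance invertible on short trials without
biasing the spectrum noticeably). The spatial filters solve
`G1' w = lambda G2' w` via whitening — the only reading consistent with
extremizing the task-to-rest variance-ratio objective; the objective itself
is exposed as `ecsp_objective()` for diagnostics.

Two open points were settled as follows:

* **Frequency weighting.** The weighting function
  `w(f) = 1/(1 + 4((f - fc)/df)^2)` (defaults `fc = 5` Hz, `df = 4` Hz —
  centred on the 3–7 Hz ictal rhythm) can enter either as a spectral filter
  or as a scalar per-trial weight. The default multiplies each trial's
  spectrum by `sqrt(w(f))` inside `[fc - df, fc + df]` and zero outside, so
  the trial PSD is weighted by `w`; a `"scalar"` mode weighting each trial's
  covariance by `w` at its spectral peak, and a `"none"` mode, are exposed.
* **32 filters from 22 channels.** A 22-channel problem has only 22
  eigenvectors, yet the feature contract requires 32 projections. Filters
  are therefore taken alternately from the two ends of the eigenvalue
  spectrum — 16 from each — reusing eigenvectors where the two halves
  overlap. Both spectrum ends matter because small eigenvalues mark
  directions where the rest condition dominates, which is equally
  discriminative.
* **Feature mode.** The arithmetic mean of a zero-mean projected trial is
  essentially zero, so the default feature is the mean squared projected
  sample (log-free variance proxy); the literal mean is retained as
  `"literal_mean"`.

Singular rest covariances (possible at `gamma2 = 0`) get a small ridge
(`1e-8` of the mean diagonal) with a warning rather than an error.

## Image descriptors

**S-PHOG.** Gradients are centered differences of a Gaussian-smoothed image
(`sigma = 1` px default; the smoothing is the point of the descriptor — the
unsmoothed path is kept as `phog_descriptor()` for ablations). The masks are
applied as correlation; since unsigned orientation folds angles modulo 180
degrees, the sign convention does not alter the descriptor. Magnitudes are
normalized by the neighborhood magnitude sum plus `eps = 1e-8` (bounded by
1; a uniform field maps interior pixels to 1/9 with the default 3x3
neighborhood). Orientations are averaged as unit vectors over the same
neighborhood — the circular mean, immune to wrap-around — with a flagged
zero angle where opposite directions cancel. Histograms use `Z = 9` bins
over [0, 180) (both values conventional for oriented-gradient descriptors),
magnitude-weighted, over pyramid levels {0, 1} (cells in row-major order),
and the concatenated vector is L1-normalized to sum one; an all-zero
gradient image yields the uniform vector with a `degenerate` flag.

**Volumetric embedder.** Two 3x3x3 convolution/max-pool stages (32 then 64
channels, tanh) with weights drawn once from a seeded normal initialization,
followed by two random linear projections of pooled per-channel statistics:
a global 256-dim block and a 128-dim block pooled over a fixed lateral mask
(the outer thirds of the width axis). The embedder is deliberately untrained:
fixed random convolutional features keep the whole stack deterministic in
its seed, require no pretrained weights, and are a standard random-features
baseline; the 128-dim block is a clearly labelled stand-in for regional
connectivity descriptors, with no anatomical claim. 2-D inputs are lifted to
single-slice volumes (reflect padding makes the depth dimension neutral).

## Classifier stack

**Primitives.** The StGE activation is `x * tanh(softplus(x))` for
nonnegative inputs and `varpi * ELU(x) + vartheta * GELU(x)` for negative
ones; both branches vanish at 0, so the function is continuous there. The
scaling factors `varpi, vartheta` are consecutive iterates of the piecewise
chaotic map `x -> x/q` (below `q`) / `(1-x)/(1-q)` (at or above `q`), drawn
once at initialization (defaults `x0 = 0.3`, `q = 0.7`, nudged into
[0.01, 0.99] to stay strictly inside the unit interval) and not learned —
no update rule is defined for them. Updated batch normalization (UBN)
standardizes each channel with batch statistics and multiplies by a gate:
elementwise `StGE(xhat) * attention_norm(xhat)` scaled by a per-channel
max/mean blend (`chi = 0.5`) of the same quantity — the only shape-consistent
reading of a pooled scalar entering a per-element normalizer. Forcing the
gate to 1 recovers standard batch normalization exactly, which the tests
assert. SPCII attention aggregates the map across each spatial axis (mean
and max), passes the stacked aggregations through a small seeded 2-D
convolution with per-map standardization and ReLU, aggregates across
channels, refines with a kernel-3 1-D convolution and a sigmoid, and
re-weights the input by the resulting height and width profiles; zero input
with zero biases yields 0.5 profiles. Ghost modules produce `1/s` of their
output channels densely and the rest by depthwise transforms (`s = 2`),
always cheaper in parameters than the dense equivalent (closed-form counts
are exported).

**Architecture and training.** The dual-branch network routes the 252-dim
EEG vector through a 1-D branch and the 384-dim image vector, reshaped to a
16x24 map (a near-square factorization; nothing in the contract fixes the
2-D arrangement), through a 2-D branch — two depthwise-separable
convolution/UBN/tanh/max-pool stages of widths 32 and 64 plus SPCII per
branch — and fuses pooled per-channel summaries. The ghost network consumes
the concatenated 636-dim feature vector zero-padded onto a 20x32 map. The
convolutional trunks are *frozen at their seeded initialization* and only
the fully connected heads (128-64-2, ReLU, dropout 0.3 after the first
layer) are trained — Adam at learning rate 0.001, binary cross-entropy,
batch 32 (16 for the image-stream ghost network), at most 100 epochs with
early stopping on validation loss (patience 10) and best-weight restoration.
This random-features-plus-trained-head design keeps training CPU-scale and
bitwise reproducible in the seed while every forward contract of the stated
layer layout holds exactly; it is the package's own choice, and the obvious
cost is that the trunks never adapt to the data. Trunk batch statistics
(UBN) are computed over the record set presented to `seiz_represent()`; the
trunk is untrained and label-free, so computing it on all records before the
subject split introduces no label leakage.

**Fusion.** Soft voting averages the two classifiers' probability rows with
weights `psi` (default equal — no weighting rule is specified — renormalized
to sum one); the fused argmax breaks the exact-0.5 tie toward class 0,
deterministically.

## Synthetic data: what it does and does not emulate

Background EEG is pink (1/f) noise plus a low-amplitude 10 Hz alpha
component — the right spectral tilt for Welch-based features — at a ~10 uV
RMS scale. Seizure segments add a rhythmic oscillation with frequency drawn
uniformly from 3–7 Hz, a second harmonic at 0.3 relative amplitude, a
raised-cosine onset envelope active over 55–90% of the segment with onset
uniform in the remainder, and amplitude calibrated so the oscillation RMS is
at least 3x the background RMS. Defaults mirror the reference cohort
structure: 2500 segments (1250 per class), 22 channels at 256 Hz for 8 s,
24 subjects each holding both classes (an 18-channel option matches the
alternative storage convention). Phantoms are smooth ellipsoids with soft
edges and mild texture in [0, 1], 52-subject default cohort, with an
optional Gaussian lesion blob whose mask is recorded alongside a mirrored
control region. Corruption is additive Gaussian noise, salt-and-pepper
impulses at the data extremes (the regime median filtering targets), or
both.

What passing tests on these data show: the plumbing, the contracts, the
limit reductions, and the *orderings* (adaptive beats plain, smoothed beats
raw, fused beats single-modality) under controlled noise. What they do not
show: performance on real recordings — the generator has no artifacts
(blinks, muscle, electrode pops), no inter-subject spectral variability, no
hemodynamics, and its classes are linearly separable by construction (a
deliberate property, asserted by test, so that classifier training is
meaningful rather than hard). Benchmark accuracies near 1.0 are therefore a
property of the synthetic conditions, not a clinical claim.

## Problem sizes and numerical conventions

The test suite and the acceptance script run the five-fold pipeline at 240
samples over 12 subjects (4-s segments, 16x16 phantoms, 30-epoch cap) and
the stochastic filter/descriptor comparisons over 20 fixed seeds — sizes
chosen so a complete run stays in the minutes range on a single CPU while
each comparison retains a clear margin. The label-shuffle null uses 600
samples with a 50/15/35 split so the test partition (~200 samples) makes
the chance-level band [0.4, 0.6] a ±3-sigma statement. Generator defaults
themselves stay at the full cohort scale (2500 segments).

Other conventions: population (not sample) variances in all local window
statistics and batch normalization; eigen-decompositions via symmetric
whitening rather than direct inversion; exact-zero guards return flagged
zeros (roll-off of silence, orientation of cancelled neighborhoods) rather
than NaN; MCC is clamped to [-1, 1] against floating-point overshoot on
perfect confusions; undefined metrics (single-class denominators) are
reported as 0 with a warning; all `seed` arguments restore the caller's RNG
state, so every generator and training run is a pure function of its
arguments.

## Limitations

No real-data readers beyond NPY/JSON (EDF and NIfTI ingestion would bolt on
at the `eeg_record`/`brain_image` boundary); no end-to-end trunk training;
no artifact-subspace removal or connectivity features; the lateral-region
embedding block is a synthetic stand-in. The cross-validation harness,
metrics and fusion logic are modality-agnostic and would apply unchanged to
real cohorts.
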