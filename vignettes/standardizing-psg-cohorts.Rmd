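---
title: "Standardizing and serving multi-cohort PSG data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardizing and serving multi-cohort PSG data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepstore)
```

## The problem

Sleep-staging models generalize poorly when trained on one clinic's data,
so training sets are assembled from many polysomnography cohorts. Each
cohort differs in directory layout, signal format, electrode montage and
naming, stage vocabulary, sample rate and amplitude statistics.
`sleepstore` fixes a single standardization recipe and isolates everything
cohort-specific behind an adapter, then stores the harmonized result once
and serves training windows from it lazily.

## The standardization recipe and its assumptions

The recipe is a template method: the step order is frozen — list, read,
map channels, band-pass, scale, clip, resample, map labels, persist — and
an adapter (`EDFSidecarAdapter`, or a subclass) overrides only listing,
reading and the two translation tables. The package asserts this order in
its tests via an instrumentation hook on `portDataset()`.

Assumptions: signals are continuous single-night recordings; hypnograms
are scored on 30 s epochs; only head-mounted modalities (EEG, EOG) are
retained — channels outside the map are dropped (or rejected, if
`dropUnmapped = FALSE`). When signal and label coverage disagree, both are
truncated to the shorter coverage in whole epochs; we prefer discarding a
trailing fraction of an epoch over serving a window whose label is
unsupported by signal.

### Channel naming

Canonical names follow the grammar `SITE[-REFSITE]` over 10–10/10–5 scalp
site names plus `E1`/`E2` for the EOG electrodes. Both the classic
(`T3`, `T5`) and modern (`T7`, `P7`) temporal names are accepted, since
cohort montages use either; mastoid references may be written `M1`/`M2`
and are normalized to `A1`/`A2` so that one session never mixes the two
spellings of the same reference.

### Parameters that matter

* `targetSampleRate` (Hz, default **128**): a common rate for all stored
  channels, high enough for the spindle band and typical raw-input models;
  configurable for other needs.
* `bandpass` (Hz, default **off**): optional `c(low, high)` zero-phase
  (forward–backward) Butterworth band-pass, order 2 per pass. Zero-phase
  filtering is required because hypnogram alignment must not be shifted by
  filter group delay. Order 2 per pass (4 effective) attenuates the
  45–64 Hz band of white noise at 128 Hz by about 30 dB while keeping
  passband ripple negligible — the tests measure this by periodogram.
* `clipMultiplier` (IQR units, default **20**): artifact guard, below.
* `iqrEpsilon` (default **1e-8**): a channel whose IQR falls below this is
  treated as degenerate (flat or near-flat lead); it is centred but not
  divided, and flagged in `meta$degenerateChannels`, because dividing by a
  vanishing IQR would amplify quantization noise without bound.
* `includeChannels` (default all): the store keeps only listed canonical
  channels, to bound storage.

### Scaling, clipping and their order

Scaling is `x' = (x − mean(x)) / IQR(x)`, computed **per record and per
channel**, so each night of each lead is normalized against its own
amplitude statistics — robust to inter-clinic gain differences and to
heavy-tailed artifacts that would corrupt a standard-deviation scale.
Quartiles use linear interpolation between order statistics (R's type 7).
The convention is stated explicitly because IQR is convention-sensitive at
these vector lengths; the test suite checks the implementation against an
independently written sort-and-interpolate oracle.

Clipping bounds samples to `[-20, +20]` after scaling — symmetric about
zero, in units of the post-scaling IQR (which is 1 by construction). The
clip threshold is deliberately crude: it removes electrode-pop-scale
artifacts while leaving physiological amplitudes (a few IQR) untouched.
Clipping runs *before* resampling, following the recipe's row order
literally; consequently the stored signal can in principle carry minute
resampler overshoot above 20 near clipped spikes, though in practice
decimation attenuates isolated spikes and the bound holds in all tests.

### Resampling

Polyphase rational-ratio resampling (`signal::resample`) with its built-in
anti-aliasing low-pass. The rational ratio is derived at millihertz
resolution, and the output is pinned to exactly
`round(n_in * target / fs_in)` samples, so epoch arithmetic stays exact.
FFT-based resampling was rejected because length padding leaks spectral
energy and output lengths are harder to pin.

### Labels

Stage codes are `0..4` (`W, N1, N2, N3, REM`) with `-1` as the sentinel
for unscored/movement/unknown epochs: contiguous non-negative codes suit
loss functions, and the sentinel is excluded from metrics and from
all-sentinel sampling windows. Label maps are total over their declared
vocabulary — an unseen token is an error naming the token and record,
never a silent guess. Built-ins cover AASM words, R&K words
(`S3` and `S4` both map to N3, `MT` to the sentinel) and numeric codes.

## The store

One HDF5 file per dataset, groups `/<subject>/<session>` with one float32
array per channel under `psg/` and an int8 `hypnogram`. Float32 halves
storage against float64 at far below signal noise; datasets are chunked at
exactly one epoch of samples so epoch-aligned window reads fetch only the
needed chunks, and compression is off by default because training-time
read speed dominates storage cost. Session replacement is
delete-then-write; there is no versioning and no multi-writer support.
Epoch indexing is 0-based and half-open everywhere.

## Serving

Splits are assigned at **subject** granularity — all sessions of a subject
land in one partition — because within-subject correlations otherwise leak
between train and test. Within each non-holdout dataset,
`round(n * fraction)` subjects go to validation and test (default 15 %
each); whole datasets can be held out.

The random sampler draws dataset uniformly, then session uniformly within
the dataset, then a start epoch uniformly over eligible starts. The
two-stage scheme stops large cohorts from dominating every batch;
per-dataset weighting can be layered on top by the consumer. Windows whose
labels would be entirely sentinel are excluded from eligibility; mixed
windows are served, since loss masking is the consumer's concern. The
deterministic sampler tiles each session with consecutive non-overlapping
windows and drops tails shorter than one window rather than padding. The
default window of 35 epochs matches the sequence-input scale of current
sleep stagers.

Pipes are `Batch -> Batch` transformations composed left to right;
each stage's output is validated and failures name the stage. Stock
augmenters are illustrative implementations of the two interface kinds:
global (additive Gaussian noise, amplitude scaling — whole window) and
regional (zero-masking of one contiguous random sub-segment). Labels are
never modified by augmentation.

Spectrogram conversion resamples to 100 Hz and short-time-transforms each
30 s epoch with a 2 s taper and 1 s hop, zero-padding the 200-sample taper
to a 256-point FFT: 29 frames × 129 bins per epoch, log(|X| + 1e-6).
These defaults follow the input convention of spectrogram-based sequence
sleep stagers, where the FFT length is the next power of two above the
taper; with a 200-point FFT one would get 101 bins instead, so the FFT
length, not the taper length, fixes the bin count.

## Metrics

Confusion matrices are 5×5 over the AASM stages with rows as reference;
pairs with a sentinel on either side are dropped before counting — the
scorer abstained, so the pair carries no agreement information. Cohen's
κ = (p_o − p_e)/(1 − p_e) is undefined when p_e = 1 (both raters constant
and identical); the package raises an explicit error rather than returning
a silent `NA`. F1 is macro-averaged over classes present on at least one
side (matching per-dataset comparison tables in this literature);
support-weighted averaging is available via `weighted = TRUE`.

## The synthetic generator

`generateDataset()` emulates exactly what the standardization consumes: a
per-subject directory tree of EDF files with one-token-per-epoch sidecar
hypnograms, heterogeneous source channel names and sample rates (256, 128
and 100 Hz by default), amplitudes/offsets/noise in microvolts, occasional
spike artifacts, and first-order Markov hypnograms with plausible
overnight stage dynamics, emitted in AASM, R&K or numeric vocabulary
(R&K N3 epochs are emitted as `S3` or `S4` with equal probability so the
non-injective mapping is exercised). Ground truth is written to a separate
JSON so tests never read it through the pipeline under test.

What it does **not** emulate: physiological stage signatures (stages are
labels, not signal regimes), EDF+ embedded annotations, discontinuous
recordings, or non-head modalities. Passing tests therefore demonstrate
the correctness of the plumbing — renaming, scaling, clipping, resampling,
label mapping, storage, sampling, scoring — not staging performance on
real EEG.

## Numerical choices and degenerate inputs

* EDF is written with int16 quantization against a per-channel symmetric
  physical range; round-trip error is below half a quantization step and
  the tests cross-check the format against an independent reader.
* Vectors shorter than 2 samples cannot be scaled (quartiles undefined);
  empty channels and zero-channel files are errors.
* Degenerate (constant) channels are centred only, never divided.
* Split ties: `round()` decides partition sizes; a dataset with fewer than
  3 subjects cannot form three non-empty partitions and is rejected when
  both fractions are positive.
* Benchmark peak memory is the R-heap high-water mark (`gc(reset=TRUE)`
  delta), which is the quantity that separates whole-object
  deserialization from chunked partial reads.

## Problem sizes used by the tests

The suite runs on cohorts of 3 subjects × 2 sessions × 40–120 epochs,
sampler statistics on 10^5 draws, metric Monte-Carlo checks on 10^4
epochs, and the format benchmark on a 16-channel, 100-epoch record
(~25 MB HDF5). These sizes make the full suite run in about a minute while
keeping every statistical assertion at comfortable power.

## Known limitations

* Only EDF signals and text sidecar hypnograms are read out of the box;
  EDF+ annotation tracks need a custom adapter.
* No automatic download of public cohorts; users point adapters at local
  copies.
* No distributed sharding or training loops — the serving layer ends at
  the batch iterator.
* One writer per store file; concurrent porting of *different* datasets is
  safe (separate files), concurrent writes to one dataset are not.
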