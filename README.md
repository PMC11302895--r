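# sleepstore

Automatic sleep staging has moved to deep networks trained on *many*
polysomnography (PSG) cohorts at once, because single-clinic models carry
clinic-specific biases. But every cohort arrives differently: its own file
layout, electrode naming, stage vocabulary (AASM `W/N1/N2/N3/REM` vs the
older R&K `W/S1–S4/REM/MT`), sample rates, units and noise profile.
`sleepstore` is an R toolkit for sleep-EEG researchers that converts such
heterogeneous cohorts into one standardized hierarchical HDF5 data store and
then serves epoch-aligned training windows from it lazily.

## What it does

**Standardization** runs a fixed template recipe per record; a cohort
adapter supplies only what varies between cohorts (file listing, signal
reading, and the channel/label translation tables — for most new cohorts,
only the channel map):

1. list records, 2. read signals + hypnogram,
3. rename channels to the 10–10 electrode system (`C3-A2`, `E1-A2`, …),
4. optional zero-phase Butterworth band-pass at user-defined cut-offs,
5. robust normalization, per record and per channel:
   `x' = (x − mean(x)) / IQR(x)` (type-7 quartiles), so every channel has
   zero mean and unit interquartile range,
6. artifact clipping to `|x'| ≤ 20` (i.e. 20 times the post-scaling IQR),
7. polyphase resampling to a common 128 Hz,
8. hypnogram harmonization to AASM codes `0=W, 1=N1, 2=N2, 3=N3, 4=REM`
   (`-1` = unscored/movement),
9. persist into the store.

**The store** is one HDF5 file per dataset, laid out
`/<subject>/<session>/psg/<channel>` (float32, chunked by 30 s epochs) plus
`/<subject>/<session>/hypnogram` (int8) — so reading a window touches only
the requested byte ranges.

**Serving** provides subject-level train/val/test splits (no subject
straddles partitions), a two-stage random sampler (dataset uniform, then
session, then start epoch — small cohorts are not drowned out by large
ones), a deterministic tiling sampler for evaluation, composable batch
pipes with stock global/regional augmenters, and log-magnitude spectrogram
conversion (100 Hz, 2 s taper / 1 s hop → 29 frames × 129 bins per epoch)
for spectrogram-input models.

**Evaluation** computes per-record stage confusion matrices, Cohen's
κ = (p_o − p_e)/(1 − p_e), and macro/weighted F1, with CSV export.

A synthetic cohort generator (sinusoid + Gaussian noise channels, Markov
hypnograms, configurable source vocabulary, EDF + sidecar output with
ground truth kept separate) makes the whole pipeline testable end to end
without downloading any real cohort.

## Worked example

```r
library(sleepstore)

# a synthetic R&K-labelled cohort: 3 subjects x 2 nights x 1 h
spec <- SyntheticCohortSpec(datasetId = "demo", nSubjects = 3,
                            sessionsPerSubject = 2, epochsPerSession = 120L,
                            vocabularyId = "rk", seed = 7)
root <- file.path(tempdir(), "raw"); store <- file.path(tempdir(), "store")
generateDataset(spec, root)

report <- portDataset(syntheticAdapter(spec), root, PreprocessConfig(), store)
report
#> PortReport demo: 6 listed, 6 ported, 0 skipped

manifest <- buildManifest(store)
manifest
#> StoreManifest of /tmp/.../store
#>   datasets: 1, subjects: 3, sessions: 6, epochs: 720

split <- splitRecords(manifest, fractions = c(1/3, 1/3), seed = 1)
split
#> SplitSpec: test=1, train=1, val=1 (val=0.33, test=0.33, seed=1)

batch <- readBatch(store,
                   randomWindows(manifest, split, "train",
                                 windowEpochs = 35, n = 4, seed = 2),
                   channels = c("C3-A2", "E1-A2"))
batch
#> Batch: 4 windows x 2 channels x 134400 samples @ 128 Hz
```

Everything standardized: 6 sessions ported, R&K tokens mapped to AASM
codes, all channels at 128 Hz with zero mean, unit IQR and `|x| ≤ 20`; the
4-window batch was read lazily (35 epochs × 30 s × 128 Hz = 134 400 samples
per channel). Scoring a prediction against the stored hypnogram:

```r
truth <- readWindow(store, SampleWindow("demo", "s01", "n1", 0L, 120L),
                    character(0))$labels
set.seed(3)
pred <- ifelse(runif(120) < 0.85, truth, sample(0:4, 120, replace = TRUE))
cm <- stageConfusion(truth, pred)
sprintf("kappa = %.3f, macro F1 = %.3f", cohenKappa(cm), macroF1(cm))
#> "kappa = 0.868, macro F1 = 0.875"
```

A command-line front end (`inst/cli/sleepstore`) wraps the same functions:
`port <config.yaml>`, `inspect <store> [--json]`, `sample <store>`, and
`benchmark` (the HDF5/Parquet/RDS read benchmark; see
`inst/extdata/example-config.yaml` for the config schema).

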