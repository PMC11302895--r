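Package: sleepstore
Title: Standardization, Storage and Serving of Multi-Cohort Polysomnography Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts heterogeneous polysomnography (PSG) cohorts into a single
    standardized hierarchical HDF5 data store and serves epoch-aligned windows
    from it for machine-learning sleep staging. Per-cohort adapters supply only
    record listing, signal reading and channel/label translation tables; a fixed
    template recipe performs channel renaming to the 10-10 electrode system,
    optional zero-phase band-pass filtering, robust per-record IQR
    normalization, outlier clipping, resampling to a common rate and hypnogram
    harmonization to AASM stage codes. The serving layer provides subject-level
    train/validation/test splits, seeded random and deterministic window
    samplers, composable batch pipes, regional/global augmenters, spectrogram
    conversion, and agreement metrics (Cohen's kappa, macro F1). A synthetic
    cohort generator with known ground truth makes every stage testable without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    rhdf5,
    signal,
    yaml,
    jsonlite,
    arrow
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
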