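# sleepstore port configuration.
#
# adapter.channel_map: source label -> canonical 10-10 name. Values are
#   either a bare string or {name: ..., modality: EEG|EOG}. Mastoid aliases
#   M1/M2 are normalized to A1/A2.
# adapter.label_map: a builtin vocabulary id ("aasm", "rk", "numeric") or
#   {vocabulary: <id>, entries: {token: code, ...}} with codes in
#   {-1, 0, 1, 2, 3, 4} (-1 = unscored/movement).
# preprocess.bandpass: omit for no filtering.

adapter:
  dataset_id: synthA
  drop_unmapped: true
  channel_map:
    "EEG C3-A2": C3-A2
    "EEG C4-A1": C4-A1
    "EOG LOC-A2": {name: E1-A2, modality: EOG}
    "EOG ROC-A1": {name: E2-A1, modality: EOG}
  label_map: aasm

preprocess:
  target_sample_rate: 128
  clip_multiplier: 20
  # bandpass: [0.3, 35]
  # include_channels: [C3-A2, E1-A2]

cohort_root: /data/raw/synthA
store:
  path: /data/store
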