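cfg <- PreprocessConfig()

test_that("listing enumerates sessions deterministically and skips unannotated ones", {
  fx <- sharedCohort()
  ad <- syntheticAdapter(fx$spec)
  refs <- listRecords(ad, fx$root)
  expect_length(refs, 6L)
  ids <- vapply(refs, function(r) paste(subjectId(r), sessionId(r)), "")
  expect_identical(ids, sort(ids))
  expect_identical(unique(vapply(refs, datasetId, "")), "synthA")

  # a session with signals but no annotations is skipped with a warning
  root2 <- copyTree(fx$root, tempfile("cohort"))
  unlink(file.path(root2, "s02", "n2.hyp"))
  expect_warning(refs2 <- listRecords(ad, root2), "no annotations")
  expect_length(refs2, 5L)

  empty <- tempfile("empty"); dir.create(empty)
  expect_warning(refs3 <- listRecords(ad, empty), "no records")
  expect_length(refs3, 0L)
  expect_error(listRecords(ad, tempfile()), "does not exist")
})

test_that("reading yields raw signals and truncates coverage to whole epochs", {
  dir <- tempfile(); dir.create(dir)
  fs <- 32
  mk <- function(seconds) list(
    signal = rnorm(seconds * fs, sd = 20), sampleRate = fs)

  # signal 61.2 epochs, 61 labels -> truncated to 61 epochs
  writeEDF(file.path(dir, "a.edf"), list("EEG C3-A2" = mk(61 * 30 + 6)))
  writeLines(rep("W", 61), file.path(dir, "a.hyp"))
  ad <- EDFSidecarAdapter("d", defaultSyntheticChannelMap(), "aasm")
  rec <- readPsg(ad, RecordRef("d", "s", "a", file.path(dir, "a.edf"),
                               file.path(dir, "a.hyp")))
  expect_length(channelSignal(rec, "EEG C3-A2"), 61 * 30 * fs)
  expect_length(recordMeta(rec)$sourceLabels, 61)
  expect_length(hypnogram(rec), 0L)   # unmapped until mapLabels

  # labels shorter than the signal -> label count wins
  writeEDF(file.path(dir, "b.edf"), list("EEG C3-A2" = mk(60 * 30)))
  writeLines(rep("N2", 58), file.path(dir, "b.hyp"))
  rec2 <- readPsg(ad, RecordRef("d", "s", "b", file.path(dir, "b.edf"),
                                file.path(dir, "b.hyp")))
  expect_length(channelSignal(rec2, "EEG C3-A2"), 58 * 30 * fs)
})

test_that("channel mapping renames, drops or rejects as configured", {
  rec <- PSGRecord("d", "s", "n", list(
    "EEG C3-A2" = list(signal = rnorm(960), sampleRate = 32),
    "LOC-M2" = list(signal = rnorm(960), sampleRate = 32),
    "ECG" = list(signal = rnorm(960), sampleRate = 32)))
  cmap <- ChannelMap(data.frame(
    source = c("EEG C3-A2", "LOC-M2"),
    canonical = c("C3-A2", "E1-M2"),
    modality = c("EEG", "EOG")))
  expect_warning(out <- mapChannels(rec, cmap), "ECG")
  # mastoid alias normalized: E1-M2 -> E1-A2
  expect_identical(channelNames(out), c("C3-A2", "E1-A2"))
  expect_identical(unname(recordMeta(out)$modality["E1-A2"]), "EOG")
  expect_identical(unname(recordMeta(out)$originalChannelNames["C3-A2"]),
                   "EEG C3-A2")

  strict <- ChannelMap(cmap@entries, dropUnmapped = FALSE)
  expect_error(mapChannels(rec, strict), "unmapped channel")

  dup <- ChannelMap(data.frame(
    source = c("EEG C3-A2", "LOC-M2"), canonical = c("C3-A2", "C3-A2"),
    modality = c("EEG", "EEG")))
  expect_error(suppressWarnings(mapChannels(rec, dup)), "duplicate")
})

test_that("band-pass filtering attenuates out-of-band power and is optional", {
  set.seed(3)
  n <- 128 * 600
  rec <- PSGRecord("d", "s", "n", list(
    "C3-A2" = list(signal = rnorm(n), sampleRate = 128)))

  # no band configured -> bitwise identity
  expect_identical(filterChannels(rec, PreprocessConfig()), rec)

  out <- filterChannels(rec, PreprocessConfig(bandpass = c(0.3, 35)))
  x <- channelSignal(rec, "C3-A2")
  y <- channelSignal(out, "C3-A2")
  expect_length(y, n)
  pin <- periodogram(x, 128); pout <- periodogram(y, 128)
  band <- pin$freq >= 45 & pin$freq <= 64
  attenDb <- 10 * log10(sum(pout$power[band]) / sum(pin$power[band]))
  expect_lt(attenDb, -20)

  expect_error(PreprocessConfig(bandpass = c(35, 0.3)), "low < high")
  expect_error(filterChannels(rec, PreprocessConfig(bandpass = c(0.3, 70))),
               "Nyquist")
})

test_that("scaling centres and normalizes by the type-7 IQR", {
  mk <- function(x) PSGRecord("d", "s", "n", list(
    "C3-A2" = list(signal = x, sampleRate = 1)))
  out <- scaleChannels(mk(c(0, 1, 2, 3, 4)), cfg)
  expect_equal(channelSignal(out, "C3-A2"), c(-1, -0.5, 0, 0.5, 1))

  # constant channel: centred only, flagged
  expect_warning(out2 <- scaleChannels(mk(rep(7, 100)), cfg), "degenerate")
  expect_identical(channelSignal(out2, "C3-A2"), rep(0, 100))
  expect_identical(recordMeta(out2)$degenerateChannels, "C3-A2")

  # fixed point: already mean 0, IQR 1
  set.seed(8)
  z <- rnorm(501)
  z <- (z - mean(z)) / bruteIQR(z)
  z <- z - mean(z)
  out3 <- scaleChannels(mk(z), cfg)
  expect_lt(max(abs(channelSignal(out3, "C3-A2") - z)), 1e-9)

  expect_error(scaleChannels(mk(numeric(0)), cfg), "empty channel")
})

test_that("scaling agrees with brute-force sorted-interpolation quartiles", {
  set.seed(21)
  for (i in 1:50) {
    n <- sample(5:2000, 1)
    x <- rnorm(n, sd = runif(1, 0.1, 100)) + runif(1, -50, 50)
    rec <- PSGRecord("d", "s", "n",
                     list("C3-A2" = list(signal = x, sampleRate = 1)))
    got <- channelSignal(scaleChannels(rec, cfg), "C3-A2")
    expect_lt(max(abs(got - (x - mean(x)) / bruteIQR(x))), 1e-9)
  }
})

test_that("clipping saturates at the configured multiple of the IQR", {
  rec <- PSGRecord("d", "s", "n", list(
    "C3-A2" = list(signal = c(25, -100, 3, -7.3, 19.999), sampleRate = 1)))
  out <- clipChannels(rec, cfg)
  expect_equal(channelSignal(out, "C3-A2"), c(20, -20, 3, -7.3, 19.999))

  inRange <- PSGRecord("d", "s", "n", list(
    "C3-A2" = list(signal = runif(100, -7.3, 7.3), sampleRate = 1)))
  expect_identical(clipChannels(inRange, cfg), inRange)
})

test_that("resampling hits the target rate with exact output lengths", {
  mk <- function(x, fs) PSGRecord("d", "s", "n", list(
    "C3-A2" = list(signal = x, sampleRate = fs)))
  out <- resampleChannels(mk(rnorm(2560), 256), cfg)
  expect_length(channelSignal(out, "C3-A2"), 1280)
  expect_equal(sampleRates(out)[["C3-A2"]], 128)

  out2 <- resampleChannels(mk(rnorm(3000), 100), cfg)
  expect_length(channelSignal(out2, "C3-A2"), 3840)

  same <- mk(rnorm(1280), 128)
  expect_identical(resampleChannels(same, cfg), same)

  # a pure tone below the output Nyquist keeps its dominant frequency
  t <- (0:(256 * 120 - 1)) / 256
  tone <- mk(sin(2 * pi * 10 * t), 256)
  y <- channelSignal(resampleChannels(tone, cfg), "C3-A2")
  expect_lt(abs(dominantFreq(y, 128) - 10), 0.05)
})

test_that("label mapping is total over its vocabulary and idempotent", {
  rk <- builtinLabelMap("rk")
  rec <- PSGRecord("d", "s", "n",
    list("C3-A2" = list(signal = rnorm(7 * 30), sampleRate = 1)),
    meta = list(sourceLabels = c("W", "S1", "S2", "S3", "S4", "REM", "MT")))
  out <- mapLabels(rec, rk)
  expect_identical(hypnogram(out), c(0L, 1L, 2L, 3L, 3L, 4L, -1L))

  aasm <- builtinLabelMap("aasm")
  expect_identical(unname(aasm@entries["W"]), 0L)

  bad <- PSGRecord("d", "s", "n",
    list("C3-A2" = list(signal = rnorm(30), sampleRate = 1)),
    meta = list(sourceLabels = "??"))
  expect_error(mapLabels(bad, rk), "\\?\\?")

  # idempotence: re-applying the same map reproduces the same hypnogram
  twice <- mapLabels(out, rk)
  expect_identical(hypnogram(twice), hypnogram(out))
})

test_that("porting runs the recipe steps in the fixed order", {
  fx <- sharedCohort()
  steps <- character(0)
  store <- tempfile("store")
  portDataset(syntheticAdapter(fx$spec), fx$root, cfg, store,
              stepHook = function(step, rec) steps <<- c(steps, step))
  perRecord <- c("readPsg", "mapChannels", "filterChannels",
                 "scaleChannels", "clipChannels", "resampleChannels",
                 "mapLabels", "persistRecord")
  expect_identical(steps, c("listRecords", rep(perRecord, 6)))
})

test_that("porting reports per-record failures without aborting the cohort", {
  fx <- sharedCohort()
  root2 <- copyTree(fx$root, tempfile("cohort"))
  # corrupt one EDF
  writeBin(as.raw(rep(0, 400)), file.path(root2, "s01", "n1.edf"))
  rep2 <- portDataset(syntheticAdapter(fx$spec), root2, cfg,
                      tempfile("store"))
  expect_equal(rep2@ported, 5L)
  expect_equal(rep2@skipped, 1L)
  expect_equal(rep2@listed, 6L)
  bad <- rep2@records[rep2@records$status == "skipped", ]
  expect_identical(paste(bad$subject, bad$session), "s01 n1")
  expect_match(bad$message, "corrupt|header")
})

test_that("re-porting a cohort leaves the manifest unchanged", {
  fx <- sharedCohort()
  m1 <- sessionTable(buildManifest(fx$store))
  rep2 <- portDataset(syntheticAdapter(fx$spec), fx$root, cfg, fx$store)
  expect_equal(rep2@ported, 6L)
  expect_identical(sessionTable(buildManifest(fx$store)), m1)
})

test_that("a new cohort needs only a new channel map", {
  # same layout, different source montage: the adapter overrides nothing
  # but the channel-map entries
  spec <- SyntheticCohortSpec(
    datasetId = "synthB", nSubjects = 1L, sessionsPerSubject = 1L,
    epochsPerSession = 10L, seed = 7L,
    channels = data.frame(
      label = c("F3:M2", "ROC"), sampleRate = c(64, 64), freq = c(6, 0.5),
      amplitude = c(40, 90), offset = c(0, 0), noiseSd = c(8, 12),
      spikeProb = 0, spikeAmp = 0))
  root <- tempfile()
  generateDataset(spec, root)
  adapter <- syntheticAdapter(spec, channelMap = ChannelMap(
    c("F3:M2" = "F3-A2", "ROC" = "E2")))
  report <- portDataset(adapter, root, cfg, store <- tempfile())
  expect_equal(report@ported, 1L)
  m <- sessionTable(buildManifest(store))
  expect_identical(m$channels, "E2;F3-A2")
  expect_equal(m$sampleRate, 128)
})

test_that("standardized channels satisfy the post-scaling contract", {
  fx <- sharedCohort()
  ad <- syntheticAdapter(fx$spec)
  ref <- listRecords(ad, fx$root)[[1]]
  rec <- scaleChannels(filterChannels(mapChannels(readPsg(ad, ref),
                                                  ad@channelMap), cfg), cfg)
  for (nm in channelNames(rec)) {
    x <- channelSignal(rec, nm)
    expect_lt(abs(mean(x)), 1e-6)
    expect_lt(abs(bruteIQR(x) - 1), 1e-6)
  }
  done <- resampleChannels(clipChannels(rec, cfg), cfg)
  for (nm in channelNames(done)) {
    expect_lte(max(abs(channelSignal(done, nm))), 20)
    expect_equal(sampleRates(done)[[nm]], 128)
  }
})
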