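test_that("hypnogram generation follows the Markov chain", {
  # absorbing identity chain started in W stays in W
  absorbing <- SyntheticCohortSpec(transition = diag(5),
                                   initDist = c(1, 0, 0, 0, 0))
  h <- generateHypnogram(absorbing, 50L, seed = 1L)
  expect_identical(h$codes, rep(0L, 50))
  expect_identical(h$tokens, rep("W", 50))

  # uniform chain: every stage frequency 0.2 within binomial CI at 1e5
  unif <- SyntheticCohortSpec(transition = matrix(0.2, 5, 5),
                              initDist = rep(0.2, 5))
  h2 <- generateHypnogram(unif, 1e5L, seed = 2L)
  freqs <- tabulate(h2$codes + 1L, 5) / 1e5
  expect_true(all(abs(freqs - 0.2) < 0.01))

  # reproducible under seed
  h3 <- generateHypnogram(unif, 100L, seed = 9L)
  h4 <- generateHypnogram(unif, 100L, seed = 9L)
  expect_identical(h3, h4)

  # non-stochastic matrices are rejected at construction
  bad <- matrix(0.3, 5, 5)
  expect_error(SyntheticCohortSpec(transition = bad), "sum to 1")
})

test_that("generated sessions have the declared shape and statistics", {
  spec <- SyntheticCohortSpec(
    epochsPerSession = 60L,
    channels = data.frame(label = "EEG C3-A2", sampleRate = 256,
                          freq = 10, amplitude = 50, offset = 5,
                          noiseSd = 10, spikeProb = 0, spikeAmp = 0))
  dir <- tempfile()
  res <- generateSession(spec, "s01", "n1", dir, seed = 4L)
  edf <- readEDF(res$signalPath)
  x <- edf$channels[["EEG C3-A2"]]$signal
  expect_length(x, 60 * 30 * 256)
  expect_length(readLines(res$labelPath), 60)

  # channel IQR within 10% of a Monte-Carlo oracle for the summed process
  set.seed(100)
  mc <- 50 * sin(2 * pi * runif(1e6)) + rnorm(1e6, sd = 10)
  expect_lt(abs(bruteIQR(x) - bruteIQR(mc)) / bruteIQR(mc), 0.1)

  # no spikes: Gaussian tail bound holds
  expect_lte(max(abs(x - 5)), 50 + 6 * 10)
})

test_that("cohorts are laid out on disk with ground truth kept separate", {
  spec <- SyntheticCohortSpec(datasetId = "rkset", nSubjects = 3L,
                              sessionsPerSubject = 2L,
                              epochsPerSession = 15L,
                              vocabularyId = "rk", seed = 5L)
  root <- tempfile()
  gen <- generateDataset(spec, root)
  edfs <- list.files(root, pattern = "\\.edf$", recursive = TRUE)
  hyps <- list.files(root, pattern = "\\.hyp$", recursive = TRUE)
  expect_length(edfs, 6L)
  expect_length(hyps, 6L)
  expect_true(file.exists(gen$groundTruthPath))

  # R&K sidecars contain only R&K tokens
  tokens <- unlist(lapply(file.path(root, hyps), readLines))
  expect_true(all(tokens %in% c("W", "S1", "S2", "S3", "S4", "REM", "MT")))

  # same seed -> byte-identical sidecars
  root2 <- tempfile()
  generateDataset(spec, root2)
  for (h in hyps)
    expect_identical(readLines(file.path(root2, h)),
                     readLines(file.path(root, h)))

  # collision guard
  expect_error(generateDataset(spec, root), "not empty")
})

test_that("porting recovers the generated ground truth exactly", {
  spec <- SyntheticCohortSpec(datasetId = "rkset2", nSubjects = 2L,
                              sessionsPerSubject = 2L,
                              epochsPerSession = 25L,
                              vocabularyId = "rk", seed = 6L)
  root <- tempfile(); store <- tempfile()
  gen <- generateDataset(spec, root)
  report <- portDataset(syntheticAdapter(spec), root, PreprocessConfig(),
                        store)
  expect_equal(report@ported, 4L)
  for (key in names(gen$truth)) {
    parts <- strsplit(key, "/")[[1]]
    h <- readWindow(store, SampleWindow("rkset2", parts[1], parts[2], 0L,
                                        length(gen$truth[[key]])),
                    character(0))$labels
    expect_true(all(h %in% -1:4))
    expect_identical(h, gen$truth[[key]])
  }
})

test_that("a 10 Hz tone with gross spikes survives the full chain", {
  # one EEG channel with spikes of 50x its own IQR
  base <- SyntheticCohortSpec(
    epochsPerSession = 60L,
    channels = data.frame(label = "EEG C3-A2", sampleRate = 256,
                          freq = 10, amplitude = 50, offset = 0,
                          noiseSd = 10, spikeProb = 0, spikeAmp = 0))
  dir0 <- tempfile()
  clean <- generateSession(base, "s01", "n1", dir0, seed = 8L)
  iqr0 <- bruteIQR(readEDF(clean$signalPath)$channels[[1]]$signal)

  spec <- SyntheticCohortSpec(
    datasetId = "spiky", nSubjects = 1L, sessionsPerSubject = 1L,
    epochsPerSession = 60L, seed = 8L,
    channels = data.frame(label = "EEG C3-A2", sampleRate = 256,
                          freq = 10, amplitude = 50, offset = 0,
                          noiseSd = 10, spikeProb = 0.2,
                          spikeAmp = 50 * iqr0))
  root <- tempfile(); store <- tempfile()
  generateDataset(spec, root)
  cfg <- PreprocessConfig(bandpass = c(0.3, 35))
  report <- portDataset(syntheticAdapter(spec), root, cfg, store)
  expect_equal(report@ported, 1L)
  x <- readWindow(store, SampleWindow("spiky", "s01", "n1", 0L, 60L),
                  "C3-A2")$signals[1, ]
  expect_lte(max(abs(x)), 20)
  expect_lt(abs(dominantFreq(x, 128) - 10), 0.1)
})
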