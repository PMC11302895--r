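test_that("splits assign whole subjects and honor the fractions", {
  store <- tempfile()
  makeTinyStore(store, "dsA", nSessions = 20L, epochs = 10L)
  m <- buildManifest(store)
  split <- splitRecords(m, fractions = c(0.15, 0.15), seed = 7L)
  tab <- table(assignmentTable(split)$partition)
  expect_equal(as.integer(tab[c("val", "test", "train")]), c(3L, 3L, 14L))

  # no subject straddles partitions
  a <- assignmentTable(split)
  expect_equal(anyDuplicated(a[c("dataset", "subject")]), 0L)

  # deterministic under seed replay; different under another seed
  split2 <- splitRecords(m, fractions = c(0.15, 0.15), seed = 7L)
  expect_identical(assignmentTable(split2), a)
  split3 <- splitRecords(m, fractions = c(0.15, 0.15), seed = 8L)
  expect_false(identical(assignmentTable(split3)$partition, a$partition))

  # zero fractions: everything trains
  all_train <- splitRecords(m, fractions = c(0, 0), seed = 1L)
  expect_true(all(assignmentTable(all_train)$partition == "train"))
})

test_that("holdout datasets are kept apart and tiny datasets rejected", {
  store <- tempfile()
  makeTinyStore(store, "dsA", nSessions = 5L, epochs = 10L)
  makeTinyStore(store, "dsHold", nSessions = 2L, epochs = 10L,
                subjectPrefix = "h")
  m <- buildManifest(store)
  split <- splitRecords(m, holdoutDatasets = "dsHold",
                        fractions = c(0.2, 0.2), seed = 1L)
  a <- assignmentTable(split)
  expect_true(all(a$partition[a$dataset == "dsHold"] == "holdout"))
  expect_setequal(unique(a$partition[a$dataset == "dsA"]),
                  c("train", "val", "test"))
  # 2 subjects cannot form 3 partitions
  expect_error(splitRecords(m, fractions = c(0.2, 0.2), seed = 1L),
               "cannot form 3 partitions")
})

test_that("the deterministic sampler tiles sessions without overlap", {
  store <- tempfile()
  persistRecord(store, makeStandardizedRecord("d", epochs = 100L, rate = 4))
  m <- buildManifest(store)
  w <- deterministicWindows(m, NULL, windowEpochs = 35L)
  expect_equal(nrow(w), 2L)
  expect_equal(w$startEpoch, c(0L, 35L))

  # exact cover when the length is a multiple of the window
  store2 <- tempfile()
  persistRecord(store2, makeStandardizedRecord("d", epochs = 70L, rate = 4))
  w2 <- deterministicWindows(buildManifest(store2), NULL,
                             windowEpochs = 35L)
  expect_equal(nrow(w2), 2L)

  # window 1 covers every epoch exactly once
  w3 <- deterministicWindows(buildManifest(store2), NULL, windowEpochs = 1L)
  expect_equal(w3$startEpoch, 0:69)

  # union size = sum floor(epochs / W) * W across a multi-session store
  fx <- sharedCohort()
  W <- 7L
  wAll <- deterministicWindows(fx$manifest, NULL, windowEpochs = W)
  covered <- sum(wAll$numEpochs)
  expect_equal(covered,
               sum((sessionTable(fx$manifest)$epochs %/% W) * W))
  key <- paste(wAll$dataset, wAll$subject, wAll$session)
  for (k in unique(key)) {
    st <- sort(wAll$startEpoch[key == k])
    expect_true(all(diff(st) >= W))   # no overlap
  }
})

test_that("random draws are uniform over eligible starts", {
  store <- tempfile()
  persistRecord(store, makeStandardizedRecord("d", epochs = 100L, rate = 4))
  m <- buildManifest(store)
  w <- randomWindows(m, windowEpochs = 35L, n = 2e4, seed = 123L)
  expect_true(all(w$startEpoch >= 0 & w$startEpoch <= 65))
  counts <- tabulate(w$startEpoch + 1L, nbins = 66L)
  p <- suppressWarnings(chisq.test(counts)$p.value)
  expect_gt(p, 0.01)
})

test_that("the two-stage draw balances datasets regardless of size", {
  store <- tempfile()
  makeTinyStore(store, "small", nSessions = 1L, epochs = 20L)
  makeTinyStore(store, "large", nSessions = 30L, epochs = 20L,
                subjectPrefix = "t")
  m <- buildManifest(store)
  w <- randomWindows(m, windowEpochs = 5L, n = 2e4, seed = 11L)
  fracSmall <- mean(w$dataset == "small")
  expect_lt(abs(fracSmall - 0.5), 0.02)
})

test_that("samplers are reproducible under a seed and vary across seeds", {
  fx <- sharedCohort()
  a <- randomWindows(fx$manifest, windowEpochs = 10L, n = 1000L, seed = 5L)
  b <- randomWindows(fx$manifest, windowEpochs = 10L, n = 1000L, seed = 5L)
  expect_identical(a, b)
  c <- randomWindows(fx$manifest, windowEpochs = 10L, n = 1000L, seed = 6L)
  expect_false(identical(a, c))
})

test_that("all-sentinel windows are never drawn", {
  store <- tempfile()
  rec <- makeStandardizedRecord("d", epochs = 30L, rate = 4)
  # epochs 0..19 unscored; only starts overlapping 20..29 are eligible
  hyp <- c(rep(-1L, 20), rep(2L, 10))
  rec <- PSGRecord("d", "s01", "n1", rec@channels, hypnogram = hyp)
  persistRecord(store, rec)
  m <- buildManifest(store)
  w <- randomWindows(m, windowEpochs = 10L, n = 500L, seed = 2L)
  expect_true(all(w$startEpoch >= 11))

  # a fully unscored session is not eligible at all
  store2 <- tempfile()
  rec2 <- PSGRecord("d", "s01", "n1", rec@channels,
                    hypnogram = rep(-1L, 30))
  persistRecord(store2, rec2)
  expect_error(randomWindows(buildManifest(store2), windowEpochs = 10L,
                             n = 1L, seed = 1L), "no session long enough")

  # too-short sessions are rejected
  expect_error(randomWindows(m, windowEpochs = 31L, n = 1L, seed = 1L),
               "no session long enough")
})

test_that("batches collate windows with consistent axes", {
  fx <- sharedCohort()
  w <- deterministicWindows(fx$manifest, NULL, windowEpochs = 10L)
  b <- readBatch(fx$store, w[1:4, ], c("C3-A2", "E1-A2"))
  expect_identical(dim(batchSignals(b)), c(4L, 2L, 10L * 30L * 128L))
  expect_identical(dim(batchLabels(b)), c(4L, 10L))
  expect_equal(b@sampleRate, 128)

  # split + iterator serve only the requested partition
  split <- splitRecords(fx$manifest, fractions = c(0, 0), seed = 1L)
  it <- batchIterator(fx$store, fx$manifest, split, "train",
                      channels = "C3-A2", windowEpochs = 10L,
                      batchSize = 3L, mode = "deterministic")
  n <- 0L
  while (!is.null(batch <- it())) n <- n + nrow(batch@provenance)
  expect_equal(n, nrow(deterministicWindows(fx$manifest, split, "train",
                                            10L)))
})
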