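# Shared fixtures, generated programmatically once per test run and reused
# across test files.

# A standardized in-memory record ready for persistRecord().
makeStandardizedRecord <- function(datasetId = "dsA", subject = "s01",
                                   session = "n1", epochs = 20L,
                                   rate = 32, channels = c("C3-A2", "C4-A1"),
                                   seed = 1L) {
  set.seed(seed)
  n <- as.integer(epochs * 30 * rate)
  chl <- lapply(stats::setNames(channels, channels), function(nm) {
    x <- rnorm(n)
    q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    list(signal = (x - mean(x)) / (q[2] - q[1]), sampleRate = rate)
  })
  hyp <- as.integer(sample(0:4, epochs, replace = TRUE))
  PSGRecord(datasetId, subject, session, chl, hypnogram = hyp)
}

# Recursive directory copy that never touches the source.
copyTree <- function(from, to) {
  files <- list.files(from, recursive = TRUE)
  for (f in files) {
    dest <- file.path(to, f)
    dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
    file.copy(file.path(from, f), dest)
  }
  to
}

# One synthetic 3x2 cohort + its ported store, built on first use.
.shared <- new.env(parent = emptyenv())

sharedCohort <- function() {
  if (!is.null(.shared$fixture)) return(.shared$fixture)
  root <- file.path(tempdir(), "shared-cohort")
  store <- file.path(tempdir(), "shared-store")
  spec <- SyntheticCohortSpec(datasetId = "synthA", nSubjects = 3L,
                              sessionsPerSubject = 2L,
                              epochsPerSession = 40L, seed = 42L)
  gen <- generateDataset(spec, root, overwrite = TRUE)
  report <- portDataset(syntheticAdapter(spec), root, PreprocessConfig(),
                        store)
  .shared$fixture <- list(root = root, store = store, spec = spec,
                          gen = gen, report = report,
                          manifest = buildManifest(store))
  .shared$fixture
}

# A store of many tiny standardized single-channel sessions, for sampler
# and laziness tests. Returns the store path.
makeTinyStore <- function(dir, datasetId, nSessions, epochs = 40L,
                          rate = 4, subjectPrefix = "s", seed = 99L) {
  for (i in seq_len(nSessions)) {
    rec <- makeStandardizedRecord(datasetId,
                                  sprintf("%s%03d", subjectPrefix, i),
                                  "n1", epochs = epochs, rate = rate,
                                  channels = "C3-A2", seed = seed + i)
    persistRecord(dir, rec)
  }
  dir
}
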