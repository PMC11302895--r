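## Synthetic cohort generation: multi-channel sinusoid + Gaussian-noise
## signals with optional spike artifacts, and first-order Markov hypnograms
## emitted in a configurable source vocabulary, written to disk in the same
## formats real cohorts arrive in (EDF + one-token-per-epoch sidecar).
## Stages are labels, not signal regimes: no physiological stage signatures
## are simulated.

## Plausible overnight stage dynamics (order W, N1, N2, N3, REM): strongly
## diagonal with the usual N1 -> N2 -> N3 progression and rare direct
## W <-> N3 jumps.
.defaultTransition <- function() {
  m <- matrix(c(
    0.900, 0.080, 0.010, 0.005, 0.005,
    0.050, 0.700, 0.230, 0.010, 0.010,
    0.010, 0.050, 0.850, 0.060, 0.030,
    0.005, 0.005, 0.100, 0.880, 0.010,
    0.030, 0.050, 0.060, 0.010, 0.850), 5, 5, byrow = TRUE)
  dimnames(m) <- list(.STAGE_NAMES, .STAGE_NAMES)
  m
}

#' Default synthetic channel set
#'
#' Two EEG leads and two EOG leads with heterogeneous source names and
#' sample rates (so renaming and resampling are both exercised): sinusoids
#' at rhythm-like frequencies with additive Gaussian noise and occasional
#' large spike artifacts, amplitudes in microvolts.
#'
#' @export
defaultSyntheticChannels <- function() {
  data.frame(
    label = c("EEG C3-A2", "EEG C4-A1", "EOG LOC-A2", "EOG ROC-A1"),
    sampleRate = c(256, 256, 128, 100),
    freq = c(10, 8, 0.5, 0.5),
    amplitude = c(50, 50, 100, 100),
    offset = c(0, 0, 10, -10),
    noiseSd = c(10, 10, 15, 15),
    spikeProb = c(0.02, 0.02, 0, 0),
    spikeAmp = c(3500, 3500, 0, 0))
}

## Channel map matching defaultSyntheticChannels().
defaultSyntheticChannelMap <- function() {
  ChannelMap(data.frame(
    source = c("EEG C3-A2", "EEG C4-A1", "EOG LOC-A2", "EOG ROC-A1"),
    canonical = c("C3-A2", "C4-A1", "E1-A2", "E2-A1"),
    modality = c("EEG", "EEG", "EOG", "EOG")))
}

#' @rdname SyntheticCohortSpec-class
#' @param datasetId,nSubjects,sessionsPerSubject,epochsPerSession,channels
#'   see slots; \code{epochsPerSession} a scalar or c(min, max) range.
#' @param transition,initDist Markov chain; defaults emulate overnight
#'   stage dynamics.
#' @param vocabularyId source vocabulary the cohort is labelled in.
#' @param seed cohort seed.
#' @export
SyntheticCohortSpec <- function(datasetId = "synthA", nSubjects = 3L,
                                sessionsPerSubject = 2L,
                                epochsPerSession = 60L,
                                channels = defaultSyntheticChannels(),
                                transition = .defaultTransition(),
                                initDist = c(0.9, 0.1, 0, 0, 0),
                                vocabularyId = "aasm", seed = 42L) {
  new("SyntheticCohortSpec", datasetId = datasetId,
      nSubjects = as.integer(nSubjects),
      sessionsPerSubject = as.integer(sessionsPerSubject),
      epochsPerSession = as.integer(epochsPerSession),
      channels = channels, transition = transition,
      initDist = initDist, vocabularyId = vocabularyId,
      seed = as.integer(seed))
}

#' Generate a Markov hypnogram
#'
#' First-order Markov chain realization over the 5 AASM stages, emitted both
#' as integer codes and as tokens of the spec's source vocabulary.
#'
#' @param spec a \linkS4class{SyntheticCohortSpec} (its transition matrix,
#'   initial distribution and vocabulary are used).
#' @param nEpochs chain length.
#' @param seed optional seed.
#' @return list with \code{codes} (integer 0-4) and \code{tokens}
#'   (character, source vocabulary).
#' @export
generateHypnogram <- function(spec, nEpochs, seed = NULL) {
  validObject(spec)
  tm <- spec@transition
  .withSeed(seed, {
    s <- integer(nEpochs)
    s[1] <- sample.int(5L, 1L, prob = spec@initDist)
    for (i in seq_len(nEpochs - 1L))
      s[i + 1L] <- sample.int(5L, 1L, prob = tm[s[i], ])
    codes <- s - 1L
    list(codes = codes, tokens = .emitTokens(spec@vocabularyId, codes))
  })
}

#' Generate one on-disk session
#'
#' Writes \code{<dir>/<session>.edf} and \code{<dir>/<session>.hyp} (one
#' stage token per line). Per channel the signal is
#' \code{offset + amplitude * sin(2 pi f t) + noise}, with spike artifacts
#' of \code{spikeAmp} microvolts injected at one random sample of each
#' epoch with probability \code{spikeProb}.
#'
#' @param spec a \linkS4class{SyntheticCohortSpec}.
#' @param subjectId,sessionId identity strings (used in the EDF header).
#' @param dir output directory (created if missing).
#' @param nEpochs session length; default drawn from
#'   \code{spec@epochsPerSession}.
#' @param seed optional seed.
#' @return list with \code{codes}, \code{tokens}, \code{signalPath},
#'   \code{labelPath}, invisibly.
#' @export
generateSession <- function(spec, subjectId, sessionId, dir,
                            nEpochs = NULL, seed = NULL) {
  validObject(spec)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  .withSeed(seed, {
    eps <- spec@epochsPerSession
    if (is.null(nEpochs))
      nEpochs <- if (length(eps) == 2L)
        sample(seq(eps[1], eps[2]), 1L) else eps[1]
    hyp <- generateHypnogram(spec, nEpochs)
    ch <- spec@channels
    channels <- list()
    for (i in seq_len(nrow(ch))) {
      fs <- ch$sampleRate[i]
      n <- as.integer(nEpochs * EPOCH_SECONDS * fs)
      t <- (seq_len(n) - 1L) / fs
      x <- ch$offset[i] + ch$amplitude[i] * sin(2 * pi * ch$freq[i] * t) +
        stats::rnorm(n, sd = ch$noiseSd[i])
      if (ch$spikeProb[i] > 0 && ch$spikeAmp[i] > 0) {
        spiky <- which(stats::runif(nEpochs) < ch$spikeProb[i])
        if (length(spiky)) {
          epochLen <- as.integer(EPOCH_SECONDS * fs)
          at <- (spiky - 1L) * epochLen +
            sample.int(epochLen, length(spiky), replace = TRUE)
          x[at] <- x[at] +
            ch$spikeAmp[i] * sample(c(-1, 1), length(spiky), replace = TRUE)
        }
      }
      channels[[ch$label[i]]] <- list(signal = x, sampleRate = fs)
    }
    signalPath <- file.path(dir, paste0(sessionId, ".edf"))
    labelPath <- file.path(dir, paste0(sessionId, ".hyp"))
    writeEDF(signalPath, channels, patientId = subjectId,
             recordingId = sessionId)
    writeLines(hyp$tokens, labelPath)
    invisible(list(codes = hyp$codes, tokens = hyp$tokens,
                   signalPath = signalPath, labelPath = labelPath))
  })
}

#' Generate a full synthetic cohort on disk
#'
#' Lays out \code{root/<subject>/<session>.edf|.hyp} for every subject and
#' session, plus \code{root/ground_truth.json} holding the true stage codes
#' and the generating parameters — kept apart from the "raw" files so tests
#' never peek through the pipeline under test.
#'
#' @param spec a \linkS4class{SyntheticCohortSpec}.
#' @param root cohort root directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return invisible list: \code{root}, \code{groundTruthPath},
#'   \code{sessions} (data.frame subject/session/epochs), \code{truth}
#'   (named list subject/session -> codes).
#' @export
generateDataset <- function(spec, root, overwrite = FALSE) {
  validObject(spec)
  if (dir.exists(root) && length(list.files(root)) && !overwrite)
    stop("directory exists and is not empty: ", root,
         " (use overwrite = TRUE)")
  if (!dir.exists(root)) dir.create(root, recursive = TRUE)
  subjects <- sprintf("s%02d", seq_len(spec@nSubjects))
  truth <- list()
  rows <- list()
  set.seed(spec@seed)
  for (sub in subjects) {
    for (k in seq_len(spec@sessionsPerSubject)) {
      ses <- sprintf("n%d", k)
      res <- generateSession(spec, sub, ses, file.path(root, sub))
      truth[[paste(sub, ses, sep = "/")]] <- res$codes
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sub, session = ses, epochs = length(res$codes))
    }
  }
  sessions <- do.call(rbind, rows)
  gt <- list(datasetId = spec@datasetId,
             vocabularyId = spec@vocabularyId,
             seed = spec@seed,
             channels = spec@channels,
             sessions = sessions,
             stages = truth)
  gtPath <- file.path(root, "ground_truth.json")
  jsonlite::write_json(gt, gtPath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(list(root = root, groundTruthPath = gtPath,
                 sessions = sessions, truth = truth))
}

#' Adapter for the bundled synthetic cohort layout
#'
#' An \linkS4class{EDFSidecarAdapter} whose channel map matches
#' \code{\link{defaultSyntheticChannels}} and whose label map is the spec's
#' vocabulary. Cohorts with custom channel sets need a custom map — and
#' only the map: every other step is inherited.
#'
#' @param spec a \linkS4class{SyntheticCohortSpec}.
#' @param channelMap override the channel map.
#' @export
syntheticAdapter <- function(spec, channelMap = defaultSyntheticChannelMap()) {
  EDFSidecarAdapter(spec@datasetId, channelMap = channelMap,
                    labelMap = builtinLabelMap(spec@vocabularyId))
}
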