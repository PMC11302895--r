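#' @import methods
NULL

## Stage coding used throughout: 0=W, 1=N1, 2=N2, 3=N3, 4=REM, -1=unscored /
## movement / unknown. The sentinel is excluded from metrics and from
## all-sentinel sampling windows, but is stored in the hypnogram as-is.
STAGE_CODES <- c(W = 0L, N1 = 1L, N2 = 2L, N3 = 3L, REM = 4L)
STAGE_SENTINEL <- -1L

## Scoring epoch length in seconds. Fixed: hypnograms are defined on 30 s
## epochs by the AASM scoring rules.
EPOCH_SECONDS <- 30

## Electrode site grammar for canonical channel names. Channels are named
## SITE or SITE-REFSITE where each SITE is a 10-10 / 10-5 scalp position
## (row prefix + z or a number), a mastoid (A1/A2; M1/M2 are accepted as
## aliases and normalized to A1/A2), or an EOG electrode (E1/E2).
.SITE_PREFIXES <- c("Fp", "AF", "F", "FT", "FC", "T", "C", "TP", "CP",
                    "P", "PO", "O", "I", "N", "A", "M", "E")
.SITE_REGEX <- paste0("^(", paste(.SITE_PREFIXES, collapse = "|"),
                      ")(z|10|[1-9])$")

isCanonicalSite <- function(x) grepl(.SITE_REGEX, x)

isCanonicalChannelName <- function(x) {
  parts <- strsplit(x, "-", fixed = TRUE)
  vapply(parts, function(p) {
    length(p) %in% c(1L, 2L) && all(isCanonicalSite(p))
  }, logical(1))
}

## Normalize mastoid aliases: M1 -> A1, M2 -> A2, in both site positions.
normalizeChannelName <- function(x) {
  parts <- strsplit(x, "-", fixed = TRUE)
  vapply(parts, function(p) {
    p[p == "M1"] <- "A1"
    p[p == "M2"] <- "A2"
    paste(p, collapse = "-")
  }, character(1))
}

#' Reference to one recording session on disk
#'
#' A lightweight pointer produced by record listing: identity of a session
#' plus the signal and annotation files that hold it. No data is read.
#'
#' @slot datasetId,subjectId,sessionId character scalars, non-empty.
#' @slot signalPaths paths to the signal file(s) (EDF).
#' @slot annotationPaths paths to hypnogram annotation file(s); may be empty
#'   only transiently (such records are skipped by listing).
#' @export
setClass("RecordRef", representation(
  datasetId = "character", subjectId = "character", sessionId = "character",
  signalPaths = "character", annotationPaths = "character"))

setValidity("RecordRef", function(object) {
  ids <- c(object@datasetId, object@subjectId, object@sessionId)
  if (length(ids) != 3L || any(!nzchar(ids)))
    return("datasetId, subjectId and sessionId must be non-empty scalars")
  if (length(object@signalPaths) < 1L)
    return("at least one signal path is required")
  TRUE
})

#' One night's polysomnography record
#'
#' The central in-memory container: a set of channels (each a numeric signal
#' with its sample rate), a hypnogram (one AASM stage code per 30 s epoch),
#' identity, and free-form metadata. Before label mapping the hypnogram slot
#' is empty and the raw source tokens live in \code{meta$sourceLabels};
#' before channel mapping the channel names are the source labels.
#'
#' @slot datasetId,subjectId,sessionId character scalars.
#' @slot channels named list; each element is \code{list(signal = numeric,
#'   sampleRate = numeric)}. Signals are in the source physical units
#'   (microvolts for EEG/EOG) until scaling.
#' @slot hypnogram integer vector of stage codes in \{-1, 0, ..., 4\};
#'   length 0 until \code{mapLabels} has run.
#' @slot meta list of provenance annotations (original channel names and
#'   rates, source vocabulary, ...).
#' @export
setClass("PSGRecord", representation(
  datasetId = "character", subjectId = "character", sessionId = "character",
  channels = "list", hypnogram = "integer", meta = "list"))

setValidity("PSGRecord", function(object) {
  ids <- c(object@datasetId, object@subjectId, object@sessionId)
  if (any(!nzchar(ids))) return("ids must be non-empty")
  ch <- object@channels
  if (length(ch)) {
    if (is.null(names(ch)) || anyDuplicated(names(ch)))
      return("channels must be uniquely named")
    for (nm in names(ch)) {
      c1 <- ch[[nm]]
      if (!is.list(c1) || !all(c("signal", "sampleRate") %in% names(c1)))
        return(sprintf("channel '%s' must have signal and sampleRate", nm))
      if (!is.numeric(c1$sampleRate) || c1$sampleRate <= 0)
        return(sprintf("channel '%s' has non-positive sample rate", nm))
    }
    durs <- vapply(ch, function(c1) length(c1$signal) / c1$sampleRate,
                   numeric(1))
    if (diff(range(durs)) > EPOCH_SECONDS)
      return("channel durations differ by more than one epoch")
  }
  h <- object@hypnogram
  if (length(h) && !all(h %in% c(STAGE_SENTINEL, STAGE_CODES)))
    return("hypnogram contains codes outside {-1,0,1,2,3,4}")
  TRUE
})

#' Translation table from source channel labels to canonical names
#'
#' @slot entries data.frame with columns \code{source}, \code{canonical},
#'   \code{modality} (\code{"EEG"} or \code{"EOG"}).
#' @slot dropUnmapped if TRUE, channels absent from the map are dropped with
#'   a warning; if FALSE they are an error.
#' @export
setClass("ChannelMap", representation(
  entries = "data.frame", dropUnmapped = "logical"))

setValidity("ChannelMap", function(object) {
  e <- object@entries
  if (!all(c("source", "canonical", "modality") %in% names(e)))
    return("entries needs columns source, canonical, modality")
  if (anyDuplicated(e$source))
    return("channel map must be functional: duplicated source labels")
  if (!all(e$modality %in% c("EEG", "EOG")))
    return("modality must be EEG or EOG")
  bad <- !isCanonicalChannelName(normalizeChannelName(e$canonical))
  if (any(bad))
    return(paste0("canonical names violate the SITE[-REFSITE] grammar: ",
                  paste(e$canonical[bad], collapse = ", ")))
  TRUE
})

#' Translation table from a source stage vocabulary to AASM codes
#'
#' @slot entries named integer vector: source token -> stage code in
#'   \{-1, 0, ..., 4\}. Movement/unknown tokens map to -1.
#' @slot vocabularyId character scalar naming the vocabulary.
#' @export
setClass("LabelMap", representation(
  entries = "integer", vocabularyId = "character"))

setValidity("LabelMap", function(object) {
  e <- object@entries
  if (is.null(names(e)) || any(!nzchar(names(e))))
    return("entries must be a named vector of stage codes")
  if (anyDuplicated(names(e))) return("duplicated source tokens")
  if (!all(e %in% c(STAGE_SENTINEL, STAGE_CODES)))
    return("codes must lie in {-1,0,1,2,3,4}")
  TRUE
})

#' Preprocessing configuration for the standardization recipe
#'
#' @slot targetSampleRate output rate in Hz (default 128).
#' @slot clipMultiplier clip bound in multiples of the post-scaling IQR
#'   (default 20).
#' @slot bandpass numeric(0) for no filtering, or c(low, high) in Hz.
#' @slot iqrEpsilon guard below which a channel's IQR is treated as
#'   degenerate (channel is centred only).
#' @slot includeChannels canonical names to retain; character(0) keeps all.
#' @export
setClass("PreprocessConfig", representation(
  targetSampleRate = "numeric", clipMultiplier = "numeric",
  bandpass = "numeric", iqrEpsilon = "numeric",
  includeChannels = "character"))

setValidity("PreprocessConfig", function(object) {
  if (object@targetSampleRate <= 0) return("targetSampleRate must be > 0")
  if (object@clipMultiplier <= 0) return("clipMultiplier must be > 0")
  bp <- object@bandpass
  if (length(bp) && (length(bp) != 2L || bp[1] <= 0 || bp[1] >= bp[2]))
    return("bandpass must be c(low, high) with 0 < low < high")
  if (object@iqrEpsilon < 0) return("iqrEpsilon must be >= 0")
  TRUE
})

#' Cohort adapter: the per-dataset part of the standardization recipe
#'
#' The template recipe (list, read, map channels, filter, scale, clip,
#' resample, map labels, persist) is fixed; an adapter supplies only what
#' varies between cohorts: how records are listed and read, and the channel
#' and label translation tables. Extend this class (or
#' \linkS4class{EDFSidecarAdapter}) and override as little as possible —
#' typically only the channel map.
#'
#' @slot datasetId identifier of the cohort.
#' @slot channelMap a \linkS4class{ChannelMap}.
#' @slot labelMap a \linkS4class{LabelMap}.
#' @export
setClass("CohortAdapter", representation(
  "VIRTUAL",
  datasetId = "character", channelMap = "ChannelMap", labelMap = "LabelMap"))

#' Adapter for cohorts stored as per-subject EDF files with text sidecars
#'
#' Expected layout: \code{root/<subject>/<session>.edf} with a hypnogram
#' sidecar \code{root/<subject>/<session>.hyp} holding one stage token per
#' 30 s epoch, one per line.
#'
#' @slot signalExt,labelExt file extensions of signal and sidecar files.
#' @export
setClass("EDFSidecarAdapter", contains = "CohortAdapter",
         representation(signalExt = "character", labelExt = "character"),
         prototype(signalExt = ".edf", labelExt = ".hyp"))

#' Inventory of a data store
#'
#' @slot store path of the store directory (one HDF5 file per dataset).
#' @slot sessions data.frame: dataset, subject, session, epochs, sampleRate,
#'   nChannels, channels (semicolon-joined canonical names).
#' @slot errors character vector describing malformed groups found on scan.
#' @export
setClass("StoreManifest", representation(
  store = "character", sessions = "data.frame", errors = "character"))

#' An epoch-aligned window into one stored session
#'
#' Half-open epoch interval [startEpoch, startEpoch + numEpochs), 0-based.
#' @export
setClass("SampleWindow", representation(
  datasetId = "character", subjectId = "character", sessionId = "character",
  startEpoch = "integer", numEpochs = "integer"))

setValidity("SampleWindow", function(object) {
  if (object@startEpoch < 0L) return("startEpoch must be >= 0")
  if (object@numEpochs < 0L) return("numEpochs must be >= 0")
  TRUE
})

#' Subject-level partition assignment
#'
#' @slot assignment data.frame: dataset, subject, partition in
#'   \{train, val, test, holdout\}.
#' @slot valFraction,testFraction requested fractions.
#' @slot seed integer seed that produced the assignment.
#' @export
setClass("SplitSpec", representation(
  assignment = "data.frame", valFraction = "numeric",
  testFraction = "numeric", seed = "integer"))

setValidity("SplitSpec", function(object) {
  a <- object@assignment
  if (!all(c("dataset", "subject", "partition") %in% names(a)))
    return("assignment needs dataset, subject, partition columns")
  if (!all(a$partition %in% c("train", "val", "test", "holdout")))
    return("unknown partition label")
  if (anyDuplicated(a[c("dataset", "subject")]))
    return("a subject is assigned twice")
  TRUE
})

#' A collated batch of sample windows
#'
#' @slot signals numeric array (window x channel x sample).
#' @slot labels integer matrix (window x epoch), codes in \{-1,0,...,4\}.
#' @slot provenance data.frame of the originating windows.
#' @slot sampleRate Hz of the signal axis.
#' @export
setClass("Batch", representation(
  signals = "array", labels = "matrix", provenance = "data.frame",
  sampleRate = "numeric"))

setValidity("Batch", function(object) {
  d <- dim(object@signals)
  if (length(d) != 3L) return("signals must be window x channel x sample")
  if (nrow(object@labels) != d[1])
    return("labels rows must equal the window axis")
  if (!all(object@labels %in% c(STAGE_SENTINEL, STAGE_CODES)))
    return("labels outside {-1,0,...,4}")
  if (nrow(object@provenance) != d[1])
    return("provenance rows must equal the window axis")
  TRUE
})

#' A batch converted to spectrograms
#'
#' @slot values numeric array (window x channel x frame x frequency bin) of
#'   log-magnitude short-time spectra.
#' @slot labels integer matrix (window x epoch).
#' @slot provenance data.frame of originating windows.
#' @slot frequencies Hz of the bin axis; \code{frameHop} seconds between
#'   frame centres.
#' @export
setClass("SpectrogramBatch", representation(
  values = "array", labels = "matrix", provenance = "data.frame",
  frequencies = "numeric", frameHop = "numeric"))

#' Augmentation specification
#'
#' @slot kind \code{"global"} (whole-window transform: \code{"noise"} adds
#'   Gaussian noise, \code{"scale"} rescales amplitude) or \code{"regional"}
#'   (\code{"mask"} zeroes a contiguous random sub-segment).
#' @slot transform one of \code{"noise"}, \code{"scale"}, \code{"mask"}.
#' @slot probability per-window application probability in [0, 1].
#' @slot magnitude transform-specific size: noise standard deviation (in
#'   post-scaling IQR units) or maximal relative amplitude change.
#' @slot fractionRange for regional transforms, c(lo, hi) bounds on the
#'   masked fraction of the window, each in (0, 1].
#' @export
setClass("AugmenterSpec", representation(
  kind = "character", transform = "character", probability = "numeric",
  magnitude = "numeric", fractionRange = "numeric"))

setValidity("AugmenterSpec", function(object) {
  if (!object@kind %in% c("global", "regional"))
    return("kind must be 'global' or 'regional'")
  if (object@probability < 0 || object@probability > 1)
    return("probability must lie in [0,1]")
  if (object@kind == "regional") {
    fr <- object@fractionRange
    if (length(fr) != 2L || fr[1] <= 0 || fr[2] > 1 || fr[1] > fr[2])
      return("fractionRange must be c(lo, hi) within (0,1]")
  }
  TRUE
})

#' Spectrogram conversion parameters
#'
#' Defaults follow the spectrogram-input convention of sequence-to-sequence
#' sleep stagers: signals are brought to 100 Hz, then each 30 s epoch is
#' short-time transformed with a 2 s taper and 1 s hop; the 200-sample taper
#' is zero-padded to a 256-point FFT, giving 29 frames x 129 bins per epoch.
#'
#' @slot intermediateRate Hz (default 100).
#' @slot windowSec,hopSec taper length and hop in seconds (defaults 2 and 1).
#' @slot taper \code{"hann"} or \code{"hamming"}.
#' @slot logOffset epsilon added before the log (default 1e-6).
#' @export
setClass("SpectrogramConfig", representation(
  intermediateRate = "numeric", windowSec = "numeric", hopSec = "numeric",
  taper = "character", logOffset = "numeric"))

setValidity("SpectrogramConfig", function(object) {
  if (object@hopSec <= 0 || object@windowSec < object@hopSec)
    return("need windowSec >= hopSec > 0")
  if (object@intermediateRate <= 0) return("intermediateRate must be > 0")
  if (!object@taper %in% c("hann", "hamming"))
    return("taper must be 'hann' or 'hamming'")
  if (object@logOffset <= 0) return("logOffset must be > 0")
  TRUE
})

#' Stage-agreement confusion matrix
#'
#' 5 x 5 counts over the AASM stages; rows are the reference, columns the
#' prediction. Epoch pairs where either side is the -1 sentinel are excluded
#' before counting.
#' @slot counts integer matrix with stage dimnames.
#' @export
setClass("StageConfusion", representation(counts = "matrix"))

setValidity("StageConfusion", function(object) {
  cm <- object@counts
  if (!identical(dim(cm), c(5L, 5L))) return("counts must be 5 x 5")
  if (any(cm < 0)) return("counts must be non-negative")
  TRUE
})

#' Specification of a synthetic PSG cohort
#'
#' Describes a cohort the generator writes to disk: per-channel band-limited
#' noise + sinusoid signals and first-order Markov hypnograms emitted in a
#' configurable source vocabulary.
#'
#' @slot datasetId cohort identifier.
#' @slot nSubjects,sessionsPerSubject cohort shape.
#' @slot epochsPerSession length-1 (fixed) or length-2 (uniform range).
#' @slot channels data.frame: label, sampleRate (Hz), freq (Hz), amplitude
#'   (uV), offset (uV), noiseSd (uV), spikeProb (per epoch), spikeAmp (uV).
#' @slot transition 5 x 5 row-stochastic stage transition matrix
#'   (order W, N1, N2, N3, REM).
#' @slot initDist initial stage distribution.
#' @slot vocabularyId \code{"aasm"}, \code{"rk"} or \code{"numeric"}.
#' @slot seed integer seed.
#' @export
setClass("SyntheticCohortSpec", representation(
  datasetId = "character", nSubjects = "integer",
  sessionsPerSubject = "integer", epochsPerSession = "integer",
  channels = "data.frame", transition = "matrix", initDist = "numeric",
  vocabularyId = "character", seed = "integer"))

setValidity("SyntheticCohortSpec", function(object) {
  tm <- object@transition
  if (!identical(dim(tm), c(5L, 5L))) return("transition must be 5 x 5")
  if (any(tm < 0) || any(abs(rowSums(tm) - 1) > 1e-9))
    return("transition rows must be non-negative and sum to 1")
  if (length(object@initDist) != 5L || abs(sum(object@initDist) - 1) > 1e-9)
    return("initDist must be a length-5 distribution")
  ch <- object@channels
  need <- c("label", "sampleRate", "freq", "amplitude", "offset",
            "noiseSd", "spikeProb", "spikeAmp")
  if (!all(need %in% names(ch)))
    return(paste("channels needs columns:", paste(need, collapse = ", ")))
  if (any(ch$sampleRate <= 0)) return("sample rates must be > 0")
  if (any(ch$spikeProb < 0 | ch$spikeProb > 1))
    return("spikeProb must lie in [0,1]")
  if (object@nSubjects < 1L || object@sessionsPerSubject < 1L)
    return("need at least one subject and one session")
  if (!length(object@epochsPerSession) %in% c(1L, 2L) ||
      any(object@epochsPerSession < 1L))
    return("epochsPerSession must be a positive scalar or range")
  TRUE
})

#' Outcome of porting one cohort into the store
#'
#' @slot datasetId cohort ported.
#' @slot listed,ported,skipped record counts; listed = ported + skipped.
#' @slot records data.frame: subject, session, status, message.
#' @slot warnings character vector of non-fatal messages.
#' @export
setClass("PortReport", representation(
  datasetId = "character", listed = "integer", ported = "integer",
  skipped = "integer", records = "data.frame", warnings = "character"))

#' File-format benchmark report
#'
#' @slot results data.frame: format, fileSizeMB, meanLoadMs, sdLoadMs,
#'   meanPeakMemMB.
#' @slot timesMs named list of per-trial load times (ms) per format.
#' @slot trials trial count; \code{machine} a free-form descriptor.
#' @export
setClass("BenchmarkReport", representation(
  results = "data.frame", timesMs = "list", trials = "integer",
  machine = "character"))

## ---- show methods -------------------------------------------------------

setMethod("show", "PSGRecord", function(object) {
  cat(sprintf("PSGRecord %s/%s/%s\n", object@datasetId, object@subjectId,
              object@sessionId))
  for (nm in names(object@channels)) {
    c1 <- object@channels[[nm]]
    cat(sprintf("  %-12s %8d samples @ %g Hz\n", nm, length(c1$signal),
                c1$sampleRate))
  }
  cat(sprintf("  hypnogram: %d epochs\n", length(object@hypnogram)))
})

setMethod("show", "StoreManifest", function(object) {
  s <- object@sessions
  cat(sprintf("StoreManifest of %s\n", object@store))
  cat(sprintf("  datasets: %d, subjects: %d, sessions: %d, epochs: %d\n",
              length(unique(s$dataset)),
              nrow(unique(s[c("dataset", "subject")])), nrow(s),
              if (nrow(s)) sum(s$epochs) else 0L))
  if (length(object@errors))
    cat("  errors:", length(object@errors), "\n")
})

setMethod("show", "Batch", function(object) {
  d <- dim(object@signals)
  cat(sprintf("Batch: %d windows x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], object@sampleRate))
})

setMethod("show", "SampleWindow", function(object) {
  cat(sprintf("SampleWindow %s/%s/%s epochs [%d, %d)\n", object@datasetId,
              object@subjectId, object@sessionId, object@startEpoch,
              object@startEpoch + object@numEpochs))
})

setMethod("show", "StageConfusion", function(object) {
  cat("StageConfusion (rows = reference):\n")
  print(object@counts)
})

setMethod("show", "PortReport", function(object) {
  cat(sprintf("PortReport %s: %d listed, %d ported, %d skipped\n",
              object@datasetId, object@listed, object@ported,
              object@skipped))
  if (length(object@warnings))
    cat(sprintf("  %d warning(s)\n", length(object@warnings)))
})

setMethod("show", "SplitSpec", function(object) {
  tab <- table(object@assignment$partition)
  cat("SplitSpec:", paste(names(tab), tab, sep = "=", collapse = ", "),
      sprintf("(val=%.2f, test=%.2f, seed=%d)\n", object@valFraction,
              object@testFraction, object@seed))
})

setMethod("show", "BenchmarkReport", function(object) {
  cat(sprintf("BenchmarkReport (%d trials, %s)\n", object@trials,
              object@machine))
  print(object@results, row.names = FALSE)
})
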