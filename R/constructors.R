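#' @rdname RecordRef-class
#' @param datasetId,subjectId,sessionId identity strings.
#' @param signalPaths,annotationPaths file paths.
#' @export
RecordRef <- function(datasetId, subjectId, sessionId, signalPaths,
                      annotationPaths = character(0)) {
  new("RecordRef", datasetId = as.character(datasetId),
      subjectId = as.character(subjectId),
      sessionId = as.character(sessionId),
      signalPaths = as.character(signalPaths),
      annotationPaths = as.character(annotationPaths))
}

#' @rdname PSGRecord-class
#' @param datasetId,subjectId,sessionId identity strings.
#' @param channels named list of \code{list(signal, sampleRate)}.
#' @param hypnogram integer stage codes (may be empty pre-mapping).
#' @param meta list of annotations.
#' @export
PSGRecord <- function(datasetId, subjectId, sessionId, channels,
                      hypnogram = integer(0), meta = list()) {
  new("PSGRecord", datasetId = as.character(datasetId),
      subjectId = as.character(subjectId),
      sessionId = as.character(sessionId), channels = channels,
      hypnogram = as.integer(hypnogram), meta = meta)
}

#' @rdname ChannelMap-class
#' @param entries data.frame with columns source, canonical, modality; or a
#'   named character vector source -> canonical (modality then defaults to
#'   EOG for targets touching E1/E2, EEG otherwise).
#' @param dropUnmapped drop (TRUE) or error on (FALSE) unmapped channels.
#' @export
ChannelMap <- function(entries, dropUnmapped = TRUE) {
  if (!is.data.frame(entries)) {
    src <- names(entries)
    canon <- unname(unlist(entries))
    eog <- grepl("(^|-)E[12](-|$)", canon)
    entries <- data.frame(source = src, canonical = canon,
                          modality = ifelse(eog, "EOG", "EEG"))
  }
  entries$canonical <- normalizeChannelName(entries$canonical)
  new("ChannelMap", entries = entries, dropUnmapped = isTRUE(dropUnmapped))
}

#' @rdname LabelMap-class
#' @param entries named integer-ish vector: token -> code.
#' @param vocabularyId name of the vocabulary.
#' @export
LabelMap <- function(entries, vocabularyId = "custom") {
  e <- as.integer(entries)
  names(e) <- names(entries)
  new("LabelMap", entries = e, vocabularyId = vocabularyId)
}

#' @rdname PreprocessConfig-class
#' @param targetSampleRate,clipMultiplier,bandpass,iqrEpsilon,includeChannels
#'   see the class slots.
#' @export
PreprocessConfig <- function(targetSampleRate = 128, clipMultiplier = 20,
                             bandpass = numeric(0), iqrEpsilon = 1e-8,
                             includeChannels = character(0)) {
  new("PreprocessConfig", targetSampleRate = targetSampleRate,
      clipMultiplier = clipMultiplier, bandpass = as.numeric(bandpass),
      iqrEpsilon = iqrEpsilon, includeChannels = includeChannels)
}

#' @rdname SampleWindow-class
#' @param datasetId,subjectId,sessionId identity of the session.
#' @param startEpoch 0-based first epoch; \code{numEpochs} window length.
#' @export
SampleWindow <- function(datasetId, subjectId, sessionId, startEpoch,
                         numEpochs) {
  new("SampleWindow", datasetId = datasetId, subjectId = subjectId,
      sessionId = sessionId, startEpoch = as.integer(startEpoch),
      numEpochs = as.integer(numEpochs))
}

#' @rdname AugmenterSpec-class
#' @param kind,transform,probability,magnitude,fractionRange see slots.
#' @export
AugmenterSpec <- function(kind = c("global", "regional"),
                          transform = NULL, probability = 1,
                          magnitude = 0.1, fractionRange = c(0.05, 0.2)) {
  kind <- match.arg(kind)
  if (is.null(transform))
    transform <- if (kind == "global") "noise" else "mask"
  new("AugmenterSpec", kind = kind, transform = transform,
      probability = probability, magnitude = magnitude,
      fractionRange = as.numeric(fractionRange))
}

#' @rdname SpectrogramConfig-class
#' @param intermediateRate,windowSec,hopSec,taper,logOffset see slots.
#' @export
SpectrogramConfig <- function(intermediateRate = 100, windowSec = 2,
                              hopSec = 1, taper = "hann",
                              logOffset = 1e-6) {
  new("SpectrogramConfig", intermediateRate = intermediateRate,
      windowSec = windowSec, hopSec = hopSec, taper = taper,
      logOffset = logOffset)
}

#' @rdname EDFSidecarAdapter-class
#' @param datasetId cohort identifier.
#' @param channelMap a \linkS4class{ChannelMap} (or object coercible by
#'   \code{\link{ChannelMap}}).
#' @param labelMap a \linkS4class{LabelMap} or a vocabulary id string known
#'   to \code{\link{builtinLabelMap}}.
#' @param signalExt,labelExt file extensions.
#' @export
EDFSidecarAdapter <- function(datasetId, channelMap, labelMap = "aasm",
                              signalExt = ".edf", labelExt = ".hyp") {
  if (!is(channelMap, "ChannelMap")) channelMap <- ChannelMap(channelMap)
  if (is.character(labelMap)) labelMap <- builtinLabelMap(labelMap)
  new("EDFSidecarAdapter", datasetId = datasetId, channelMap = channelMap,
      labelMap = labelMap, signalExt = signalExt, labelExt = labelExt)
}
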