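#' List all records of a cohort
#'
#' Step 1 of the standardization recipe: enumerate every session of every
#' subject under \code{root}, in deterministic lexicographic order, grouped
#' by subject. Sessions with signal files but no annotations are skipped
#' with a warning.
#'
#' @param adapter a \linkS4class{CohortAdapter}.
#' @param root cohort root directory.
#' @return list of \linkS4class{RecordRef}.
#' @export
setGeneric("listRecords", function(adapter, root) standardGeneric("listRecords"))

#' Read one record as a raw PSG
#'
#' Step 2 of the recipe: load signals (original units and sample rates) and
#' raw labels (kept in \code{meta$sourceLabels} until \code{\link{mapLabels}}).
#' Signal and label coverage are truncated to the shorter of the two, in
#' whole 30 s epochs.
#'
#' @param adapter a \linkS4class{CohortAdapter}.
#' @param ref a \linkS4class{RecordRef}.
#' @return a \linkS4class{PSGRecord} with source channel names and labels.
#' @export
setGeneric("readPsg", function(adapter, ref) standardGeneric("readPsg"))

#' Apply one pipe stage to a batch
#'
#' Pipes are composable batch-to-batch transformations; implement a subclass
#' of \linkS4class{Pipe} and a \code{pipeApply} method to extend the serving
#' pipeline.
#'
#' @param pipe a \linkS4class{Pipe}.
#' @param batch a \linkS4class{Batch} (or the output of an upstream pipe).
#' @return the transformed batch.
#' @export
setGeneric("pipeApply", function(pipe, batch) standardGeneric("pipeApply"))

#' @rdname accessors
#' @export
setGeneric("datasetId", function(x) standardGeneric("datasetId"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("sessionId", function(x) standardGeneric("sessionId"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("hypnogram", function(x) standardGeneric("hypnogram"))
#' @rdname accessors
#' @export
setGeneric("epochCount", function(x) standardGeneric("epochCount"))
#' @rdname accessors
#' @export
setGeneric("sampleRates", function(x) standardGeneric("sampleRates"))
#' @rdname accessors
#' @export
setGeneric("channelSignal", function(x, name) standardGeneric("channelSignal"))
#' @rdname accessors
#' @export
setGeneric("recordMeta", function(x) standardGeneric("recordMeta"))
#' @rdname accessors
#' @export
setGeneric("sessionTable", function(x) standardGeneric("sessionTable"))
#' @rdname accessors
#' @export
setGeneric("assignmentTable", function(x) standardGeneric("assignmentTable"))
#' @rdname accessors
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))
#' @rdname accessors
#' @export
setGeneric("batchSignals", function(x) standardGeneric("batchSignals"))
#' @rdname accessors
#' @export
setGeneric("batchLabels", function(x) standardGeneric("batchLabels"))

#' Accessors for sleepstore classes
#'
#' Small read-only accessors; prefer these over direct slot access.
#'
#' @param x an object of the documented classes.
#' @param name a canonical channel name.
#' @name accessors
NULL

setMethod("datasetId", "PSGRecord", function(x) x@datasetId)
setMethod("subjectId", "PSGRecord", function(x) x@subjectId)
setMethod("sessionId", "PSGRecord", function(x) x@sessionId)
setMethod("datasetId", "RecordRef", function(x) x@datasetId)
setMethod("subjectId", "RecordRef", function(x) x@subjectId)
setMethod("sessionId", "RecordRef", function(x) x@sessionId)
setMethod("datasetId", "SampleWindow", function(x) x@datasetId)
setMethod("subjectId", "SampleWindow", function(x) x@subjectId)
setMethod("sessionId", "SampleWindow", function(x) x@sessionId)
setMethod("channelNames", "PSGRecord", function(x) names(x@channels))
setMethod("hypnogram", "PSGRecord", function(x) x@hypnogram)
setMethod("epochCount", "PSGRecord", function(x) length(x@hypnogram))
setMethod("sampleRates", "PSGRecord", function(x)
  vapply(x@channels, function(c1) c1$sampleRate, numeric(1)))
setMethod("channelSignal", "PSGRecord", function(x, name) {
  if (!name %in% names(x@channels))
    stop(sprintf("no channel '%s'; available: %s", name,
                 paste(names(x@channels), collapse = ", ")))
  x@channels[[name]]$signal
})
setMethod("recordMeta", "PSGRecord", function(x) x@meta)
setMethod("sessionTable", "StoreManifest", function(x) x@sessions)
setMethod("assignmentTable", "SplitSpec", function(x) x@assignment)
setMethod("confusionCounts", "StageConfusion", function(x) x@counts)
setMethod("batchSignals", "Batch", function(x) x@signals)
setMethod("batchLabels", "Batch", function(x) x@labels)
setMethod("batchSignals", "SpectrogramBatch", function(x) x@values)
setMethod("batchLabels", "SpectrogramBatch", function(x) x@labels)
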