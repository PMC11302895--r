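## The common data store: a directory holding one HDF5 file per dataset,
## each laid out as /<subject>/<session>/psg/<channel> (1-D float32, chunked
## by whole 30 s epochs) plus /<subject>/<session>/hypnogram (1-D int8).
## Session-group attributes: sample_rate (Hz), epochs, and provenance
## strings. Chunking by epoch makes epoch-aligned partial reads touch only
## the requested byte ranges.

.datasetFile <- function(store, datasetId)
  file.path(store, paste0(datasetId, ".hdf5"))

.sessionPath <- function(subjectId, sessionId)
  paste0("/", subjectId, "/", sessionId)

#' Persist a standardized record into the store
#'
#' Step 9 of the recipe. The record must be fully standardized: canonical
#' channel names, a mapped hypnogram, and one common sample rate across
#' channels. Values are stored as 32-bit floats; re-persisting a session
#' replaces its group (delete-then-write).
#'
#' @param store store directory (created if missing).
#' @param rec a \linkS4class{PSGRecord}.
#' @return the HDF5 file path, invisibly.
#' @export
persistRecord <- function(store, rec) {
  stopifnot(is(rec, "PSGRecord"))
  validObject(rec)
  if (!length(rec@channels)) stop("record has no channels")
  if (!length(rec@hypnogram)) stop("record has no mapped hypnogram")
  rates <- sampleRates(rec)
  if (diff(range(rates)) != 0)
    stop("channels must share one sample rate before persisting")
  rate <- rates[[1]]
  lens <- vapply(rec@channels, function(c1) length(c1$signal), numeric(1))
  if (diff(range(lens)) != 0)
    stop("channel lengths differ; record is not standardized")
  nEpochs <- length(rec@hypnogram)
  if (lens[[1]] != nEpochs * EPOCH_SECONDS * rate)
    stop("signal length does not match hypnogram epochs")
  bad <- !isCanonicalChannelName(names(rec@channels))
  if (any(bad))
    stop("non-canonical channel name(s): ",
         paste(names(rec@channels)[bad], collapse = ", "))

  if (!dir.exists(store)) dir.create(store, recursive = TRUE)
  file <- .datasetFile(store, rec@datasetId)
  if (!file.exists(file)) rhdf5::h5createFile(file)
  ses <- .sessionPath(rec@subjectId, rec@sessionId)

  fid <- rhdf5::H5Fopen(file)
  subExists <- rhdf5::H5Lexists(fid, rec@subjectId)
  sesExists <- subExists && rhdf5::H5Lexists(fid, ses)
  rhdf5::H5Fclose(fid)
  if (sesExists) rhdf5::h5delete(file, ses)
  if (!subExists) rhdf5::h5createGroup(file, rec@subjectId)
  rhdf5::h5createGroup(file, ses)
  rhdf5::h5createGroup(file, paste0(ses, "/psg"))

  epochSamples <- as.integer(EPOCH_SECONDS * rate)
  for (nm in names(rec@channels)) {
    dsPath <- paste0(ses, "/psg/", nm)
    rhdf5::h5createDataset(file, dsPath, dims = lens[[1]],
                           storage.mode = "double",
                           H5type = "H5T_IEEE_F32LE",
                           chunk = min(epochSamples, lens[[1]]), level = 0)
    rhdf5::h5write(rec@channels[[nm]]$signal, file, dsPath)
  }
  rhdf5::h5createDataset(file, paste0(ses, "/hypnogram"), dims = nEpochs,
                         storage.mode = "integer",
                         H5type = "H5T_STD_I8LE",
                         chunk = nEpochs, level = 0)
  rhdf5::h5write(rec@hypnogram, file, paste0(ses, "/hypnogram"))

  fid <- rhdf5::H5Fopen(file)
  gid <- rhdf5::H5Gopen(fid, ses)
  rhdf5::h5writeAttribute(rate, gid, "sample_rate")
  rhdf5::h5writeAttribute(as.integer(nEpochs), gid, "epochs")
  vocab <- rec@meta$vocabularyId
  if (!is.null(vocab))
    rhdf5::h5writeAttribute(vocab, gid, "source_vocabulary")
  orig <- rec@meta$originalChannelNames
  if (!is.null(orig))
    rhdf5::h5writeAttribute(paste(names(orig), orig, sep = "=",
                                  collapse = ";"),
                            gid, "original_channel_names")
  rhdf5::H5Gclose(gid)
  rhdf5::H5Fclose(fid)
  rhdf5::h5closeAll()
  invisible(file)
}

#' Build the inventory of a data store
#'
#' Scans every dataset file in the store and returns the full
#' dataset/subject/session inventory with channel lists, epoch counts and
#' sample rates, in deterministic (sorted) order. Malformed session groups
#' (e.g. missing hypnogram) are listed under \code{errors}, not fatal.
#'
#' @param store store directory or a single \code{.hdf5} file.
#' @return a \linkS4class{StoreManifest}.
#' @export
buildManifest <- function(store) {
  files <- if (dir.exists(store)) {
    sort(list.files(store, pattern = "\\.hdf5$", full.names = TRUE))
  } else if (file.exists(store)) store else
    stop("store not readable: ", store)
  rows <- list()
  errors <- character(0)
  for (f in files) {
    ds <- sub("\\.hdf5$", "", basename(f))
    ls <- rhdf5::h5ls(f, recursive = TRUE)
    if (!nrow(ls)) next
    subjects <- sort(ls$name[ls$group == "/" & ls$otype == "H5I_GROUP"])
    for (sub in subjects) {
      sessions <- sort(ls$name[ls$group == paste0("/", sub) &
                               ls$otype == "H5I_GROUP"])
      for (ses in sessions) {
        grp <- paste0("/", sub, "/", ses)
        inGrp <- ls[ls$group == grp, ]
        if (!"hypnogram" %in% inGrp$name) {
          errors <- c(errors, sprintf(
            "%s:%s/%s: missing hypnogram", ds, sub, ses))
          next
        }
        chans <- sort(ls$name[ls$group == paste0(grp, "/psg")])
        at <- rhdf5::h5readAttributes(f, grp)
        rows[[length(rows) + 1L]] <- data.frame(
          dataset = ds, subject = sub, session = ses,
          epochs = as.integer(at$epochs),
          sampleRate = as.numeric(at$sample_rate),
          nChannels = length(chans),
          channels = paste(chans, collapse = ";"))
      }
    }
  }
  rhdf5::h5closeAll()
  sessions <- if (length(rows)) do.call(rbind, rows) else
    data.frame(dataset = character(0), subject = character(0),
               session = character(0), epochs = integer(0),
               sampleRate = numeric(0), nChannels = integer(0),
               channels = character(0))
  new("StoreManifest",
      store = if (dir.exists(store)) store else dirname(store),
      sessions = sessions, errors = errors)
}

#' Export a manifest as JSON
#'
#' @param manifest a \linkS4class{StoreManifest}.
#' @param path optional output file; if NULL the JSON string is returned.
#' @export
manifestJSON <- function(manifest, path = NULL) {
  obj <- list(store = manifest@store, sessions = manifest@sessions,
              errors = manifest@errors)
  js <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                         pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Lazily read one epoch window from the store
#'
#' Reads exactly the requested epoch range of the requested channels — only
#' those byte ranges are touched, so peak memory is bounded by the window,
#' not the session or the file.
#'
#' @param store store directory.
#' @param w a \linkS4class{SampleWindow}.
#' @param channels canonical channel names to read.
#' @return list with \code{signals} (channels x samples numeric matrix,
#'   rownames = channels) and \code{labels} (integer vector, one per epoch).
#' @export
readWindow <- function(store, w, channels) {
  stopifnot(is(w, "SampleWindow"))
  file <- .datasetFile(store, w@datasetId)
  if (!file.exists(file)) stop("no dataset file for ", w@datasetId)
  ses <- .sessionPath(w@subjectId, w@sessionId)
  at <- rhdf5::h5readAttributes(file, ses)
  nEpochs <- as.integer(at$epochs)
  rate <- as.numeric(at$sample_rate)
  if (w@startEpoch + w@numEpochs > nEpochs)
    stop(sprintf("window [%d, %d) out of bounds for session with %d epochs",
                 w@startEpoch, w@startEpoch + w@numEpochs, nEpochs))
  nSamp <- as.integer(w@numEpochs * EPOCH_SECONDS * rate)
  signals <- matrix(numeric(0), nrow = length(channels), ncol = nSamp,
                    dimnames = list(channels, NULL))
  if (nSamp > 0) {
    sampStart <- w@startEpoch * EPOCH_SECONDS * rate + 1
    for (i in seq_along(channels)) {
      dsPath <- paste0(ses, "/psg/", channels[i])
      fid <- rhdf5::H5Fopen(file)
      ok <- rhdf5::H5Lexists(fid, dsPath)
      rhdf5::H5Fclose(fid)
      if (!ok) {
        avail <- sort(rhdf5::h5ls(file)$name[
          rhdf5::h5ls(file)$group == paste0(ses, "/psg")])
        rhdf5::h5closeAll()
        stop(sprintf("unknown channel '%s'; available: %s", channels[i],
                     paste(avail, collapse = ", ")))
      }
      signals[i, ] <- rhdf5::h5read(file, dsPath, start = sampStart,
                                    count = nSamp)
    }
  }
  labels <- if (w@numEpochs > 0)
    as.integer(rhdf5::h5read(file, paste0(ses, "/hypnogram"),
                             start = w@startEpoch + 1,
                             count = w@numEpochs))
  else integer(0)
  rhdf5::h5closeAll()
  list(signals = signals, labels = labels)
}

## Full hypnogram of one stored session (used by samplers for eligibility).
.readHypnogram <- function(store, datasetId, subjectId, sessionId) {
  file <- .datasetFile(store, datasetId)
  h <- as.integer(rhdf5::h5read(
    file, paste0(.sessionPath(subjectId, sessionId), "/hypnogram")))
  rhdf5::h5closeAll()
  h
}
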