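## The standardization recipe. Step order is fixed:
##   list -> read -> map channels -> filter -> scale -> clip -> resample
##   -> map labels -> persist
## Adapters supply only listing, reading and the two translation tables.

#' Built-in stage vocabularies
#'
#' Returns the label map of a bundled vocabulary: \code{"aasm"} (tokens W,
#' N1, N2, N3, REM, ?), \code{"rk"} (Rechtschaffen & Kales: W, S1, S2, S3,
#' S4, REM, MT; S3 and S4 both map to N3, MT to the -1 sentinel) or
#' \code{"numeric"} (tokens "-1".."4").
#'
#' @param vocabularyId one of \code{"aasm"}, \code{"rk"}, \code{"numeric"}.
#' @return a \linkS4class{LabelMap}.
#' @export
builtinLabelMap <- function(vocabularyId) {
  entries <- switch(vocabularyId,
    aasm = c(W = 0L, N1 = 1L, N2 = 2L, N3 = 3L, REM = 4L, "?" = -1L),
    rk = c(W = 0L, S1 = 1L, S2 = 2L, S3 = 3L, S4 = 3L, REM = 4L, MT = -1L),
    numeric = c("-1" = -1L, "0" = 0L, "1" = 1L, "2" = 2L, "3" = 3L,
                "4" = 4L),
    stop("unknown vocabulary: ", vocabularyId))
  LabelMap(entries, vocabularyId = vocabularyId)
}

## Tokens the synthetic generator emits for AASM codes 0..4 and the -1
## sentinel. For R&K, N3 is emitted as S3 or S4 (both score as N3); the
## choice is random so the non-injective mapping is exercised.
.emitTokens <- function(vocabularyId, codes) {
  switch(vocabularyId,
    aasm = c("?", "W", "N1", "N2", "N3", "REM")[codes + 2L],
    rk = {
      tok <- c("MT", "W", "S1", "S2", "S3", "REM")[codes + 2L]
      n3 <- which(codes == 3L)
      if (length(n3))
        tok[n3] <- sample(c("S3", "S4"), length(n3), replace = TRUE)
      tok
    },
    numeric = as.character(codes),
    stop("unknown vocabulary: ", vocabularyId))
}

## ---- adapter methods ----------------------------------------------------

#' @rdname listRecords
setMethod("listRecords", "EDFSidecarAdapter", function(adapter, root) {
  if (!dir.exists(root)) stop("cohort root does not exist: ", root)
  subjects <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  refs <- list()
  for (sub in subjects) {
    edfs <- sort(list.files(file.path(root, sub),
                            pattern = paste0("\\", adapter@signalExt, "$"),
                            full.names = TRUE))
    for (edf in edfs) {
      ses <- sub(paste0("\\", adapter@signalExt, "$"), "", basename(edf))
      hyp <- file.path(root, sub, paste0(ses, adapter@labelExt))
      if (!file.exists(hyp)) {
        warning(sprintf("session %s/%s has signals but no annotations; skipped",
                        sub, ses), call. = FALSE)
        next
      }
      refs[[length(refs) + 1L]] <- RecordRef(
        adapter@datasetId, sub, ses, edf, hyp)
    }
  }
  if (!length(refs))
    warning("no records found under ", root, call. = FALSE)
  refs
})

#' @rdname readPsg
setMethod("readPsg", "EDFSidecarAdapter", function(adapter, ref) {
  edf <- readEDF(ref@signalPaths[1])
  if (!length(edf$channels)) stop("zero channels in ", ref@signalPaths[1])
  tokens <- readLines(ref@annotationPaths[1], warn = FALSE)
  tokens <- trimws(tokens)
  tokens <- tokens[nzchar(tokens)]
  sigEpochs <- floor(min(vapply(edf$channels, function(c1)
    length(c1$signal) / c1$sampleRate, numeric(1))) / EPOCH_SECONDS)
  nEpochs <- min(sigEpochs, length(tokens))
  channels <- lapply(edf$channels, function(c1) {
    n <- as.integer(nEpochs * EPOCH_SECONDS * c1$sampleRate)
    list(signal = c1$signal[seq_len(n)], sampleRate = c1$sampleRate)
  })
  PSGRecord(ref@datasetId, ref@subjectId, ref@sessionId, channels,
            meta = list(
              sourceLabels = tokens[seq_len(nEpochs)],
              sourceChannelNames = names(edf$channels),
              sourceSampleRates = vapply(edf$channels,
                                         function(c1) c1$sampleRate,
                                         numeric(1)),
              vocabularyId = adapter@labelMap@vocabularyId))
})

## ---- recipe steps -------------------------------------------------------

#' Rename channels to canonical 10-10 names
#'
#' Step 3: every retained channel is renamed by the cohort's channel map;
#' mastoid aliases M1/M2 are normalized to A1/A2. Channels absent from the
#' map are dropped with a warning (\code{dropUnmapped = TRUE}) or raise an
#' error. Original names are kept in \code{meta$originalChannelNames}.
#'
#' @param rec a \linkS4class{PSGRecord} with source channel names.
#' @param cmap a \linkS4class{ChannelMap}.
#' @return the record with canonical channel names.
#' @export
mapChannels <- function(rec, cmap) {
  stopifnot(is(rec, "PSGRecord"), is(cmap, "ChannelMap"))
  e <- cmap@entries
  src <- names(rec@channels)
  idx <- match(src, e$source)
  unmapped <- src[is.na(idx)]
  if (length(unmapped)) {
    if (!cmap@dropUnmapped)
      stop(sprintf("unmapped channel(s) in %s/%s: %s", rec@subjectId,
                   rec@sessionId, paste(unmapped, collapse = ", ")))
    warning(sprintf("dropping unmapped channel(s): %s",
                    paste(unmapped, collapse = ", ")), call. = FALSE)
  }
  keep <- !is.na(idx)
  canon <- e$canonical[idx[keep]]
  if (anyDuplicated(canon))
    stop(sprintf("duplicate canonical channel target(s) in %s/%s: %s",
                 rec@subjectId, rec@sessionId,
                 paste(canon[duplicated(canon)], collapse = ", ")))
  channels <- rec@channels[keep]
  names(channels) <- canon
  meta <- rec@meta
  meta$originalChannelNames <- stats::setNames(src[keep], canon)
  meta$modality <- stats::setNames(e$modality[idx[keep]], canon)
  initialize(rec, channels = channels, meta = meta)
}

#' Band-pass filter channels
#'
#' Step 4: zero-phase (forward-backward) Butterworth band-pass, order 2 per
#' pass, at the configured cut-offs. With no band configured this is the
#' identity.
#'
#' @param rec a \linkS4class{PSGRecord}.
#' @param cfg a \linkS4class{PreprocessConfig}.
#' @return the filtered record; signal lengths unchanged.
#' @export
filterChannels <- function(rec, cfg) {
  stopifnot(is(rec, "PSGRecord"), is(cfg, "PreprocessConfig"))
  bp <- cfg@bandpass
  if (!length(bp)) return(rec)
  channels <- lapply(rec@channels, function(c1) {
    nyq <- c1$sampleRate / 2
    if (bp[2] >= nyq)
      stop(sprintf("bandpass high cut %g Hz >= Nyquist %g Hz", bp[2], nyq))
    bf <- signal::butter(2, bp / nyq, type = "pass")
    c1$signal <- signal::filtfilt(bf, c1$signal)
    c1
  })
  initialize(rec, channels = channels)
}

## Interquartile range under the linear-interpolation ("type 7") quartile
## convention; the convention matters, so it is fixed here once.
channelIQR <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  q[2] - q[1]
}

#' Robust-normalize channels
#'
#' Step 5: per record and per channel, \code{x' = (x - mean(x)) / IQR(x)},
#' leaving each channel with zero mean and unit interquartile range.
#' Channels whose IQR falls below \code{iqrEpsilon} are degenerate
#' (near-constant): they are centred only and flagged with a warning.
#'
#' @inheritParams filterChannels
#' @return the scaled record; \code{meta$degenerateChannels} lists channels
#'   that were centred only.
#' @export
scaleChannels <- function(rec, cfg) {
  stopifnot(is(rec, "PSGRecord"), is(cfg, "PreprocessConfig"))
  if (!length(rec@channels)) stop("record has no channels to scale")
  degenerate <- character(0)
  channels <- rec@channels
  for (nm in names(channels)) {
    x <- channels[[nm]]$signal
    if (!length(x)) stop("empty channel: ", nm)
    iqr <- channelIQR(x)
    if (iqr < cfg@iqrEpsilon) {
      warning(sprintf("channel %s has degenerate IQR (%g); centred only",
                      nm, iqr), call. = FALSE)
      channels[[nm]]$signal <- x - mean(x)
      degenerate <- c(degenerate, nm)
    } else {
      channels[[nm]]$signal <- (x - mean(x)) / iqr
    }
  }
  meta <- rec@meta
  meta$degenerateChannels <- degenerate
  initialize(rec, channels = channels, meta = meta)
}

#' Clip outlier samples
#'
#' Step 6: after scaling, every sample is clipped to
#' \code{[-clipMultiplier, +clipMultiplier]} — i.e. to \code{clipMultiplier}
#' times the post-scaling IQR (which is 1 by construction), symmetric about
#' zero. In-range samples are untouched.
#'
#' @inheritParams filterChannels
#' @export
clipChannels <- function(rec, cfg) {
  stopifnot(is(rec, "PSGRecord"), is(cfg, "PreprocessConfig"))
  m <- cfg@clipMultiplier
  channels <- lapply(rec@channels, function(c1) {
    c1$signal <- pmin(pmax(c1$signal, -m), m)
    c1
  })
  initialize(rec, channels = channels)
}

## p/q rational approximation of a resampling ratio; exact for integer and
## millihertz-resolution rates.
.rationalRatio <- function(target, fs) {
  p <- round(target * 1000)
  q <- round(fs * 1000)
  g <- .gcd(p, q)
  c(p = p / g, q = q / g)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Resample channels to the target rate
#'
#' Step 7: polyphase rational-ratio resampling with an anti-aliasing
#' low-pass, to \code{cfg@targetSampleRate} (128 Hz by default). Output
#' length is \code{round(n * target / fs)}; channels already at the target
#' rate pass through unchanged.
#'
#' @inheritParams filterChannels
#' @export
resampleChannels <- function(rec, cfg) {
  stopifnot(is(rec, "PSGRecord"), is(cfg, "PreprocessConfig"))
  target <- cfg@targetSampleRate
  channels <- lapply(rec@channels, function(c1) {
    if (c1$sampleRate <= 0) stop("non-positive sample rate")
    if (c1$sampleRate == target) return(c1)
    pq <- .rationalRatio(target, c1$sampleRate)
    nOut <- round(length(c1$signal) * target / c1$sampleRate)
    y <- signal::resample(c1$signal, pq["p"], pq["q"])
    if (length(y) >= nOut) y <- y[seq_len(nOut)]
    else y <- c(y, rep(y[length(y)], nOut - length(y)))
    list(signal = y, sampleRate = target)
  })
  initialize(rec, channels = channels)
}

#' Harmonize hypnogram labels to AASM stage codes
#'
#' Step 8: translates the raw source tokens (held in
#' \code{meta$sourceLabels}) into stage codes 0-4, with movement/unknown
#' tokens mapping to the -1 sentinel. A token outside the declared
#' vocabulary is an error naming the token and the record.
#'
#' @param rec a \linkS4class{PSGRecord}.
#' @param lmap a \linkS4class{LabelMap}.
#' @export
mapLabels <- function(rec, lmap) {
  stopifnot(is(rec, "PSGRecord"), is(lmap, "LabelMap"))
  tokens <- rec@meta$sourceLabels
  if (is.null(tokens))
    stop("record carries no source labels in meta$sourceLabels")
  idx <- match(tokens, names(lmap@entries))
  if (anyNA(idx)) {
    bad <- unique(tokens[is.na(idx)])
    stop(sprintf("token(s) outside vocabulary '%s' in record %s/%s: %s",
                 lmap@vocabularyId, rec@subjectId, rec@sessionId,
                 paste(bad, collapse = ", ")))
  }
  initialize(rec, hypnogram = unname(lmap@entries[idx]))
}

## ---- the template method ------------------------------------------------

#' Port a cohort into the common data store
#'
#' The template method of the standardization half: runs the fixed recipe
#' (list, read, map channels, band-pass filter, scale, clip, resample, map
#' labels) on every record of a cohort and persists each result into the
#' store. Per-record failures are collected into the report, never fatal to
#' the whole run; re-running overwrites per-session groups idempotently.
#'
#' @param adapter a \linkS4class{CohortAdapter} for the cohort.
#' @param root cohort root directory.
#' @param cfg a \linkS4class{PreprocessConfig}.
#' @param store store directory (one HDF5 file per dataset is kept inside).
#' @param stepHook optional \code{function(step, rec)} invoked as each recipe
#'   step completes — used for instrumentation and progress reporting.
#' @return a \linkS4class{PortReport}.
#' @export
portDataset <- function(adapter, root, cfg = PreprocessConfig(),
                        store, stepHook = NULL) {
  stopifnot(is(adapter, "CohortAdapter"), is(cfg, "PreprocessConfig"))
  hook <- function(step, rec) if (!is.null(stepHook)) stepHook(step, rec)
  warningsSeen <- character(0)
  collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warningsSeen <<- c(warningsSeen, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  refs <- collect(listRecords(adapter, root))
  hook("listRecords", NULL)
  rows <- list()
  ported <- 0L
  for (ref in refs) {
    status <- tryCatch({
      collect({
        rec <- readPsg(adapter, ref);            hook("readPsg", rec)
        rec <- mapChannels(rec, adapter@channelMap)
        if (length(cfg@includeChannels)) {
          keep <- intersect(names(rec@channels), cfg@includeChannels)
          if (!length(keep))
            stop("no configured channel present in record")
          rec@channels <- rec@channels[keep]
        }
        hook("mapChannels", rec)
        rec <- filterChannels(rec, cfg);         hook("filterChannels", rec)
        rec <- scaleChannels(rec, cfg);          hook("scaleChannels", rec)
        rec <- clipChannels(rec, cfg);           hook("clipChannels", rec)
        rec <- resampleChannels(rec, cfg);       hook("resampleChannels", rec)
        rec <- mapLabels(rec, adapter@labelMap); hook("mapLabels", rec)
        persistRecord(store, rec);               hook("persistRecord", rec)
      })
      ported <- ported + 1L
      c("ported", "")
    }, error = function(e) c("skipped", conditionMessage(e)))
    rows[[length(rows) + 1L]] <- data.frame(
      subject = ref@subjectId, session = ref@sessionId,
      status = status[1], message = status[2])
  }
  records <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject = character(0), session = character(0),
               status = character(0), message = character(0))
  new("PortReport", datasetId = adapter@datasetId,
      listed = length(refs), ported = ported,
      skipped = length(refs) - ported, records = records,
      warnings = warningsSeen)
}
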