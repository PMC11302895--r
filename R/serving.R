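## Data serving: subject-level splits, random and deterministic window
## samplers over the store manifest, and batch collation.

## Evaluate expr under a temporary RNG seed, restoring the caller's RNG.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Split subjects into train/validation/test partitions
#'
#' Assignment is at subject granularity — all sessions of a subject land in
#' one partition, preventing within-subject leakage. Within every
#' non-holdout dataset, \code{round(n * fraction)} subjects go to validation
#' and test (closest counts to the requested fractions); the rest train.
#' Holdout datasets are assigned wholly to the \code{holdout} partition.
#' Deterministic given \code{seed}.
#'
#' @param manifest a \linkS4class{StoreManifest}.
#' @param holdoutDatasets dataset ids kept apart for testing only.
#' @param fractions \code{c(valFraction, testFraction)}, each in [0, 1) and
#'   summing below 1; default 15\% each.
#' @param seed integer seed.
#' @return a \linkS4class{SplitSpec}.
#' @export
splitRecords <- function(manifest, holdoutDatasets = character(0),
                         fractions = c(0.15, 0.15), seed = 1L) {
  stopifnot(is(manifest, "StoreManifest"), length(fractions) == 2L,
            all(fractions >= 0), sum(fractions) < 1)
  subjects <- unique(manifest@sessions[c("dataset", "subject")])
  subjects <- subjects[order(subjects$dataset, subjects$subject), ]
  out <- list()
  .withSeed(as.integer(seed), {
    for (ds in sort(unique(subjects$dataset))) {
      subs <- subjects$subject[subjects$dataset == ds]
      if (ds %in% holdoutDatasets) {
        part <- rep("holdout", length(subs))
      } else {
        n <- length(subs)
        if (all(fractions > 0) && n < 3L)
          stop(sprintf(
            "dataset %s has %d subject(s); cannot form 3 partitions", ds, n))
        nVal <- round(n * fractions[1])
        nTest <- round(n * fractions[2])
        perm <- sample.int(n)
        part <- rep("train", n)
        part[perm[seq_len(nVal)]] <- "val"
        if (nTest > 0) part[perm[nVal + seq_len(nTest)]] <- "test"
      }
      out[[ds]] <- data.frame(dataset = ds, subject = subs,
                              partition = part)
    }
  })
  assignment <- if (length(out)) do.call(rbind, out) else
    data.frame(dataset = character(0), subject = character(0),
               partition = character(0))
  rownames(assignment) <- NULL
  new("SplitSpec", assignment = assignment, valFraction = fractions[1],
      testFraction = fractions[2], seed = as.integer(seed))
}

## Sessions of the manifest belonging to a partition (or all, split = NULL).
.partitionSessions <- function(manifest, split, partition) {
  s <- manifest@sessions
  if (is.null(split)) return(s)
  a <- split@assignment
  keep <- a$partition == partition
  merge(s, a[keep, c("dataset", "subject")],
        by = c("dataset", "subject"), sort = TRUE)
}

## Cache of per-session eligible window starts. A start is eligible when the
## window [start, start+W) contains at least one scored (non-sentinel)
## epoch; windows consisting purely of -1 labels carry no supervision.
.eligCache <- new.env(parent = emptyenv())

.eligibleStarts <- function(store, ds, sub, ses, epochs, windowEpochs) {
  key <- paste(store, ds, sub, ses, windowEpochs, sep = "\r")
  hit <- .eligCache[[key]]
  if (!is.null(hit)) return(hit)
  if (epochs < windowEpochs) {
    .eligCache[[key]] <- integer(0)
    return(integer(0))
  }
  h <- .readHypnogram(store, ds, sub, ses)
  scored <- cumsum(c(0L, h != STAGE_SENTINEL))
  starts <- 0:(epochs - windowEpochs)
  ok <- (scored[starts + windowEpochs + 1L] - scored[starts + 1L]) > 0L
  res <- starts[ok]
  .eligCache[[key]] <- res
  res
}

#' Draw random sample windows
#'
#' The random sampler used for training: a two-stage uniform draw — first a
#' dataset (uniform over datasets, regardless of their size), then a session
#' uniform within that dataset, then a start epoch uniform over the
#' session's eligible starts. Windows whose labels would be all -1 sentinel
#' are never drawn. Vectorized over \code{n}; reproducible given
#' \code{seed}.
#'
#' @param manifest a \linkS4class{StoreManifest}.
#' @param split optional \linkS4class{SplitSpec}; with \code{partition},
#'   restricts the draw.
#' @param partition partition name when \code{split} is given.
#' @param windowEpochs window length in 30 s epochs (default 35).
#' @param n number of windows to draw.
#' @param seed optional integer seed (otherwise the current RNG stream is
#'   used).
#' @return data.frame with columns dataset, subject, session, startEpoch,
#'   numEpochs — one row per draw, in draw order.
#' @export
randomWindows <- function(manifest, split = NULL, partition = "train",
                          windowEpochs = 35L, n = 1L, seed = NULL) {
  sessions <- .partitionSessions(manifest, split, partition)
  if (!nrow(sessions)) stop("no sessions in partition '", partition, "'")
  store <- manifest@store
  elig <- lapply(seq_len(nrow(sessions)), function(i)
    .eligibleStarts(store, sessions$dataset[i], sessions$subject[i],
                    sessions$session[i], sessions$epochs[i],
                    as.integer(windowEpochs)))
  sessions <- sessions[lengths(elig) > 0L, , drop = FALSE]
  elig <- elig[lengths(elig) > 0L]
  if (!nrow(sessions))
    stop("no session long enough for a ", windowEpochs, "-epoch window")

  datasets <- sort(unique(sessions$dataset))
  .withSeed(seed, {
    dsPick <- sample.int(length(datasets), n, replace = TRUE)
    sesPick <- integer(n)
    for (d in seq_along(datasets)) {
      rows <- which(dsPick == d)
      if (!length(rows)) next
      inDs <- which(sessions$dataset == datasets[d])
      sesPick[rows] <- inDs[sample.int(length(inDs), length(rows),
                                       replace = TRUE)]
    }
    start <- integer(n)
    for (s in unique(sesPick)) {
      rows <- which(sesPick == s)
      pool <- elig[[s]]
      start[rows] <- pool[sample.int(length(pool), length(rows),
                                     replace = TRUE)]
    }
    data.frame(dataset = sessions$dataset[sesPick],
               subject = sessions$subject[sesPick],
               session = sessions$session[sesPick],
               startEpoch = start,
               numEpochs = as.integer(windowEpochs))
  })
}

#' @rdname randomWindows
#' @return \code{randomSample} returns a single \linkS4class{SampleWindow}.
#' @export
randomSample <- function(manifest, split = NULL, partition = "train",
                         windowEpochs = 35L, seed = NULL) {
  w <- randomWindows(manifest, split, partition, windowEpochs, n = 1L,
                     seed = seed)
  SampleWindow(w$dataset, w$subject, w$session, w$startEpoch, w$numEpochs)
}

#' Deterministically tile sessions into windows
#'
#' The deterministic sampler used for validation and testing: consecutive,
#' non-overlapping windows per session in manifest order. Each epoch is
#' covered at most once; a tail shorter than a window is dropped, so
#' coverage is exact when the session length is a multiple of
#' \code{windowEpochs}.
#'
#' @inheritParams randomWindows
#' @return data.frame of windows (dataset, subject, session, startEpoch,
#'   numEpochs).
#' @export
deterministicWindows <- function(manifest, split = NULL,
                                 partition = "val", windowEpochs = 35L) {
  sessions <- .partitionSessions(manifest, split, partition)
  windowEpochs <- as.integer(windowEpochs)
  out <- list()
  for (i in seq_len(nrow(sessions))) {
    k <- sessions$epochs[i] %/% windowEpochs
    if (k < 1L) next
    out[[length(out) + 1L]] <- data.frame(
      dataset = sessions$dataset[i], subject = sessions$subject[i],
      session = sessions$session[i],
      startEpoch = (seq_len(k) - 1L) * windowEpochs,
      numEpochs = windowEpochs)
  }
  if (!length(out))
    return(data.frame(dataset = character(0), subject = character(0),
                      session = character(0), startEpoch = integer(0),
                      numEpochs = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Collate windows into a batch
#'
#' Reads each window lazily from the store and stacks signals into a
#' (window x channel x sample) array and labels into a (window x epoch)
#' matrix. All windows must have one length and all sessions one sample
#' rate.
#'
#' @param store store directory.
#' @param windows data.frame from \code{\link{randomWindows}} /
#'   \code{\link{deterministicWindows}}, or a list of
#'   \linkS4class{SampleWindow}.
#' @param channels canonical channel names to serve.
#' @return a \linkS4class{Batch}.
#' @export
readBatch <- function(store, windows, channels) {
  if (is.list(windows) && !is.data.frame(windows))
    windows <- do.call(rbind, lapply(windows, function(w) data.frame(
      dataset = w@datasetId, subject = w@subjectId, session = w@sessionId,
      startEpoch = w@startEpoch, numEpochs = w@numEpochs)))
  nw <- nrow(windows)
  if (!nw) stop("no windows to read")
  if (length(unique(windows$numEpochs)) != 1L)
    stop("all windows in a batch must have the same epoch count")
  nep <- windows$numEpochs[1]
  first <- readWindow(store, SampleWindow(
    windows$dataset[1], windows$subject[1], windows$session[1],
    windows$startEpoch[1], nep), channels)
  nsamp <- ncol(first$signals)
  signals <- array(NA_real_, c(nw, length(channels), nsamp))
  labels <- matrix(NA_integer_, nw, nep)
  signals[1, , ] <- first$signals
  labels[1, ] <- first$labels
  for (i in seq_len(nw)[-1]) {
    wi <- readWindow(store, SampleWindow(
      windows$dataset[i], windows$subject[i], windows$session[i],
      windows$startEpoch[i], nep), channels)
    if (ncol(wi$signals) != nsamp)
      stop("windows mix sample rates; cannot collate")
    signals[i, , ] <- wi$signals
    labels[i, ] <- wi$labels
  }
  rate <- nsamp / (nep * EPOCH_SECONDS)
  new("Batch", signals = signals, labels = labels,
      provenance = as.data.frame(windows), sampleRate = rate)
}

#' Iterate batches from the store
#'
#' A thin adapter exposing sampler + pipes as an iterable stream, the shape
#' a deep-learning loader consumes. Returns a closure; each call yields the
#' next \linkS4class{Batch} (after applying \code{pipes}), or NULL when a
#' deterministic stream is exhausted (random streams never end).
#'
#' @inheritParams randomWindows
#' @param store store directory; \code{channels} the channels to serve.
#' @param channels canonical channel names.
#' @param batchSize windows per batch.
#' @param pipes optional list of \linkS4class{Pipe} stages.
#' @param mode \code{"random"} or \code{"deterministic"}.
#' @export
batchIterator <- function(store, manifest, split = NULL,
                          partition = "train", channels,
                          windowEpochs = 35L, batchSize = 4L,
                          pipes = list(), mode = c("random", "deterministic"),
                          seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "deterministic") {
    queue <- deterministicWindows(manifest, split, partition, windowEpochs)
    pos <- 0L
  }
  if (!is.null(seed)) set.seed(seed)
  function() {
    w <- if (mode == "random") {
      randomWindows(manifest, split, partition, windowEpochs, n = batchSize)
    } else {
      if (pos >= nrow(queue)) return(NULL)
      take <- seq.int(pos + 1L, min(pos + batchSize, nrow(queue)))
      pos <<- pos + length(take)
      queue[take, , drop = FALSE]
    }
    applyPipes(readBatch(store, w, channels), pipes)
  }
}
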