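## File-format benchmark harness: serializes one record to HDF5, Parquet and
## whole-object RDS, then measures single-channel extraction time and peak
## R-heap allocation per trial. Reports raw numbers only — absolute values
## are machine-specific, and no cross-format winner is declared.

.gcMb <- function(g, col) sum(g[, col])

## Run fn once, returning elapsed ms and the peak R-heap delta (MB) relative
## to the heap state at entry. gc(reset = TRUE) re-bases the "max used"
## water mark so the delta isolates this call's allocations.
.measure <- function(fn) {
  g0 <- gc(reset = TRUE)
  base <- .gcMb(g0, "(Mb)")
  tm <- system.time(x <- fn())["elapsed"]
  g1 <- gc()
  peak <- .gcMb(g1, 6) - base     # column 6 = Mb at the max-used water mark
  rm(x)
  c(ms = unname(tm) * 1000, peakMB = max(peak, 0))
}

#' Benchmark storage formats on one record
#'
#' Serializes the same standardized record to each requested format and
#' measures extraction of a single channel: wall time and peak R-heap
#' allocation per trial. \code{"hdf5"} reads only the channel's dataset
#' (chunked partial read); \code{"parquet"} reads one column;
#' \code{"rds"} — the whole-object serialization baseline — must
#' deserialize the entire file before the channel can be extracted.
#'
#' @param rec a standardized \linkS4class{PSGRecord} (one sample rate,
#'   equal channel lengths).
#' @param formats subset of \code{c("hdf5", "parquet", "rds")}.
#' @param trials repetitions per format (>= 1).
#' @param channel channel to extract; default the first.
#' @param dir scratch directory for the serialized files.
#' @return a \linkS4class{BenchmarkReport}.
#' @export
benchmarkFormats <- function(rec, formats = c("hdf5", "parquet", "rds"),
                             trials = 5L, channel = NULL,
                             dir = tempfile("bench")) {
  stopifnot(is(rec, "PSGRecord"), trials >= 1L)
  unknown <- setdiff(formats, c("hdf5", "parquet", "rds"))
  if (length(unknown))
    stop("unknown format token(s): ", paste(unknown, collapse = ", "))
  if (is.null(channel)) channel <- channelNames(rec)[1]
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  paths <- list()
  loaders <- list()
  if ("hdf5" %in% formats) {
    store <- file.path(dir, "h5store")
    persistRecord(store, rec)
    paths$hdf5 <- .datasetFile(store, rec@datasetId)
    loaders$hdf5 <- local({
      f <- paths$hdf5
      ds <- paste0(.sessionPath(rec@subjectId, rec@sessionId), "/psg/",
                   channel)
      function() {
        x <- rhdf5::h5read(f, ds)
        rhdf5::h5closeAll()
        x
      }
    })
  }
  if ("parquet" %in% formats) {
    df <- as.data.frame(lapply(rec@channels, function(c1) c1$signal))
    names(df) <- channelNames(rec)
    paths$parquet <- file.path(dir, "record.parquet")
    arrow::write_parquet(df, paths$parquet)
    rm(df)
    loaders$parquet <- local({
      f <- paths$parquet
      pcol <- channel
      # a plain character col_select trips a tidyselect deprecation note
      function() suppressWarnings(arrow::read_parquet(f, col_select = pcol))
    })
  }
  if ("rds" %in% formats) {
    obj <- list(channels = lapply(rec@channels, function(c1) c1$signal),
                hypnogram = rec@hypnogram)
    paths$rds <- file.path(dir, "record.rds")
    saveRDS(obj, paths$rds, compress = FALSE)
    rm(obj)
    loaders$rds <- local({
      f <- paths$rds
      ch <- channel
      function() readRDS(f)$channels[[ch]]
    })
  }

  rows <- list()
  timesMs <- list()
  for (fmt in formats) {
    m <- vapply(seq_len(trials), function(i) .measure(loaders[[fmt]]),
                numeric(2))
    timesMs[[fmt]] <- m["ms", ]
    rows[[fmt]] <- data.frame(
      format = fmt,
      fileSizeMB = file.size(paths[[fmt]]) / 2^20,
      meanLoadMs = mean(m["ms", ]),
      sdLoadMs = stats::sd(m["ms", ]),
      meanPeakMemMB = mean(m["peakMB", ]))
  }
  new("BenchmarkReport", results = do.call(rbind, rows),
      timesMs = timesMs, trials = as.integer(trials),
      machine = paste(R.version.string, Sys.info()[["sysname"]],
                      Sys.info()[["machine"]]))
}

## A large-ish standardized in-memory record for benchmarking: nChannels
## channels of unit-IQR noise at the target rate.
.benchmarkRecord <- function(nChannels = 16L, epochs = 100L, rate = 128,
                             seed = 7L) {
  .withSeed(seed, {
    n <- as.integer(epochs * EPOCH_SECONDS * rate)
    sites <- c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "O1",
               "O2", "F7", "F8", "T7", "T8", "Cz", "Pz", "Fz", "Oz")
    chn <- paste0(sites[seq_len(nChannels)], "-A1")
    channels <- lapply(stats::setNames(chn, chn), function(nm) {
      x <- stats::rnorm(n)
      list(signal = (x - mean(x)) / channelIQR(x), sampleRate = rate)
    })
    PSGRecord("bench", "s01", "n1", channels,
              hypnogram = rep(0L, epochs))
  })
}
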