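## Minimal EDF (European Data Format) reader/writer.
##
## EDF stores a 256-byte ASCII header, 256 ASCII bytes per signal, then data
## records of little-endian int16 samples, one block per signal per record.
## Physical values are recovered by linear mapping between the digital and
## physical min/max declared in the header. This implementation covers
## continuous multi-rate recordings with 1 s data records, which is all the
## pipeline's adapters require; EDF+ annotation tracks are not parsed (the
## bundled adapters use sidecar hypnograms).

.edfPad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

.edfNum <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7)
  if (nchar(s) > width) s <- substr(s, 1, width)
  .edfPad(s, width)
}

#' Write channels to an EDF file
#'
#' @param path output file path.
#' @param channels named list; each element \code{list(signal, sampleRate)}
#'   with an integer sample rate. All channels must span the same whole
#'   number of seconds.
#' @param patientId,recordingId free-text header fields (80 bytes each).
#' @param startdate,starttime header date/time as \code{"dd.mm.yy"} /
#'   \code{"hh.mm.ss"}.
#' @return \code{path}, invisibly.
#' @export
writeEDF <- function(path, channels, patientId = "X", recordingId = "X",
                     startdate = "01.01.00", starttime = "00.00.00") {
  if (!length(channels)) stop("cannot write an EDF file with zero channels")
  rates <- vapply(channels, function(c1) c1$sampleRate, numeric(1))
  if (any(rates != round(rates)))
    stop("EDF writer requires integer sample rates")
  durs <- vapply(channels, function(c1) length(c1$signal) / c1$sampleRate,
                 numeric(1))
  if (any(abs(durs - round(durs[1])) > 1e-9))
    stop("all channels must span the same whole number of seconds")
  nRec <- as.integer(round(durs[1]))
  ns <- length(channels)
  spr <- as.integer(rates)          # samples per 1 s record

  digMax <- 32767L
  physMax <- vapply(channels, function(c1)
    max(max(abs(c1$signal)), 1e-6), numeric(1))

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edfPad("0", 8), .edfPad(patientId, 80), .edfPad(recordingId, 80),
    .edfPad(startdate, 8), .edfPad(starttime, 8),
    .edfPad(256L * (1L + ns), 8), .edfPad("", 44),
    .edfPad(nRec, 8), .edfPad(1L, 8), .edfPad(ns, 4))
  sig <- paste0(
    paste(vapply(names(channels), .edfPad, "", width = 16), collapse = ""),
    paste(rep(.edfPad("", 80), ns), collapse = ""),
    paste(rep(.edfPad("uV", 8), ns), collapse = ""),
    paste(vapply(-physMax, .edfNum, "", width = 8), collapse = ""),
    paste(vapply(physMax, .edfNum, "", width = 8), collapse = ""),
    paste(rep(.edfPad(-digMax, 8), ns), collapse = ""),
    paste(rep(.edfPad(digMax, 8), ns), collapse = ""),
    paste(rep(.edfPad("", 80), ns), collapse = ""),
    paste(vapply(spr, .edfPad, "", width = 8), collapse = ""),
    paste(rep(.edfPad("", 32), ns), collapse = ""))
  writeChar(paste0(hdr, sig), con, eos = NULL, useBytes = TRUE)

  ## header physical bounds are re-parsed so quantization uses exactly what
  ## a reader will see
  physHdr <- vapply(physMax, function(p)
    as.numeric(.edfNum(p, 8)), numeric(1))
  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- channels[[i]]$signal
    d <- as.integer(round(x / physHdr[i] * digMax))
    dig[[i]] <- matrix(pmax(pmin(d, digMax), -digMax), nrow = spr[i])
  }
  out <- matrix(0L, nrow = sum(spr), ncol = nRec)
  off <- 0L
  for (i in seq_len(ns)) {
    out[off + seq_len(spr[i]), ] <- dig[[i]]
    off <- off + spr[i]
  }
  writeBin(as.integer(out), con, size = 2, endian = "little")
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file.
#' @return list with \code{channels} (named list of \code{list(signal,
#'   sampleRate)} in physical units), \code{nRecords},
#'   \code{recordDuration} (s), \code{patientId}, \code{recordingId}.
#' @export
readEDF <- function(path) {
  if (!file.exists(path)) stop("no such EDF file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  version <- rd(8)
  patientId <- trimws(rd(80))
  recordingId <- trimws(rd(80))
  rd(8); rd(8)                       # startdate, starttime
  headerBytes <- suppressWarnings(as.integer(rd(8)))
  rd(44)
  nRec <- suppressWarnings(as.integer(rd(8)))
  recDur <- suppressWarnings(as.numeric(rd(8)))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (is.na(ns) || is.na(nRec) || is.na(recDur) || ns < 1L || nRec < 0L)
    stop("corrupt or non-EDF header in ", path)
  if (!is.na(headerBytes) && headerBytes != 256L * (1L + ns))
    stop("EDF header length field inconsistent in ", path)

  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  rd(80 * ns)                        # transducer
  rd(8 * ns)                         # physical dimension
  num <- function(w) suppressWarnings(
    vapply(seq_len(ns), function(i) as.numeric(rd(w)), numeric(1)))
  physMin <- num(8); physMax <- num(8)
  digMin <- num(8); digMax <- num(8)
  rd(80 * ns)                        # prefiltering
  spr <- suppressWarnings(
    vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1)))
  rd(32 * ns)
  if (anyNA(c(physMin, physMax, digMin, digMax, spr)) || any(spr < 1L))
    stop("corrupt EDF signal headers in ", path)

  total <- sum(spr)
  raw <- readBin(con, "integer", n = total * nRec, size = 2,
                 signed = TRUE, endian = "little")
  if (length(raw) < total * nRec)
    stop("EDF data section truncated in ", path)
  m <- matrix(raw, nrow = total, ncol = nRec)
  channels <- vector("list", ns)
  off <- 0L
  for (i in seq_len(ns)) {
    dig <- as.numeric(m[off + seq_len(spr[i]), , drop = FALSE])
    gain <- (physMax[i] - physMin[i]) / (digMax[i] - digMin[i])
    channels[[i]] <- list(signal = physMin[i] + (dig - digMin[i]) * gain,
                          sampleRate = spr[i] / recDur)
    off <- off + spr[i]
  }
  names(channels) <- labels
  list(channels = channels, nRecords = nRec, recordDuration = recDur,
       patientId = patientId, recordingId = recordingId,
       version = trimws(version))
}
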