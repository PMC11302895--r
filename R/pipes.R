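## Composable batch pipes and the stock augmenters / spectrogram stage.

#' Pipe: a composable batch transformation
#'
#' Virtual base class. Concrete pipes implement \code{\link{pipeApply}};
#' \code{\link{applyPipes}} composes them left to right and validates each
#' stage's output, naming the offending stage on failure.
#'
#' @slot name stage name used in error messages.
#' @export
setClass("Pipe", representation("VIRTUAL", name = "character"))

#' @rdname Pipe-class
#' @slot fn a \code{function(batch) -> batch}.
#' @export
setClass("FunctionPipe", contains = "Pipe", representation(fn = "function"))

#' @rdname Pipe-class
#' @slot spec an \linkS4class{AugmenterSpec}; \code{seed} optional.
#' @export
setClass("AugmentPipe", contains = "Pipe",
         representation(spec = "AugmenterSpec", seed = "integer"))

#' @rdname Pipe-class
#' @slot cfg a \linkS4class{SpectrogramConfig}.
#' @export
setClass("SpectrogramPipe", contains = "Pipe",
         representation(cfg = "SpectrogramConfig"))

#' @rdname Pipe-class
#' @param fn,name function and stage name for a \code{FunctionPipe}.
#' @export
FunctionPipe <- function(fn, name = "function")
  new("FunctionPipe", fn = fn, name = name)

#' @rdname Pipe-class
#' @param spec,seed augmenter spec and optional seed for an
#'   \code{AugmentPipe}.
#' @export
AugmentPipe <- function(spec, seed = NA_integer_)
  new("AugmentPipe", spec = spec, seed = as.integer(seed),
      name = paste0("augment:", spec@kind, "/", spec@transform))

#' @rdname Pipe-class
#' @param cfg a \linkS4class{SpectrogramConfig} for a
#'   \code{SpectrogramPipe}.
#' @export
SpectrogramPipe <- function(cfg = SpectrogramConfig())
  new("SpectrogramPipe", cfg = cfg, name = "spectrogram")

#' @rdname pipeApply
setMethod("pipeApply", "FunctionPipe", function(pipe, batch)
  pipe@fn(batch))

#' @rdname pipeApply
setMethod("pipeApply", "AugmentPipe", function(pipe, batch)
  augmentBatch(batch, pipe@spec,
               seed = if (is.na(pipe@seed)) NULL else pipe@seed))

#' @rdname pipeApply
setMethod("pipeApply", "SpectrogramPipe", function(pipe, batch)
  toSpectrogram(batch, pipe@cfg))

#' Compose pipes over a batch
#'
#' Applies each pipe stage left to right. The empty pipeline is the
#' identity. After every stage the output is validated; an invalid output is
#' an error naming the stage.
#'
#' @param batch a \linkS4class{Batch}.
#' @param pipes list of \linkS4class{Pipe} objects (possibly empty).
#' @return the transformed batch (a \linkS4class{Batch} or
#'   \linkS4class{SpectrogramBatch}).
#' @export
applyPipes <- function(batch, pipes = list()) {
  for (p in pipes) {
    out <- pipeApply(p, batch)
    err <- NULL
    if (is(out, "Batch") || is(out, "SpectrogramBatch")) {
      err <- tryCatch({ validObject(out); NULL },
                      error = function(e) conditionMessage(e))
    } else {
      err <- paste("output is not a Batch or SpectrogramBatch but",
                   class(out)[1])
    }
    if (!is.null(err))
      stop(sprintf("pipe stage '%s' produced an invalid batch: %s",
                   p@name, err))
    batch <- out
  }
  batch
}

#' Augment a batch
#'
#' Applies the configured augmenter to each window independently with the
#' configured probability. Global transforms act on the whole window:
#' \code{"noise"} adds Gaussian noise of sd \code{magnitude};
#' \code{"scale"} multiplies the window by a factor drawn uniformly from
#' \code{[1 - magnitude, 1 + magnitude]}. The regional transform
#' \code{"mask"} zeroes one contiguous random sub-segment whose fraction of
#' the window is drawn from \code{fractionRange} (the masked length is
#' \code{floor(fraction * samples)}), identically across channels. Labels,
#' axis sizes and unselected windows are never modified.
#'
#' @param batch a \linkS4class{Batch}.
#' @param spec an \linkS4class{AugmenterSpec}.
#' @param seed optional seed for reproducible augmentation.
#' @return the augmented \linkS4class{Batch}.
#' @export
augmentBatch <- function(batch, spec, seed = NULL) {
  stopifnot(is(batch, "Batch"), is(spec, "AugmenterSpec"))
  validObject(spec)
  d <- dim(batch@signals)
  if (spec@probability == 0) return(batch)
  .withSeed(seed, {
    sel <- stats::runif(d[1]) < spec@probability
    if (!any(sel)) return(batch)
    signals <- batch@signals
    for (w in which(sel)) {
      if (spec@kind == "global") {
        if (spec@transform == "noise") {
          signals[w, , ] <- signals[w, , ] +
            stats::rnorm(d[2] * d[3], sd = spec@magnitude)
        } else if (spec@transform == "scale") {
          f <- stats::runif(1, 1 - spec@magnitude, 1 + spec@magnitude)
          signals[w, , ] <- signals[w, , ] * f
        } else stop("unknown global transform: ", spec@transform)
      } else {
        if (spec@transform != "mask")
          stop("unknown regional transform: ", spec@transform)
        frac <- stats::runif(1, spec@fractionRange[1], spec@fractionRange[2])
        len <- floor(frac * d[3])
        if (len >= 1) {
          start <- sample.int(d[3] - len + 1L, 1L)
          signals[w, , seq.int(start, length.out = len)] <- 0
        }
      }
    }
    initialize(batch, signals = signals)
  })
}

## Symmetric cosine tapers.
.taper <- function(name, n) {
  k <- seq_len(n) - 1L
  switch(name,
         hann = 0.5 - 0.5 * cos(2 * pi * k / (n - 1)),
         hamming = 0.54 - 0.46 * cos(2 * pi * k / (n - 1)),
         stop("unknown taper: ", name))
}

#' Convert a batch to log-magnitude spectrograms
#'
#' For spectrogram-input sequence models: each window is resampled to the
#' intermediate rate (100 Hz by default), then every 30 s epoch is
#' short-time Fourier transformed with a \code{windowSec} taper and
#' \code{hopSec} hop; the taper is zero-padded to the next power-of-two FFT
#' length and \code{log(|X| + logOffset)} is taken. Under the defaults each
#' epoch yields 29 frames x 129 frequency bins; frames of consecutive epochs
#' are concatenated along the frame axis.
#'
#' @param batch a \linkS4class{Batch}.
#' @param cfg a \linkS4class{SpectrogramConfig}.
#' @return a \linkS4class{SpectrogramBatch} with values
#'   (window x channel x frame x bin).
#' @export
toSpectrogram <- function(batch, cfg = SpectrogramConfig()) {
  stopifnot(is(batch, "Batch"), is(cfg, "SpectrogramConfig"))
  validObject(cfg)
  d <- dim(batch@signals)
  ir <- cfg@intermediateRate
  epochSamples <- as.integer(EPOCH_SECONDS * ir)
  nEpochs <- ncol(batch@labels)
  winLen <- as.integer(cfg@windowSec * ir)
  hop <- as.integer(cfg@hopSec * ir)
  if (epochSamples < winLen)
    stop("epoch shorter than the spectrogram taper")
  nfft <- 2^ceiling(log2(winLen))
  nBins <- nfft / 2 + 1
  framesPerEpoch <- (epochSamples - winLen) %/% hop + 1L
  taper <- .taper(cfg@taper, winLen)
  freqs <- (0:(nfft / 2)) * ir / nfft

  pq <- .rationalRatio(ir, batch@sampleRate)
  nIr <- as.integer(nEpochs * epochSamples)
  frameStarts <- (seq_len(framesPerEpoch) - 1L) * hop
  values <- array(NA_real_,
                  c(d[1], d[2], nEpochs * framesPerEpoch, nBins))
  for (w in seq_len(d[1])) for (ch in seq_len(d[2])) {
    x <- batch@signals[w, ch, ]
    if (batch@sampleRate != ir) {
      x <- signal::resample(x, pq["p"], pq["q"])
      x <- if (length(x) >= nIr) x[seq_len(nIr)] else
        c(x, rep(x[length(x)], nIr - length(x)))
    }
    for (ep in seq_len(nEpochs)) {
      seg <- x[(ep - 1L) * epochSamples + seq_len(epochSamples)]
      fr <- vapply(frameStarts, function(s) {
        buf <- numeric(nfft)
        buf[seq_len(winLen)] <- seg[s + seq_len(winLen)] * taper
        Mod(stats::fft(buf))[seq_len(nBins)]
      }, numeric(nBins))
      values[w, ch, (ep - 1L) * framesPerEpoch + seq_len(framesPerEpoch), ] <-
        t(log(fr + cfg@logOffset))
    }
  }
  new("SpectrogramBatch", values = values, labels = batch@labels,
      provenance = batch@provenance, frequencies = freqs,
      frameHop = cfg@hopSec)
}
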