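# Independent oracles, deliberately written from first principles rather
# than via the code paths they check.

# Quartile by sorting + linear interpolation between order statistics
# (position h = (n-1)p + 1).
bruteQuartile <- function(x, p) {
  xs <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

bruteIQR <- function(x) bruteQuartile(x, 0.75) - bruteQuartile(x, 0.25)

# Cohen's kappa by direct pair counting over label vectors.
bruteKappa <- function(ref, pred) {
  keep <- ref != -1L & pred != -1L
  ref <- ref[keep]; pred <- pred[keep]
  po <- mean(ref == pred)
  pe <- 0
  for (k in unique(c(ref, pred)))
    pe <- pe + mean(ref == k) * mean(pred == k)
  (po - pe) / (1 - pe)
}

# Macro F1 by per-class counting over label vectors.
bruteMacroF1 <- function(ref, pred, classes = 0:4) {
  keep <- ref != -1L & pred != -1L
  ref <- ref[keep]; pred <- pred[keep]
  f1 <- c()
  for (k in classes) {
    tp <- sum(ref == k & pred == k)
    fp <- sum(ref != k & pred == k)
    fn <- sum(ref == k & pred != k)
    if (tp + fp + fn == 0) next
    f1 <- c(f1, 2 * tp / (2 * tp + fp + fn))
  }
  mean(f1)
}

# One-sided periodogram; returns freq (Hz) and power.
periodogram <- function(x, fs) {
  n <- length(x)
  X <- stats::fft(x - mean(x))
  half <- seq_len(n %/% 2 + 1)
  data.frame(freq = (half - 1) * fs / n,
             power = Mod(X[half])^2 / n)
}

dominantFreq <- function(x, fs) {
  p <- periodogram(x, fs)
  p$freq[which.max(p$power)]
}
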