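## Agreement metrics between reference and predicted hypnograms.

.STAGE_NAMES <- c("W", "N1", "N2", "N3", "REM")

#' Stage confusion matrix
#'
#' Counts epoch-wise agreement between a reference and a predicted
#' hypnogram over the 5 AASM stages. Epoch pairs where either side carries
#' the -1 sentinel (unscored/movement) are dropped before counting.
#'
#' @param reference,predicted integer stage-code vectors of equal length,
#'   codes in \{-1, 0, ..., 4\}.
#' @return a \linkS4class{StageConfusion}; rows are the reference.
#' @export
stageConfusion <- function(reference, predicted) {
  if (length(reference) != length(predicted))
    stop(sprintf("length mismatch: reference %d vs predicted %d",
                 length(reference), length(predicted)))
  ok <- reference != STAGE_SENTINEL & predicted != STAGE_SENTINEL
  r <- factor(reference[ok], levels = 0:4)
  p <- factor(predicted[ok], levels = 0:4)
  counts <- unclass(table(r, p))
  dimnames(counts) <- list(reference = .STAGE_NAMES,
                           predicted = .STAGE_NAMES)
  new("StageConfusion", counts = counts)
}

## Core kappa on a plain counts matrix (any K); shared by the S4 front-end.
.kappa <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix: no scored epoch pairs")
  po <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (abs(1 - pe) < .Machine$double.eps * 4)
    stop("Cohen's kappa undefined: expected agreement equals 1 ",
         "(both raters constant)")
  (po - pe) / (1 - pe)
}

#' Cohen's kappa
#'
#' Chance-corrected epoch-wise agreement,
#' \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with observed agreement
#' \eqn{p_o} (diagonal mass) and expected agreement \eqn{p_e} (product of
#' the marginals). Undefined when \eqn{p_e = 1} (both scorers constant and
#' identical); this is signalled as an error.
#'
#' @param cm a \linkS4class{StageConfusion} or a square counts matrix.
#' @return kappa in [-1, 1].
#' @export
cohenKappa <- function(cm) {
  if (is(cm, "StageConfusion")) cm <- cm@counts
  .kappa(cm)
}

## Per-class F1 = 2TP / (2TP + FP + FN); NaN for classes absent on both
## sides.
.perClassF1 <- function(cm) {
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  denom <- 2 * tp + fp + fn
  f1 <- ifelse(denom == 0, NaN, 2 * tp / denom)
  names(f1) <- rownames(cm)
  f1
}

#' Macro (or support-weighted) F1
#'
#' Unweighted mean over classes of per-class F1; classes with no reference
#' and no predicted instances are excluded from the mean. With
#' \code{weighted = TRUE} the mean is weighted by reference support
#' instead.
#'
#' @param cm a \linkS4class{StageConfusion} or a square counts matrix.
#' @param weighted weight classes by reference support.
#' @export
macroF1 <- function(cm, weighted = FALSE) {
  if (is(cm, "StageConfusion")) cm <- cm@counts
  if (sum(cm) == 0) stop("empty confusion matrix: no scored epoch pairs")
  f1 <- .perClassF1(cm)
  present <- !is.nan(f1)
  if (!any(present)) stop("no class present on either side")
  if (weighted) {
    wts <- rowSums(cm)[present]
    sum(f1[present] * wts) / sum(wts)
  } else {
    mean(f1[present])
  }
}

#' Export per-record metrics as CSV
#'
#' Computes kappa, per-class F1 and macro F1 for each (reference,
#' prediction) pair and writes one CSV row per record — the shape of a
#' per-record supplementary metrics table.
#'
#' @param records named list; each element
#'   \code{list(reference = codes, predicted = codes)}. Names are record
#'   ids.
#' @param path output CSV path.
#' @return the metrics data.frame, invisibly (also written to \code{path}).
#' @export
exportMetrics <- function(records, path) {
  rows <- lapply(names(records), function(id) {
    cm <- stageConfusion(records[[id]]$reference, records[[id]]$predicted)
    f1 <- .perClassF1(cm@counts)
    kappa <- tryCatch(cohenKappa(cm), error = function(e) NA_real_)
    df <- data.frame(record = id, kappa = kappa,
                     macroF1 = macroF1(cm))
    for (s in .STAGE_NAMES) df[[paste0("f1_", s)]] <- f1[[s]]
    df
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
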