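#' Image-level anomaly score
#'
#' The maximum of the per-region anomaly scores: a scan is as anomalous as
#' its most anomalous local region, so even small lesions drive the
#' image-level decision.
#'
#' @param sg a [ScoreGrid-class] (or plain numeric matrix/vector).
#' @return a non-negative scalar.
#' @export
imageScore <- function(sg) {
  s <- if (is(sg, "ScoreGrid")) sg@scores else sg
  if (length(s) == 0L) stopInput("empty score grid")
  max(s)
}

#' Render a pixel-resolution anomaly heat map
#'
#' Bilinear upsampling of the region score grid to `outSize`, followed by
#' Gaussian smoothing with standard deviation `sigma` pixels. Smoothing is
#' for rendering only — image-level scores are always taken from the raw
#' grid.
#'
#' @param sg a [ScoreGrid-class].
#' @param outSize output side length (at least the grid size).
#' @param sigma smoothing std in pixels; 0 disables smoothing. Default 4.
#' @return an [AnomalyMap-class].
#' @export
anomalyHeatmap <- function(sg, outSize, sigma = 4) {
  s <- sg@scores
  if (outSize < max(dim(s))) stopInput("outSize must be >= the grid size")
  m <- if (all(dim(s) == c(outSize, outSize))) s
       else EBImage::imageData(EBImage::resize(EBImage::Image(s),
                                               w = outSize, h = outSize,
                                               filter = "bilinear"))
  if (sigma > 0)
    m <- EBImage::imageData(EBImage::gblur(EBImage::Image(m), sigma = sigma))
  new("AnomalyMap", pixels = m, sourceId = sg@sourceId,
      smoothingSigma = sigma)
}

#' ROC area under the curve
#'
#' The Mann-Whitney statistic: the probability that a random anomalous
#' score exceeds a random normal score, ties counted one half. Computed
#' from ranks, so it is invariant under any strictly increasing transform
#' of the scores.
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector (1 = anomalous).
#' @return AUC in \[0, 1\].
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stopInput("both classes must be present to compute ROC-AUC")
  r <- rank(scores)                      # average ranks handle ties as 1/2
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold maximizing F1 on the anomalous class
#'
#' Scans the minimum score and all midpoints between consecutive sorted
#' unique scores (every achievable prediction pattern under the closed
#' `>=` decision rule) and returns the threshold with the highest F1;
#' ties go to the lowest threshold.
#'
#' @inheritParams rocAuc
#' @return a scalar threshold.
#' @export
selectThresholdMaxF1 <- function(scores, labels) {
  labels <- as.integer(labels)
  if (!any(labels == 1L) || !any(labels == 0L))
    stopInput("both classes must be present to select a threshold")
  u <- sort(unique(scores))
  cand <- c(u[1], if (length(u) > 1) (u[-length(u)] + u[-1]) / 2)
  f1s <- vapply(cand, function(th) {
    pred <- scores >= th
    tp <- sum(pred & labels == 1L)
    fp <- sum(pred & labels == 0L)
    fn <- sum(!pred & labels == 1L)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  cand[which.max(f1s)]                   # which.max takes the first maximum
}

#' Confusion-matrix metrics at a threshold
#'
#' Predict anomalous iff `score >= threshold` (closed on the anomalous
#' side). Sensitivity is anomalous recall, specificity normal recall.
#'
#' @inheritParams rocAuc
#' @param threshold decision threshold.
#' @return named list: `rocAuc`, `f1`, `accuracy`, `sensitivity`,
#'   `specificity`, `threshold`, `nNormal`, `nAnomalous`.
#' @export
classificationMetrics <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  stopifnot(is.finite(threshold))
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1L); fp <- sum(pred & labels == 0L)
  fn <- sum(!pred & labels == 1L); tn <- sum(!pred & labels == 0L)
  list(
    rocAuc = if (tp + fn > 0 && fp + tn > 0) rocAuc(scores, labels) else NA_real_,
    f1 = if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn),
    accuracy = (tp + tn) / length(labels),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    threshold = threshold,
    nNormal = fp + tn, nAnomalous = tp + fn)
}
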