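#' @include enet.R
NULL

#' Mean squared error of classification (Brier score)
#'
#' Mean over samples of `(probability - label)^2`.  With `hard = TRUE`
#' the probability is first thresholded at `cutoff`, giving the
#' misclassification rate instead.
#'
#' @param probs predicted probabilities.
#' @param labels binary labels (0/1), same length.
#' @param hard threshold probabilities before squaring (default FALSE).
#' @param cutoff threshold used when `hard = TRUE`.
#' @return scalar mean squared error.
#' @export
mseClassification <- function(probs, labels, hard = FALSE, cutoff = 0.5) {
  if (length(probs) != length(labels))
    stop("probs and labels must have equal length")
  p <- if (hard) as.numeric(probs >= cutoff) else as.numeric(probs)
  mean((p - as.numeric(labels))^2)
}

#' Area under the precision-recall curve
#'
#' Step-wise (non-linear) interpolation: thresholds sweep the distinct
#' predicted probabilities in decreasing order, tied probabilities are
#' grouped, and the area is the sum of `(recall_k - recall_{k-1}) *
#' precision_k` rectangles.  Preferred over ROC-AUC when the classes are
#' imbalanced.
#'
#' @param probs predicted probabilities.
#' @param labels binary labels; both classes must be present.
#' @return scalar in \[0, 1\].
#' @export
aucPrecisionRecall <- function(probs, labels) {
  if (length(probs) != length(labels))
    stop("probs and labels must have equal length")
  labels <- as.numeric(labels)
  npos <- sum(labels == 1)
  if (npos == 0 || npos == length(labels))
    stop("both classes must be present")
  ord <- order(probs, decreasing = TRUE)
  p <- probs[ord]
  y <- labels[ord]
  # group ties: cumulative counts at each distinct threshold
  last <- cumsum(rle(p)$lengths)
  tp <- cumsum(y)[last]
  fp <- cumsum(1 - y)[last]
  recall <- tp / npos
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Misclassification count at a probability cutoff
#'
#' Counts samples whose thresholded prediction (`prob >= cutoff` means
#' positive) disagrees with the label.
#'
#' @param probs predicted probabilities.
#' @param labels binary labels.
#' @param cutoff classification cutoff in (0, 1), default 0.5.
#' @return integer count.
#' @export
misclassificationCount <- function(probs, labels, cutoff = 0.5) {
  if (length(probs) != length(labels))
    stop("probs and labels must have equal length")
  stopifnot(cutoff > 0, cutoff < 1)
  sum(as.numeric(probs >= cutoff) != as.numeric(labels))
}
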