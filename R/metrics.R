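#' Classification metrics
#'
#' `auroc()` is the area under the ROC curve (rank / Mann-Whitney form,
#' computed through pROC); `average_precision()` is the area under the
#' precision-recall curve in its step form (precision averaged at every
#' positive, the `average_precision_score` convention).
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1) of the same length.
#' @return A scalar in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels > 0)
  if (all(labels == 1) || all(labels == 0)) {
    stop("AUROC undefined: labels contain a single class")
  }
  as.numeric(pROC::auc(
    response = labels, predictor = as.numeric(scores),
    direction = "<", quiet = TRUE
  ))
}

#' @rdname auroc
#' @export
average_precision <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels > 0)
  n_pos <- sum(labels)
  if (n_pos == 0L) stop("average precision undefined: no positives")
  ord <- order(-scores, labels) # ties: count negatives first (conservative)
  y <- labels[ord]
  tp <- cumsum(y)
  precision <- tp / seq_along(y)
  sum(precision[y == 1]) / n_pos
}
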