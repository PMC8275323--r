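#' Ranking and threshold metrics for binary binding scores
#'
#' ROC-AUC is computed as the normalized Wilcoxon rank-sum statistic
#' (midranks, i.e. tied scores count one half), which equals the
#' probability that a random positive outranks a random negative.
#' Balanced accuracy is the mean of sensitivity and specificity at the
#' fixed decision threshold.
#'
#' @param scores Numeric scores (higher = more likely binding).
#' @param labels Binary labels, same length.
#' @param threshold Decision threshold for the balanced accuracy
#'   (default 0.5).
#' @return A list with `roc_auc`, `balanced_accuracy`, `n_pos`, `n_neg`.
#' @examples
#' evaluate(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))$roc_auc  # 0.75
#' @export
evaluate <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  if (anyNA(scores) || anyNA(labels)) stop("scores and labels must not contain NA")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC-AUC is undefined without both a positive and a negative label")
  r <- rank(scores)  # midranks handle ties
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  sens <- mean(scores[labels == 1] > threshold)
  spec <- mean(scores[labels == 0] <= threshold)
  list(roc_auc = auc, balanced_accuracy = (sens + spec) / 2,
       n_pos = n_pos, n_neg = n_neg)
}
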