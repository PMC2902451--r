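# ROC evaluation of a distance measure against a reference clustering.
#
# A pair of structures is predicted "same cluster" when its distance is at
# or below a threshold; sweeping the threshold over all midpoints between
# consecutive distinct distances traces the exact empirical ROC curve.

#' ROC curve of pairwise distances against cluster labels
#'
#' For every threshold, pairs with distance <= threshold are predicted to
#' belong to the same cluster; true positives are correctly predicted
#' same-cluster pairs.  Sensitivity = TP / (TP + FN) is plotted against
#' 1 - Specificity = FP / (FP + TN), and the area under the curve is
#' computed by the trapezoid rule.  Thresholds are all midpoints between
#' consecutive sorted unique distances, plus sentinels below the minimum
#' and above the maximum, so the curve is the exact empirical ROC.
#'
#' @param distances A `dist` object, a symmetric matrix of pairwise
#'   distances, or a numeric vector of pair distances (in which case
#'   `labels` must be a logical vector marking same-cluster pairs).
#' @param labels Cluster assignment of the items (length = number of
#'   items), or, for vector `distances`, a logical per-pair indicator.
#' @return An object of class `gauss_roc`: list with `points` (data frame
#'   of threshold, sensitivity, specificity, fpr), `auc`, `n_pairs`,
#'   `n_same`, `n_diff`.
#' @export
#' @examples
#' d <- dist(c(0, 0.1, 0.2, 5, 5.1, 5.2))
#' roc_curve(d, labels = c(1, 1, 1, 2, 2, 2))$auc
roc_curve <- function(distances, labels) {
  if (inherits(distances, "dist") || is.matrix(distances)) {
    m <- as.matrix(distances)
    n <- nrow(m)
    if (length(labels) != n)
      stop("`labels` must have one element per item")
    if (length(unique(labels)) < 2L)
      stop("degenerate labels: need at least two clusters")
    pairs <- which(upper.tri(m), arr.ind = TRUE)
    d <- m[pairs]
    same <- labels[pairs[, 1L]] == labels[pairs[, 2L]]
  } else {
    d <- as.numeric(distances)
    same <- as.logical(labels)
    if (length(d) != length(same))
      stop("pair distances and pair labels differ in length")
  }
  n_same <- sum(same)
  n_diff <- sum(!same)
  if (n_same == 0L || n_diff == 0L)
    stop("degenerate labels: need both same- and different-cluster pairs")

  u <- sort(unique(d))
  thresholds <- c(u[1L] - 1, (u[-1L] + u[-length(u)]) / 2, u[length(u)] + 1)
  sens <- fpr <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    pred <- d <= thresholds[i]
    sens[i] <- sum(pred & same) / n_same
    fpr[i] <- sum(pred & !same) / n_diff
  }
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1L] + sens[ord][-length(sens)]) / 2)
  structure(list(points = data.frame(threshold = thresholds,
                                     sensitivity = sens,
                                     specificity = 1 - fpr,
                                     fpr = fpr),
                 auc = auc, n_pairs = length(d),
                 n_same = n_same, n_diff = n_diff),
            class = "gauss_roc")
}

#' @export
print.gauss_roc <- function(x, ...) {
  cat(sprintf("ROC over %d pairs (%d same-cluster, %d different): AUC = %.4f\n",
              x$n_pairs, x$n_same, x$n_diff, x$auc))
  invisible(x)
}

#' @export
#' @importFrom graphics abline lines
plot.gauss_roc <- function(x, ...) {
  plot(x$points$fpr, x$points$sensitivity, type = "s",
       xlab = "1 - Specificity", ylab = "Sensitivity",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  abline(0, 1, lty = 3)
  invisible(x)
}
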