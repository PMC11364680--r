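# ROC construction, AUC (trapezoid = Mann-Whitney with ties counted half),
# percentile-bootstrap AUC confidence interval, and Youden-index threshold
# selection. Test-positivity convention throughout: score >= threshold.

#' Build a ROC curve over AI scores
#'
#' Candidate thresholds are the distinct observed scores in ascending order
#' plus one sentinel above the maximum (so the curve reaches
#' sensitivity 0 / specificity 1); at the minimum score every visit is
#' test-positive (sensitivity 1). A visit is test-positive when its score is
#' greater than or equal to the threshold.
#'
#' @param scores Numeric vector of AI scores.
#' @param labels Logical vector, `TRUE` = cancer (histology-proven).
#' @return An object of class `roc_curve`: tibble with columns `threshold`,
#'   `sensitivity`, `specificity`, plus attributes `n_pos`, `n_neg` and the
#'   original data (used by [roc_auc()] and [auc_bootstrap_ci()]).
#' @export
#' @examples
#' build_roc(c(10, 20, 90), c(FALSE, FALSE, TRUE))
build_roc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) {
    stop_validation("scores and labels must have equal length")
  }
  if (anyNA(scores) || anyNA(labels)) {
    stop_validation("scores and labels must not contain missing values")
  }
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop_degenerate("ROC requires both classes present")
  }
  o <- order(scores)
  s <- scores[o]
  l <- labels[o]
  first_idx <- which(!duplicated(s))          # start of each distinct value
  thr <- c(s[first_idx], s[length(s)] + 1)    # sentinel above the maximum
  cum_pos <- c(0, cumsum(l))
  # counts strictly below each threshold
  pos_below <- c(cum_pos[first_idx], n_pos)
  below <- c(first_idx - 1L, length(s))
  neg_below <- below - pos_below
  curve <- tibble::tibble(
    threshold = thr,
    sensitivity = (n_pos - pos_below) / n_pos,
    specificity = neg_below / n_neg
  )
  structure(curve, class = c("roc_curve", class(curve)),
            n_pos = n_pos, n_neg = n_neg, scores = scores, labels = labels)
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the curve built by [build_roc()]. With thresholds
#' at the distinct observed scores this equals the Mann-Whitney concordance
#' probability with ties counted half.
#'
#' @param curve A `roc_curve`.
#' @return AUC as a proportion in \[0, 1\].
#' @export
roc_auc <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  fpr <- 1 - curve$specificity   # descending along increasing threshold
  tpr <- curve$sensitivity
  sum(-diff(fpr) * (tpr[-length(tpr)] + tpr[-1]) / 2)
}

#' Percentile-bootstrap confidence interval for the AUC
#'
#' Resamples visits with replacement, recomputes the AUC per replicate, and
#' returns the percentile interval. A replicate that draws only one class is
#' redrawn (the count of redraws is reported via a message and an
#' attribute).
#'
#' @param scores,labels As in [build_roc()].
#' @param n_boot Number of bootstrap replicates (at least 100; default
#'   2000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector `c(lower, upper)` with attributes `point`
#'   (observed AUC), `n_boot` and `n_redrawn`.
#' @export
auc_bootstrap_ci <- function(scores, labels, n_boot = 2000, level = 0.95,
                             seed = NULL) {
  if (n_boot < 100) stop_config("n_boot must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  labels <- as.logical(labels)
  n <- length(scores)
  point <- roc_auc(build_roc(scores, labels))
  aucs <- numeric(n_boot)
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (any(labels[idx]) && any(!labels[idx])) break
      n_redrawn <- n_redrawn + 1L
    }
    aucs[b] <- roc_auc(build_roc(scores[idx], labels[idx]))
  }
  if (n_redrawn > 0) {
    message(sprintf("auc_bootstrap_ci: %d single-class replicate(s) redrawn",
                    n_redrawn))
  }
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(aucs, c(alpha, 1 - alpha)))
  structure(ci, point = point, n_boot = n_boot, n_redrawn = n_redrawn)
}

#' Youden-index threshold selection
#'
#' Returns the threshold maximizing Youden's J = sensitivity +
#' specificity - 1 over the curve's candidate thresholds. Ties (within
#' 1e-12) are broken toward the lowest qualifying threshold, favouring
#' sensitivity as appropriate in a screening context; the rule and the
#' number of tied candidates are surfaced in the result.
#'
#' @param curve A `roc_curve`.
#' @return An object of class `threshold_result`: list with `threshold`,
#'   `youden_j`, `sensitivity`, `specificity`, `tie_break` and `n_tied`.
#' @export
#' @examples
#' youden_threshold(build_roc(c(10, 20, 90), c(FALSE, FALSE, TRUE)))
youden_threshold <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  j <- curve$sensitivity + curve$specificity - 1
  jmax <- max(j)
  tied <- which(j >= jmax - 1e-12)
  best <- tied[1L]   # thresholds ascend, so the first tied index is lowest
  structure(list(
    threshold = curve$threshold[best],
    youden_j = j[best],
    sensitivity = curve$sensitivity[best],
    specificity = curve$specificity[best],
    tie_break = "lowest threshold",
    n_tied = length(tied)
  ), class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "Youden operating point: threshold %.4f (J = %.4f; sensitivity %.2f%%, specificity %.2f%%)\n",
    x$threshold, x$youden_j, 100 * x$sensitivity, 100 * x$specificity))
  if (x$n_tied > 1) {
    cat(sprintf("  (%d tied thresholds; tie broken toward the %s)\n",
                x$n_tied, x$tie_break))
  }
  invisible(x)
}
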