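# Confusion-based metrics, PR/ROC curves, and imbalance arithmetic.
#
# Evaluation is always on hard labels; soft labels (in (0, 0.5]) are
# thresholded back to their hard class with a warning. A pair is predicted
# positive iff its score >= threshold (ties predict positive).

hard_labels <- function(labels) {
  if (any(labels < 0 | labels > 1))
    stop("labels must lie in [0, 1]", call. = FALSE)
  soft <- !(labels %in% c(0, 1))
  if (any(soft)) {
    warning(sprintf("%d soft label(s) thresholded at 0.5 for evaluation",
                    sum(soft)))
    labels <- as.numeric(labels > 0.5)
  }
  labels
}

#' Confusion counts at a score threshold
#'
#' @param scores numeric scores in [0, 1].
#' @param labels labels in [0, 1]; soft labels are hardened at 0.5 with a
#'   warning.
#' @param threshold predict positive iff `score >= threshold`.
#' @return list of class `confusion_counts` with integer `TP`, `FP`, `TN`,
#'   `FN`.
#' @export
confusion <- function(scores, labels, threshold) {
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]",
                                         call. = FALSE)
  y <- hard_labels(labels)
  pred <- scores >= threshold
  structure(list(TP = sum(pred & y == 1), FP = sum(pred & y == 0),
                 TN = sum(!pred & y == 0), FN = sum(!pred & y == 1)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion: TP=%d FP=%d TN=%d FN=%d\n", x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Recall, precision and F1 from confusion counts
#'
#' `recall = TP / (TP + FN)`, `precision = TP / (TP + FP)`, F1 their
#' harmonic mean. A zero denominator yields `NA_real_` (an undefined-metric
#' flag), never an error.
#'
#' @param c a `confusion_counts` object.
#' @return single numeric value, or `NA` when undefined.
#' @export
recall_score <- function(c) {
  d <- c$TP + c$FN
  if (d == 0) NA_real_ else c$TP / d
}

#' @rdname recall_score
#' @export
precision_score <- function(c) {
  d <- c$TP + c$FP
  if (d == 0) NA_real_ else c$TP / d
}

#' @rdname recall_score
#' @export
f1_score <- function(c) {
  p <- precision_score(c)
  r <- recall_score(c)
  if (is.na(p) || is.na(r)) return(NA_real_)
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

#' Precision implied by class rates under a 1:k ratio
#'
#' Closed form linking per-class rates to precision on a dataset with `k`
#' negatives per positive: with `P` positives, predicted positives are
#' `tpr * P + fpr * k * P`, so
#' `precision = tpr / (tpr + k * fpr)`.
#' This is why a scorer's true/false positive rates are ratio-invariant
#' while its precision collapses as `k` grows.
#'
#' @param tpr true positive rate (recall) in [0, 1].
#' @param fpr false positive rate in [0, 1].
#' @param k negatives per positive, > 0.
#' @return precision in [0, 1]; 1 when `fpr == 0` and `tpr > 0`; `NA` when
#'   `tpr == fpr == 0`.
#' @examples
#' precision_from_rates(0.1425, 0.0195, 1) # ~0.8796
#' @export
precision_from_rates <- function(tpr, fpr, k) {
  stopifnot(tpr >= 0, tpr <= 1, fpr >= 0, fpr <= 1, k > 0)
  if (tpr == 0 && fpr == 0) return(NA_real_)
  tpr / (tpr + k * fpr)
}

# Shared sweep over distinct-score thresholds (descending); ties grouped.
threshold_sweep <- function(scores, labels) {
  y <- hard_labels(labels)
  P <- sum(y == 1)
  N <- sum(y == 0)
  if (P == 0 || N == 0)
    stop("curve needs at least one positive and one negative", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- y[ord]
  cum_tp <- cumsum(y == 1)
  cum_fp <- cumsum(y == 0)
  last <- c(diff(s) != 0, TRUE)        # last index within each tie group
  list(threshold = s[last], tp = cum_tp[last], fp = cum_fp[last],
       P = P, N = N)
}

#' Precision-recall curve and non-interpolated average precision
#'
#' The curve has one point per distinct score (ties grouped at a single
#' threshold). The area is the non-interpolated average precision
#' `AP = sum_i (R_i - R_{i-1}) * P_i` over thresholds in decreasing score
#' order — the standard estimator for imbalanced evaluation, stable under
#' ties.
#'
#' @inheritParams confusion
#' @return data.frame (`threshold`, `recall`, `precision`) of class
#'   `pr_curve` with attribute `area`.
#' @export
pr_curve <- function(scores, labels) {
  sw <- threshold_sweep(scores, labels)
  rec <- sw$tp / sw$P
  prec <- sw$tp / (sw$tp + sw$fp)
  ap <- sum(diff(c(0, rec)) * prec)
  structure(data.frame(threshold = sw$threshold, recall = rec,
                       precision = prec),
            area = ap, class = c("pr_curve", "data.frame"))
}

#' ROC curve and trapezoidal area
#'
#' @inheritParams confusion
#' @return data.frame (`threshold`, `fpr`, `tpr`) of class `roc_curve` with
#'   attribute `area` (trapezoid rule, including the (0,0) and (1,1)
#'   endpoints).
#' @export
roc_curve <- function(scores, labels) {
  sw <- threshold_sweep(scores, labels)
  tpr <- c(0, sw$tp / sw$P)
  fpr <- c(0, sw$fp / sw$N)
  if (tpr[length(tpr)] != 1 || fpr[length(fpr)] != 1) {
    tpr <- c(tpr, 1)
    fpr <- c(fpr, 1)
  }
  area <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(data.frame(threshold = c(Inf, sw$threshold,
                                     rep(-Inf, length(tpr) - length(sw$threshold) - 1L)),
                       fpr = fpr, tpr = tpr),
            area = area, class = c("roc_curve", "data.frame"))
}

#' Area under a PR or ROC curve
#'
#' `auprc(scores, labels)` and `auroc(scores, labels)` also accept a
#' previously computed curve.
#'
#' @param x a `pr_curve`/`roc_curve`, or a numeric score vector.
#' @param labels labels, when `x` is a score vector.
#' @return area in [0, 1].
#' @export
auprc <- function(x, labels = NULL) {
  if (inherits(x, "pr_curve")) return(attr(x, "area"))
  attr(pr_curve(x, labels), "area")
}

#' @rdname auprc
#' @export
auroc <- function(x, labels = NULL) {
  if (inherits(x, "roc_curve")) return(attr(x, "area"))
  attr(roc_curve(x, labels), "area")
}

#' Score-threshold policy
#'
#' Two operating points are reported by default: a permissive "normal"
#' cutoff at 0.1 and a conservative "strict" cutoff at 0.5.
#'
#' @param normal,strict thresholds with `0 < normal < strict < 1`.
#' @return list of class `threshold_policy`.
#' @export
threshold_policy <- function(normal = 0.1, strict = 0.5) {
  if (!(0 < normal && normal < strict && strict < 1))
    stop("need 0 < normal < strict < 1", call. = FALSE)
  structure(list(normal = normal, strict = strict),
            class = "threshold_policy")
}

#' Precision/recall/F1 at the policy thresholds plus a dense grid
#'
#' @inheritParams confusion
#' @param policy a [threshold_policy()].
#' @param grid additional thresholds for plotting (default 0..1 by 0.01).
#' @return data.frame (`threshold`, `level`, `precision`, `recall`, `f1`)
#'   where `level` is `"normal"`, `"strict"` or `"grid"`.
#' @export
threshold_report <- function(scores, labels, policy = threshold_policy(),
                             grid = seq(0, 1, by = 0.01)) {
  ths <- c(policy$normal, policy$strict, grid)
  lvl <- c("normal", "strict", rep("grid", length(grid)))
  y <- suppressWarnings(hard_labels(labels))
  rows <- lapply(seq_along(ths), function(i) {
    cc <- confusion(scores, y, ths[i])
    data.frame(threshold = ths[i], level = lvl[i],
               precision = precision_score(cc), recall = recall_score(cc),
               f1 = f1_score(cc), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Evaluate a score vector on a labeled dataset
#'
#' Bundles confusion counts at the policy thresholds, both curves and their
#' areas into one report.
#'
#' @inheritParams threshold_report
#' @return list of class `eval_report`: `auprc`, `auroc`, `pr`, `roc`,
#'   `thresholds` (the policy rows of [threshold_report()]), `n_pos`,
#'   `n_neg`.
#' @export
evaluate_scores <- function(scores, labels, policy = threshold_policy()) {
  y <- suppressWarnings(hard_labels(labels))
  pr <- pr_curve(scores, y)
  roc <- roc_curve(scores, y)
  rep <- threshold_report(scores, y, policy, grid = numeric(0))
  structure(list(auprc = attr(pr, "area"), auroc = attr(roc, "area"),
                 pr = pr, roc = roc, thresholds = rep,
                 n_pos = sum(y == 1), n_neg = sum(y == 0)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("evaluation on %d positives / %d negatives (1:%.1f)\n",
              x$n_pos, x$n_neg, x$n_neg / x$n_pos))
  cat(sprintf("  auPRC = %.4f   auROC = %.4f\n", x$auprc, x$auroc))
  for (i in seq_len(nrow(x$thresholds))) {
    r <- x$thresholds[i, ]
    cat(sprintf("  %-6s (>= %.2f): precision %.4f  recall %.4f  F1 %.4f\n",
                r$level, r$threshold, r$precision, r$recall, r$f1))
  }
  invisible(x)
}

#' @exportS3Method graphics::plot
plot.pr_curve <- function(x, ...) {
  graphics::plot(x$recall, x$precision, type = "s", xlim = c(0, 1),
                 ylim = c(0, 1), xlab = "Recall", ylab = "Precision",
                 main = sprintf("PR curve (AP = %.3f)", attr(x, "area")), ...)
}

#' @exportS3Method graphics::plot
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC curve (AUC = %.3f)", attr(x, "area")), ...)
  graphics::abline(0, 1, lty = 3)
}
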