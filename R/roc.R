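#' Tie-corrected AUROC by pair counting
#'
#' The probability that a random class-1 score exceeds a random class-0
#' score, counting ties as 1/2 — computed through mid-ranks, which is
#' algebraically identical to enumerating all between-class pairs.
#'
#' @param scores numeric vector.
#' @param labels binary vector (both classes present).
#' @return AUROC in `[0, 1]`.
#' @export
auroc_value <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("auroc error: single-class labels")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve and AUROC
#'
#' Builds the full ROC curve over all distinct score thresholds (decision
#' rule: positive when score >= threshold) and integrates it by the
#' trapezoid rule; with ties counted as 1/2 this equals the pair-counting
#' AUROC of [auroc_value()] to machine precision. Also reports the maximum
#' Youden index over the curve.
#'
#' @param scores numeric vector.
#' @param labels binary vector (both classes present).
#' @return An `roc_result`: `thresholds` (decreasing), `sensitivity`,
#'   `specificity`, `auroc` (trapezoid), `auroc_paircount`, `youden_max`.
#' @export
compute_auroc <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("auroc error: single-class labels")
  thr <- sort(unique(scores), decreasing = TRUE)
  # cumulative counts above each threshold, vectorized over distinct values
  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]
  y_sorted <- labels[ord]
  last_of_value <- cumsum(table(factor(s_sorted, levels = thr)))
  tp <- cumsum(y_sorted == 1)[last_of_value]
  fp <- cumsum(y_sorted == 0)[last_of_value]
  sens <- c(0, tp / n1)          # leading point: threshold above all scores
  fpr <- c(0, fp / n0)
  auc_trap <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  spec <- 1 - fpr
  structure(list(thresholds = c(Inf, thr),
                 sensitivity = as.numeric(sens),
                 specificity = as.numeric(spec),
                 auroc = auc_trap,
                 auroc_paircount = auroc_value(scores, labels),
                 youden_max = max(sens + spec - 1)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC over %d thresholds: AUROC = %.4f, max Youden J = %.4f\n",
              length(x$thresholds), x$auroc, x$youden_max))
  invisible(x)
}

# mid-rank placement values: V10[i] = P(score_i > Y) + 0.5 P(= Y) over the
# class-0 scores, and symmetrically V01 over class-1 scores
delong_placements <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  m <- length(x)
  n <- length(y)
  v10 <- vapply(x, function(xi) (sum(xi > y) + 0.5 * sum(xi == y)) / n,
                numeric(1))
  v01 <- vapply(y, function(yj) (sum(x > yj) + 0.5 * sum(x == yj)) / m,
                numeric(1))
  list(v10 = v10, v01 = v01, auroc = mean(v10))
}

#' DeLong comparison of two correlated AUROCs
#'
#' Paired DeLong test for two score vectors measured on the same patients:
#' the covariance of the AUROC estimates is formed from the empirical
#' placement values and the difference is referred to a standard normal.
#' Also exposes the one-sample DeLong standard errors for CI construction.
#'
#' @param scores_a,scores_b score vectors over the same patients.
#' @param labels binary vector.
#' @return A `delong_result`: `auroc_a`, `auroc_b`, `se_a`, `se_b`,
#'   `var_diff`, `z`, `p` (two-sided), `degenerate` flag (TRUE when the
#'   difference has zero variance, in which case `p = 1`).
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop("delong error: length mismatch")
  }
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  m <- length(pa$v10)
  n <- length(pa$v01)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  se_a <- sqrt(s10[1, 1] / m + s01[1, 1] / n)
  se_b <- sqrt(s10[2, 2] / m + s01[2, 2] / n)
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  degenerate <- !is.finite(var_diff) || var_diff < 1e-12
  z <- if (degenerate) 0 else (pa$auroc - pb$auroc) / sqrt(var_diff)
  p <- if (degenerate) 1 else 2 * stats::pnorm(-abs(z))
  structure(list(auroc_a = pa$auroc, auroc_b = pb$auroc,
                 se_a = se_a, se_b = se_b, var_diff = var_diff,
                 z = z, p = p, degenerate = degenerate),
            class = "delong_result")
}

#' Confusion-matrix metrics with a Pearson chi-square test
#'
#' Builds the 2x2 table of predicted versus true class and reports counts,
#' sensitivity, specificity, PPV and NPV, plus the uncorrected Pearson
#' chi-square statistic (df = 1) and its two-sided p value. A metric whose
#' margin is empty is reported as `NA` (undefined), never as 0; the
#' chi-square is `NA` when any table margin is zero.
#'
#' @param predicted binary vector of predicted classes.
#' @param truth binary vector of true classes (both classes present).
#' @return A `confusion_report` list.
#' @export
confusion_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("confusion error: length mismatch")
  }
  if (length(unique(truth)) < 2) {
    stop("confusion error: truth has a single class")
  }
  tp <- sum(predicted == 1 & truth == 1)
  fn <- sum(predicted == 0 & truth == 1)
  fp <- sum(predicted == 1 & truth == 0)
  tn <- sum(predicted == 0 & truth == 0)
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  n <- tp + fn + fp + tn
  margins <- c(tp + fn, fp + tn, tp + fp, fn + tn)
  if (any(margins == 0)) {
    chi2 <- NA_real_
    p <- NA_real_
  } else {
    chi2 <- n * (tp * tn - fp * fn)^2 / prod(margins)
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 sensitivity = safe_div(tp, tp + fn),
                 specificity = safe_div(tn, tn + fp),
                 ppv = safe_div(tp, tp + fp),
                 npv = safe_div(tn, tn + fn),
                 chi2 = chi2, p = p),
            class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("sens %.3f  spec %.3f  PPV %.3f  NPV %.3f  chi2 %.3f  p %.4g\n",
              x$sensitivity, x$specificity, x$ppv, x$npv, x$chi2, x$p))
  invisible(x)
}
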