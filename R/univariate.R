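#' Per-marker univariate comparison panel
#'
#' For every marker, compares the observed values between classes with the
#' statistics used for right-skewed clinical biomarkers: class medians and
#' their iCCA/HCC fold-change, Welch's t test (robust to unequal variances,
#' Satterthwaite df), a Mann-Whitney U cross-check (exact when both groups
#' have at most 10 untied observations, otherwise the tie-corrected normal
#' approximation), Cohen's d on the pooled standard deviation, the post-hoc
#' power of the two-sided Welch test at alpha = 0.05 given the observed
#' effect size (descriptive only), and the single-marker AUROC. Markers with
#' a degenerate group (< 2 observed values) are flagged with `NA` rows while
#' the rest of the panel is computed.
#'
#' @param table a `cohort` object (missing entries are ignored per marker).
#' @return A `marker_summary` data frame with one row per marker.
#' @export
univariate_marker_stats <- function(table) {
  specs <- cohort_specs(table)
  m <- marker_matrix(table)
  y <- table$label
  rows <- lapply(specs$name, function(nm) {
    x1 <- m[y == 1, nm]
    x0 <- m[y == 0, nm]
    x1 <- x1[!is.na(x1)]
    x0 <- x0[!is.na(x0)]
    out <- data.frame(marker = nm,
                      n_hcc = length(x0), n_icca = length(x1),
                      median_hcc = NA_real_, median_icca = NA_real_,
                      fold_change = NA_real_, welch_t = NA_real_,
                      welch_df = NA_real_, welch_p = NA_real_,
                      mw_u = NA_real_, mw_p = NA_real_,
                      cohens_d = NA_real_, power = NA_real_,
                      auroc = NA_real_, degenerate = TRUE,
                      stringsAsFactors = FALSE)
    if (length(x0) < 2 || length(x1) < 2) return(out)
    out$degenerate <- FALSE
    out$median_hcc <- stats::median(x0)
    out$median_icca <- stats::median(x1)
    out$fold_change <- out$median_icca / out$median_hcc
    if (stats::sd(x0) == 0 && stats::sd(x1) == 0 &&
        mean(x0) == mean(x1)) {
      # identical constant groups: all statistics are null by definition
      out$welch_t <- 0; out$welch_p <- 1
      out$welch_df <- length(x0) + length(x1) - 2
      out$cohens_d <- 0; out$power <- 0.05
      out$mw_u <- length(x0) * length(x1) / 2; out$mw_p <- 1
      out$auroc <- 0.5
      return(out)
    }
    tt <- stats::t.test(x1, x0, var.equal = FALSE)
    out$welch_t <- unname(tt$statistic)
    out$welch_df <- unname(tt$parameter)
    out$welch_p <- tt$p.value
    exact <- length(x0) <= 10 && length(x1) <= 10 &&
      !any(duplicated(c(x0, x1)))
    mw <- suppressWarnings(
      stats::wilcox.test(x1, x0, exact = exact, correct = FALSE))
    out$mw_u <- unname(mw$statistic)
    out$mw_p <- mw$p.value
    n1 <- length(x1); n0 <- length(x0)
    sp <- sqrt(((n1 - 1) * stats::var(x1) + (n0 - 1) * stats::var(x0)) /
                 (n1 + n0 - 2))
    out$cohens_d <- if (sp > 0) (mean(x1) - mean(x0)) / sp else 0
    out$power <- welch_posthoc_power(out$cohens_d, n1, n0, out$welch_df)
    out$auroc <- auroc_value(c(x1, x0), rep(c(1, 0), c(n1, n0)))
    out
  })
  res <- do.call(rbind, rows)
  class(res) <- c("marker_summary", "data.frame")
  res
}

# two-sided noncentral-t power of the Welch test at the observed effect size
welch_posthoc_power <- function(d, n1, n0, df, alpha = 0.05) {
  ncp <- abs(d) * sqrt(n1 * n0 / (n1 + n0))
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tcrit, df, ncp = ncp)
}
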