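#' Principal-component contribution scores
#'
#' Runs PCA on the column-standardized matrix and scores each marker by the
#' sum of absolute loadings over the first `K` components (components
#' ordered by decreasing explained variance). The score is invariant to the
#' arbitrary sign of each component. Components with (numerically) zero
#' variance are dropped before summing, so a rank-deficient matrix
#' contributes only its informative directions.
#'
#' @param X numeric matrix (patients x markers), complete.
#' @param K number of leading components to sum over (default 4).
#' @return Named numeric vector of non-negative contributions per marker.
#' @export
pca_contribution <- function(X, K = 4) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("pca error: X contains missing values")
  if (K < 1 || K > ncol(X)) {
    stop("pca error: K must lie in 1..", ncol(X))
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  keep <- pc$sdev > max(pc$sdev) * 1e-8
  k_eff <- min(K, sum(keep))
  w <- pc$rotation[, seq_len(k_eff), drop = FALSE]
  stats::setNames(rowSums(abs(w)), colnames(X))
}

#' Merge L1 selection with PCA contributions into a marker ranking
#'
#' The selected set is the union of the L1 support (markers with a non-zero
#' penalized coefficient) and the top-`q` markers by PCA contribution. The
#' rank is lexicographic: markers with non-zero coefficients first, within
#' them by decreasing `|coefficient|`, then by decreasing contribution.
#'
#' @param model an `l1_logistic` fit over the marker panel.
#' @param contributions named contributions from [pca_contribution()] over
#'   the same panel.
#' @param q how many top-contribution markers to union in (default 5).
#' @return A `prioritization_result` data frame: `marker`, `coefficient`,
#'   `contribution`, `selected`, `rank`.
#' @export
merge_rankings <- function(model, contributions, q = 5) {
  beta <- model$coefficients
  panel <- names(beta)
  if (!setequal(panel, names(contributions))) {
    stop("merge error: model and contributions cover different panels")
  }
  if (q < 0 || q > length(panel)) {
    stop("merge error: q must lie in 0..", length(panel))
  }
  contributions <- contributions[panel]
  top_q <- if (q > 0) {
    panel[order(-contributions)][seq_len(q)]
  } else {
    character(0)
  }
  selected <- (beta != 0) | (panel %in% top_q)
  ord <- order(beta == 0, -abs(beta), -contributions)
  res <- data.frame(marker = panel,
                    coefficient = as.numeric(beta),
                    contribution = as.numeric(contributions),
                    selected = selected,
                    rank = match(seq_along(panel), ord),
                    stringsAsFactors = FALSE)
  res <- res[order(res$rank), ]
  rownames(res) <- NULL
  class(res) <- c("prioritization_result", "data.frame")
  res
}

#' Prioritize markers on a training cohort
#'
#' Convenience wrapper running the full prioritization stage: penalty
#' selection by stratified cross-validation, the L1 fit at the selected
#' penalty, PCA contributions over the first `K` components, and the merged
#' ranking.
#'
#' @param ztrain training `cohort` with standardized markers (complete).
#' @param q,K passed to [merge_rankings()] and [pca_contribution()].
#' @param fold_seed seed for the cross-validation folds.
#' @return List: `result` (`prioritization_result`), `model`
#'   (`l1_logistic`), `lambda`, `contributions`, `cv`.
#' @export
prioritize_markers <- function(ztrain, q = 5, K = 4, fold_seed = 1L) {
  X <- marker_matrix(ztrain)
  y <- ztrain$label
  cv <- select_lambda_cv(X, y, fold_seed = fold_seed)
  model <- fit_l1_logistic(X, y, cv$lambda)
  contrib <- pca_contribution(X, K = K)
  list(result = merge_rankings(model, contrib, q = q), model = model,
       lambda = cv$lambda, contributions = contrib, cv = cv)
}
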