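#' Bootstrap AUROC with percentile confidence interval
#'
#' Nonparametric bootstrap of the AUROC: patients are resampled with
#' replacement within each class (stratified, so both classes are always
#' present and the AUROC is defined), the AUROC is recomputed per resample,
#' and the 95% interval is taken from the 2.5/97.5 percentiles of the
#' bootstrap distribution.
#'
#' @param scores numeric score vector.
#' @param labels binary vector (both classes present).
#' @param B number of resamples (default 1000; fewer than 100 warns).
#' @param seed integer seed.
#' @return A `bootstrap_auroc` list: `estimate` (observed AUROC), `B`,
#'   `mean`, `ci` (length-2), `distribution`.
#' @export
bootstrap_auroc <- function(scores, labels, B = 1000L, seed = 42L) {
  if (B < 100) warning("bootstrap with B < 100 iterations is unstable")
  i1 <- which(labels == 1)
  i0 <- which(labels == 0)
  if (!length(i1) || !length(i0)) stop("bootstrap error: single-class labels")
  dist <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- c(i1[sample.int(length(i1), replace = TRUE)],
               i0[sample.int(length(i0), replace = TRUE)])
      auroc_value(scores[idx], labels[idx])
    }, numeric(1))
  })
  structure(list(estimate = auroc_value(scores, labels), B = B,
                 mean = mean(dist),
                 ci = unname(stats::quantile(dist, c(0.025, 0.975))),
                 distribution = dist),
            class = "bootstrap_auroc")
}

#' Monte Carlo measurement-noise perturbation
#'
#' Certifies an additive score model against analytical variability: in each
#' iteration every model-marker value `x` is replaced by `x * (1 + u)` with
#' `u` drawn independently per cell (uniform on `[-eps, +eps]` by default,
#' or a Gaussian with sd `eps/2` truncated at `±eps`), the cohort is
#' re-scored with the cut-offs and total-score threshold frozen, and the
#' AUROC of the perturbed total score against the true labels is recorded.
#' A noise level of 0 reproduces the unperturbed AUROC exactly.
#'
#' @param table a `cohort`, complete for the model markers, native units.
#' @param model a `score_model`.
#' @param noise_levels relative noise half-widths in `[0, 1)`; default
#'   `c(0, 0.05, 0.10, 0.20)` (the 0 row is the deterministic control).
#' @param iters iterations per level (default 500).
#' @param seed integer seed.
#' @param noise `"uniform"` (default) or `"gaussian"`.
#' @param marker_mask optional character vector restricting perturbation to
#'   a subset of the model markers (default: all of them).
#' @return An `mc_perturbation` object with `summary` data frame
#'   (`noise_level`, `iters`, `mean_auroc`, `sd_auroc`, `min_auroc`) and
#'   `baseline_auroc`.
#' @export
mc_perturbation <- function(table, model,
                            noise_levels = c(0, 0.05, 0.10, 0.20),
                            iters = 500L, seed = 42L,
                            noise = c("uniform", "gaussian"),
                            marker_mask = NULL) {
  noise <- match.arg(noise)
  if (any(noise_levels < 0 | noise_levels >= 1)) {
    stop("mc error: noise levels must lie in [0, 1)")
  }
  panel <- model$cutoffs$marker
  perturb <- if (is.null(marker_mask)) panel else intersect(panel, marker_mask)
  m <- marker_matrix(table, panel)
  if (anyNA(m)) stop("mc error: table must be complete for model markers")
  y <- table$label
  baseline <- auroc_value(score_points(model, m), y)
  draw <- function(eps, cells) {
    if (noise == "uniform") {
      stats::runif(cells, -eps, eps)
    } else {
      u <- stats::rnorm(cells, 0, eps / 2)
      pmin(pmax(u, -eps), eps)
    }
  }
  rows <- withr::with_seed(seed, {
    lapply(noise_levels, function(eps) {
      aucs <- vapply(seq_len(iters), function(i) {
        mp <- m
        u <- matrix(draw(eps, nrow(m) * length(perturb)),
                    nrow(m), length(perturb))
        mp[, perturb] <- mp[, perturb] * (1 + u)
        auroc_value(score_points(model, mp), y)
      }, numeric(1))
      data.frame(noise_level = eps, iters = iters,
                 mean_auroc = mean(aucs), sd_auroc = stats::sd(aucs),
                 min_auroc = min(aucs))
    })
  })
  structure(list(summary = do.call(rbind, rows), baseline_auroc = baseline,
                 noise = noise, seed = seed),
            class = "mc_perturbation")
}

#' Repeated random-split stability analysis
#'
#' Re-runs the whole modelling pipeline from scratch on `n_splits`
#' stratified train/test partitions (seed = `base_seed + index`, so any
#' split can be reproduced in isolation): disease-stratified median
#' imputation and z-scoring fitted on the training part only,
#' cross-validated L1 feature selection, a ridge-stabilized logistic refit
#' on the selected markers, and an additive model with per-split Youden
#' cut-offs and total-score threshold. Both models are evaluated by AUROC on
#' the untouched test part, alongside every single marker. Splits in which a
#' class would be lost are re-drawn with an incremented sub-seed and
#' counted. When a split selects no marker, both models fall back to the
#' single marker with the best training AUROC (counted in `n_fallback`).
#'
#' @param table a `cohort` (both classes with at least 5 patients
#'   recommended).
#' @param n_splits number of repeated splits (default 200).
#' @param train_fraction training fraction (default 0.8).
#' @param base_seed base seed; split `i` uses `base_seed + i`.
#' @param q top-contribution markers unioned into the selected set when
#'   ranking (default 0: the per-split selection is the pure L1 support).
#' @return A `repeated_splits` object: `per_split` data frame (test AUROCs,
#'   selected panel size), `selection` logical matrix, `single_auroc`
#'   matrix, `selection_freq`, `summary` (mean/sd/CI/median/IQR per model),
#'   `paired_wilcoxon_p`, `paired_t_p`, `n_redraws`, `n_fallback`.
#' @export
repeated_splits <- function(table, n_splits = 200L, train_fraction = 0.8,
                            base_seed = 42L, q = 0L) {
  specs <- cohort_specs(table)
  markers <- specs$name
  sel <- matrix(FALSE, n_splits, length(markers),
                dimnames = list(NULL, markers))
  single <- matrix(NA_real_, n_splits, length(markers),
                   dimnames = list(NULL, markers))
  auroc_hybrid <- numeric(n_splits)
  auroc_additive <- numeric(n_splits)
  seeds <- integer(n_splits)
  n_redraws <- 0L
  n_fallback <- 0L
  for (i in seq_len(n_splits)) {
    seed_i <- base_seed + i
    parts <- NULL
    attempt <- 0L
    while (is.null(parts)) {
      parts <- tryCatch(
        split_train_test(table, train_fraction,
                         seed = seed_i + attempt * 1000003L,
                         stratified = TRUE),
        error = function(e) NULL)
      if (is.null(parts)) {
        attempt <- attempt + 1L
        n_redraws <- n_redraws + 1L
        if (attempt > 50L) stop("repeated splits: cannot form a valid split")
      }
    }
    seeds[i] <- seed_i + attempt * 1000003L
    train <- impute_stratified_median(parts$train, "paper_faithful")
    test <- impute_stratified_median(parts$test, "leakage_safe",
                                     reference = train)
    zs <- standardize(train)
    ztest <- standardize(test, zs$stats)$table
    Xtr <- marker_matrix(zs$table)
    ytr <- train$label
    Xte <- marker_matrix(ztest)
    yte <- test$label
    # single-marker test AUROCs (native direction: higher = more iCCA-like)
    for (nm in markers) single[i, nm] <- auroc_value(Xte[, nm], yte)

    cv <- select_lambda_cv(Xtr, ytr, fold_seed = seed_i)
    l1 <- fit_l1_logistic(Xtr, ytr, cv$lambda)
    chosen <- names(which(l1$coefficients != 0))
    if (q > 0) {
      contrib <- pca_contribution(Xtr, K = min(4, ncol(Xtr)))
      chosen <- union(chosen,
                      names(sort(contrib, decreasing = TRUE))[seq_len(q)])
    }
    if (!length(chosen)) {
      n_fallback <- n_fallback + 1L
      train_auc <- vapply(markers, function(nm)
        auroc_value(Xtr[, nm], ytr), numeric(1))
      chosen <- markers[which.max(abs(train_auc - 0.5))]
    } else {
      sel[i, chosen] <- TRUE
    }
    hy <- fit_ridge_logistic(Xtr[, chosen, drop = FALSE], ytr)
    auroc_hybrid[i] <- auroc_value(
      logistic_predict(hy, Xte[, chosen, drop = FALSE]), yte)

    add_specs <- specs[specs$name %in% chosen, , drop = FALSE]
    class(add_specs) <- class(specs)
    add_model <- build_split_additive(train, chosen)
    pts <- score_points(add_model, marker_matrix(test, chosen))
    auroc_additive[i] <- auroc_value(pts, yte)
  }
  per_split <- data.frame(split = seq_len(n_splits), seed = seeds,
                          auroc_hybrid = auroc_hybrid,
                          auroc_additive = auroc_additive,
                          n_selected = rowSums(sel))
  summarize <- function(x) {
    ci <- mean(x) + c(-1, 1) * stats::qt(0.975, length(x) - 1) *
      stats::sd(x) / sqrt(length(x))
    c(mean = mean(x), sd = stats::sd(x), ci_low = ci[1], ci_high = ci[2],
      median = stats::median(x),
      iqr_low = unname(stats::quantile(x, 0.25)),
      iqr_high = unname(stats::quantile(x, 0.75)))
  }
  wil <- suppressWarnings(stats::wilcox.test(
    auroc_additive, auroc_hybrid, paired = TRUE, exact = FALSE,
    correct = FALSE))
  tt <- stats::t.test(auroc_additive, auroc_hybrid, paired = TRUE)
  structure(list(
    per_split = per_split, selection = sel, single_auroc = single,
    selection_freq = colMeans(sel),
    single_auroc_mean = colMeans(single),
    summary = rbind(hybrid = summarize(auroc_hybrid),
                    additive = summarize(auroc_additive)),
    paired_wilcoxon_p = wil$p.value, paired_t_p = tt$p.value,
    n_redraws = n_redraws, n_fallback = n_fallback,
    base_seed = base_seed, train_fraction = train_fraction),
    class = "repeated_splits")
}

# additive model over an arbitrary marker subset (used inside repeated
# splits, where the panel is the per-split selection, not a named variant)
build_split_additive <- function(train, panel) {
  specs <- cohort_specs(train)
  m <- marker_matrix(train, panel)
  rows <- lapply(panel, function(nm) {
    dir <- specs$score_direction[match(nm, specs$name)]
    cs <- youden_cutoff(m[, nm], train$label, direction = dir)
    data.frame(marker = nm, units = specs$units[match(nm, specs$name)],
               cutoff = cs$cutoff, source = "youden", direction = dir,
               J = cs$J, stringsAsFactors = FALSE)
  })
  model <- structure(list(variant = "selected", cutoffs = do.call(rbind, rows),
                          threshold = 1L,
                          threshold_source = "youden_on_total"),
                     class = "score_model")
  pts <- score_points(model, m)
  model$threshold <- tryCatch({
    cs <- youden_cutoff(pts, train$label, direction = "above_scores_point")
    max(1L, min(length(panel), as.integer(ceiling(cs$cutoff))))
  }, error = function(e) max(1L, min(length(panel), 4L)))
  model
}

#' @export
print.repeated_splits <- function(x, ...) {
  cat(sprintf("Repeated splits: %d x %.0f:%.0f, base seed %d\n",
              nrow(x$per_split), 100 * x$train_fraction,
              100 * (1 - x$train_fraction), x$base_seed))
  print(round(x$summary, 4))
  cat("selection frequency:\n")
  print(round(x$selection_freq, 3))
  invisible(x)
}
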