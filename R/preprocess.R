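#' Z-score standardization of marker columns
#'
#' Replaces every marker value by `(x - mean) / sd`. When `stats` is absent
#' the per-marker mean and sample standard deviation (n - 1 denominator) are
#' fitted on `table` itself, ignoring missing entries — the intended use is
#' to fit on the training split and apply the returned stats to held-out
#' data, so no test information leaks into the scaling.
#'
#' @param table a `cohort` object.
#' @param stats optional `standardization_stats` from a previous call.
#' @return List with elements `table` (markers in z-units) and `stats`
#'   (class `standardization_stats`: named `mean` and `sd` vectors).
#' @export
standardize <- function(table, stats = NULL) {
  m <- marker_matrix(table)
  if (is.null(stats)) {
    mu <- colMeans(m, na.rm = TRUE)
    sdv <- apply(m, 2, stats::sd, na.rm = TRUE)
    zero <- !is.finite(sdv) | sdv <= 0
    if (any(zero)) {
      stop("standardization error: zero-variance marker(s): ",
           paste(colnames(m)[zero], collapse = ", "))
    }
    stats <- structure(list(mean = mu, sd = sdv),
                       class = "standardization_stats")
  } else {
    stopifnot(inherits(stats, "standardization_stats"))
    if (!all(colnames(m) %in% names(stats$mean))) {
      stop("standardization error: stats do not cover all markers")
    }
  }
  z <- sweep(sweep(m, 2, stats$mean[colnames(m)], "-"),
             2, stats$sd[colnames(m)], "/")
  list(table = replace_markers(table, z), stats = stats)
}

#' Invert a standardization
#'
#' @param table a `cohort` whose markers are in z-units.
#' @param stats the `standardization_stats` that produced it.
#' @return A `cohort` with markers back in native units.
#' @export
unstandardize <- function(table, stats) {
  m <- marker_matrix(table)
  x <- sweep(sweep(m, 2, stats$sd[colnames(m)], "*"),
             2, stats$mean[colnames(m)], "+")
  replace_markers(table, x)
}

#' Median imputation of missing serology values
#'
#' Two modes are provided because disease-stratified imputation consults the
#' diagnosis label, which is unknown for a patient awaiting classification:
#'
#' * `paper_faithful` — each missing value is replaced by the median of that
#'   marker within the patient's own diagnosis class (used on training data).
#' * `leakage_safe` — missing values are replaced by the overall median of
#'   the marker in a `reference` table (the training split), so labels are
#'   never consulted at prediction time.
#'
#' Observed values are never altered; the result contains no missing values.
#'
#' @param table a `cohort` object.
#' @param mode `"paper_faithful"` or `"leakage_safe"`.
#' @param reference training `cohort` supplying medians for `leakage_safe`.
#' @return An imputed `cohort`.
#' @export
impute_stratified_median <- function(table,
                                     mode = c("paper_faithful", "leakage_safe"),
                                     reference = NULL) {
  mode <- match.arg(mode)
  specs <- cohort_specs(table)
  m <- marker_matrix(table)
  bad <- colnames(m)[apply(m, 2, anyNA) &
                       !specs$allow_missing[match(colnames(m), specs$name)]]
  if (length(bad)) {
    stop("imputation error: missing values in marker(s) that do not allow ",
         "them: ", paste(bad, collapse = ", "))
  }
  if (!anyNA(m)) return(table)
  if (mode == "leakage_safe") {
    if (is.null(reference)) {
      stop("imputation error: leakage_safe mode requires a reference table")
    }
    ref <- marker_matrix(reference)
  }
  for (nm in colnames(m)) {
    miss <- is.na(m[, nm])
    if (!any(miss)) next
    if (mode == "paper_faithful") {
      for (cls in c(0, 1)) {
        rows <- table$label == cls & miss
        if (!any(rows)) next
        obs <- m[table$label == cls & !miss, nm]
        if (!length(obs)) {
          stop("imputation error: no observed ", nm,
               " values in class ", cls)
        }
        m[rows, nm] <- stats::median(obs)
      }
    } else {
      obs <- ref[!is.na(ref[, nm]), nm]
      if (!length(obs)) {
        stop("imputation error: no observed ", nm, " values in reference")
      }
      m[miss, nm] <- stats::median(obs)
    }
  }
  replace_markers(table, m)
}

#' Stratified train/test split
#'
#' Partitions the cohort into disjoint, exhaustive train and test parts.
#' With `stratified = TRUE` (default) sampling is done within each diagnosis
#' class so class proportions are preserved to rounding; a part that would
#' receive zero members of a class is an error (AUROC would be undefined).
#' The same seed always yields the same partition.
#'
#' @param table a `cohort` object.
#' @param train_fraction fraction of patients assigned to training, in (0,1).
#' @param seed integer seed for the partition.
#' @param stratified stratify by class? Default `TRUE`.
#' @return List with `cohort` elements `train` and `test`.
#' @export
split_train_test <- function(table, train_fraction = 0.8, seed = 42L,
                             stratified = TRUE) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  n <- nrow(table)
  idx_train <- withr::with_seed(seed, {
    if (stratified) {
      unlist(lapply(c(0, 1), function(cls) {
        rows <- which(table$label == cls)
        if (length(rows) < 2) {
          stop("split error: class ", cls, " has fewer than 2 members")
        }
        k <- round(train_fraction * length(rows))
        if (k < 1 || k >= length(rows)) {
          stop("split error: class ", cls,
               " would be absent from one part under stratified splitting")
        }
        rows[sample.int(length(rows), k)]
      }), use.names = FALSE)
    } else {
      k <- round(train_fraction * n)
      if (k < 1 || k >= n) stop("split error: degenerate split size")
      sample.int(n, k)
    }
  })
  idx_train <- sort(idx_train)
  list(train = subset_cohort(table, idx_train),
       test = subset_cohort(table, setdiff(seq_len(n), idx_train)))
}
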