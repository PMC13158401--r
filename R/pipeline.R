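#' Configure a full analysis run
#'
#' Bundles every tunable of [run_full_analysis()] into one reproducible
#' record. The default sizes mirror the study workflow: seed 42, 80:20
#' stratified split, 1000 bootstrap resamples, Monte Carlo noise at
#' 0/5/10/20% with 500 iterations per level, and 200 repeated splits.
#'
#' @param input optional path to a cohort CSV; when `NULL` a synthetic
#'   cohort is generated from `profile`.
#' @param profile generator profile used when `input` is `NULL`; currently
#'   `"paper_like"`.
#' @param variants score variants to build and evaluate.
#' @param threshold_source `"youden_on_total"` or `"fixed_text_rule"`.
#' @param seed master seed for every stochastic stage.
#' @param train_fraction,stratified split parameters.
#' @param bootstrap_B,mc_iters,mc_levels,n_splits robustness sizes.
#' @param mc_noise `"uniform"` or `"gaussian"` perturbation law.
#' @param q top-contribution markers unioned into the selected set.
#' @param n_per_class synthetic cohort size per class (profile runs only).
#' @return A `run_config` object.
#' @export
run_config <- function(input = NULL, profile = "paper_like",
                       variants = c("hybrid_with_afp", "hybrid_without_afp",
                                    "hybrid_fixed_afp", "prism"),
                       threshold_source = "youden_on_total",
                       seed = 42L, train_fraction = 0.8, stratified = TRUE,
                       bootstrap_B = 1000L, mc_iters = 500L,
                       mc_levels = c(0, 0.05, 0.10, 0.20),
                       mc_noise = "uniform", n_splits = 200L, q = 5L,
                       n_per_class = 25L) {
  stopifnot(is.null(input) || file.exists(input))
  structure(list(input = input, profile = profile, variants = variants,
                 threshold_source = threshold_source, seed = as.integer(seed),
                 train_fraction = train_fraction, stratified = stratified,
                 bootstrap_B = as.integer(bootstrap_B),
                 mc_iters = as.integer(mc_iters), mc_levels = mc_levels,
                 mc_noise = mc_noise, n_splits = as.integer(n_splits),
                 q = as.integer(q), n_per_class = as.integer(n_per_class)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in fixed order on one cohort: load or simulate;
#' stratified 80:20 split; disease-stratified median imputation on the
#' training part and leakage-safe imputation of the test part; z-scoring
#' fitted on the training part; cross-validated L1 + PCA marker
#' prioritization; ridge-stabilized hybrid logistic refits per variant
#' panel, evaluated on the held-out test part; additive score models built
#' on the training part and evaluated on test and on the full cohort
#' (with confusion metrics and a DeLong hybrid-vs-additive comparison);
#' bootstrap, Monte Carlo perturbation (fixed 5-point model, frozen
#' cut-offs) and repeated-split robustness; and, when survival columns are
#' present, median-stratified survival of CD9+CD133/2+ EVs in iCCA and
#' CD81+CD133/2+ EVs in HCC. Every stochastic stage is seeded from the
#' config, so identical configs give identical bundles.
#'
#' @param config a `run_config`.
#' @return A `report_bundle` list (see [write_report()]).
#' @export
run_full_analysis <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cohort <- if (!is.null(config$input)) {
    read_cohort(config$input)
  } else if (config$profile == "paper_like") {
    generate_cohort(paper_like_config(seed = config$seed,
                                      n_per_class = config$n_per_class))
  } else {
    stop("pipeline error: unknown profile ", config$profile)
  }

  marker_summary <- univariate_marker_stats(cohort)

  parts <- split_train_test(cohort, config$train_fraction,
                            seed = config$seed,
                            stratified = config$stratified)
  train <- impute_stratified_median(parts$train, "paper_faithful")
  test <- impute_stratified_median(parts$test, "leakage_safe",
                                   reference = train)
  full <- impute_stratified_median(cohort, "paper_faithful")
  zs <- standardize(train)
  ztrain <- zs$table
  ztest <- standardize(test, zs$stats)$table

  prior <- prioritize_markers(ztrain, q = config$q,
                              fold_seed = config$seed)

  evaluation <- list()
  scorecards <- list()
  for (variant in config$variants) {
    panel <- panel_markers(variant)
    hy <- fit_ridge_logistic(marker_matrix(ztrain, panel), train$label)
    prob_test <- logistic_predict(hy, marker_matrix(ztest, panel))
    add_model <- build_additive_model(train, variant,
                                      config$threshold_source)
    sc_test <- score_cohort(add_model, test)
    sc_full <- score_cohort(add_model, full)
    cmp <- delong_compare(sc_test$points, prob_test, test$label)
    conf_full <- confusion_metrics(sc_full$predicted, full$label)
    evaluation[[variant]] <- list(
      hybrid_test_auroc = auroc_value(prob_test, test$label),
      additive_test_auroc = auroc_value(sc_test$points, test$label),
      additive_full_auroc = auroc_value(sc_full$points, full$label),
      additive_full_confusion = conf_full,
      delong_additive_vs_hybrid = cmp,
      threshold = add_model$threshold)
    scorecards[[variant]] <- add_model
  }

  prism_model <- if ("prism" %in% names(scorecards)) {
    scorecards[["prism"]]
  } else {
    build_additive_model(train, "prism", config$threshold_source)
  }
  prism_full <- score_cohort(prism_model, full)
  boot <- bootstrap_auroc(prism_full$points, full$label,
                          B = config$bootstrap_B, seed = config$seed)
  mc <- mc_perturbation(full, prism_model, noise_levels = config$mc_levels,
                        iters = config$mc_iters, seed = config$seed,
                        noise = config$mc_noise)
  splits <- repeated_splits(cohort, n_splits = config$n_splits,
                            train_fraction = config$train_fraction,
                            base_seed = config$seed)

  surv <- NULL
  if ("os_days" %in% names(cohort)) {
    surv <- list(
      icca_cd9 = survival_stratified(full, "cd9_cd133_2_per_ml",
                                     label_class = 1,
                                     seed = config$seed),
      hcc_cd81 = survival_stratified(full, "cd81_cd133_2_per_ml",
                                     label_class = 0,
                                     seed = config$seed))
  }

  structure(list(config = config, cohort = cohort,
                 marker_summary = marker_summary,
                 prioritization = prior, evaluation = evaluation,
                 scorecards = scorecards, bootstrap = boot, mc = mc,
                 splits = splits, survival = surv,
                 versions = list(
                   evscore = as.character(utils::packageVersion("evscore")),
                   r = paste(R.version$major, R.version$minor, sep = "."))),
            class = "report_bundle")
}

#' Write a report bundle to disk
#'
#' Serializes every component of a [run_full_analysis()] bundle under
#' deterministic filenames (CSV for tables, JSON for structured results,
#' text scorecards) and writes a manifest listing each artifact with its
#' MD5 content hash. Re-running an identical config reproduces identical
#' hashes; no timestamps are embedded.
#'
#' @param bundle a `report_bundle`.
#' @param outdir output directory (created if absent).
#' @param overwrite allow overwriting existing artifact files
#'   (default `FALSE`: collision is an error).
#' @return Data frame manifest (`file`, `md5`), invisibly; also written as
#'   `manifest.json`.
#' @export
write_report <- function(bundle, outdir, overwrite = FALSE) {
  stopifnot(inherits(bundle, "report_bundle"))
  if (!dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  if (!dir.exists(outdir)) stop("report error: cannot create ", outdir)
  files <- character(0)
  emit_csv <- function(df, name) {
    path <- file.path(outdir, name)
    if (file.exists(path) && !overwrite) {
      stop("report error: ", name, " exists (use overwrite = TRUE)")
    }
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  emit_json <- function(obj, name) {
    path <- file.path(outdir, name)
    if (file.exists(path) && !overwrite) {
      stop("report error: ", name, " exists (use overwrite = TRUE)")
    }
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10,
                         pretty = TRUE, force = TRUE)
    files <<- c(files, path)
  }
  emit_text <- function(lines, name) {
    path <- file.path(outdir, name)
    if (file.exists(path) && !overwrite) {
      stop("report error: ", name, " exists (use overwrite = TRUE)")
    }
    writeLines(lines, path)
    files <<- c(files, path)
  }

  emit_csv(as.data.frame(bundle$marker_summary), "marker_summary.csv")
  emit_csv(as.data.frame(bundle$prioritization$result), "prioritization.csv")
  emit_json(list(lambda = bundle$prioritization$lambda,
                 intercept = bundle$prioritization$model$intercept,
                 coefficients = as.list(bundle$prioritization$model$coefficients),
                 contributions = as.list(bundle$prioritization$contributions)),
            "prioritization.json")
  for (variant in names(bundle$scorecards)) {
    emit_text(format_scorecard(bundle$scorecards[[variant]]),
              paste0("scorecard_", variant, ".txt"))
    emit_json(jsonlite::fromJSON(scorecard_json(bundle$scorecards[[variant]])),
              paste0("scorecard_", variant, ".json"))
  }
  emit_json(lapply(bundle$evaluation, function(ev) {
    list(hybrid_test_auroc = ev$hybrid_test_auroc,
         additive_test_auroc = ev$additive_test_auroc,
         additive_full_auroc = ev$additive_full_auroc,
         threshold = ev$threshold,
         confusion = unclass(ev$additive_full_confusion),
         delong = unclass(ev$delong_additive_vs_hybrid))
  }), "evaluation.json")
  emit_json(list(bootstrap = list(B = bundle$bootstrap$B,
                                  estimate = bundle$bootstrap$estimate,
                                  mean = bundle$bootstrap$mean,
                                  ci = bundle$bootstrap$ci),
                 mc = bundle$mc$summary,
                 splits = list(summary = as.data.frame(bundle$splits$summary),
                               selection_freq =
                                 as.list(bundle$splits$selection_freq),
                               paired_wilcoxon_p =
                                 bundle$splits$paired_wilcoxon_p,
                               paired_t_p = bundle$splits$paired_t_p,
                               n_redraws = bundle$splits$n_redraws,
                               n_fallback = bundle$splits$n_fallback),
                 seed = bundle$config$seed,
                 versions = bundle$versions), "robustness.json")
  emit_csv(bundle$splits$per_split, "per_split_aurocs.csv")
  emit_csv(bundle$mc$summary, "mc_summary.csv")
  if (!is.null(bundle$survival)) {
    emit_json(lapply(bundle$survival, function(s) {
      list(marker = s$marker, label_class = s$label_class, n = s$n,
           n_above = s$n_above, n_below = s$n_below,
           median_above = s$median_above, median_below = s$median_below,
           median_ratio = s$median_ratio,
           median_ratio_ci = s$median_ratio_ci,
           logrank_chisq = s$logrank$chisq, logrank_p = s$logrank$p,
           gehan_chisq = s$gehan$chisq, gehan_p = s$gehan$p,
           cox_hr = if (inherits(s$cox, "cox_result")) s$cox$hr else NA,
           cox_ci = if (inherits(s$cox, "cox_result")) s$cox$ci else NA,
           oe_hr = s$oe_hr)
    }), "survival.json")
    for (nm in names(bundle$survival)) {
      s <- bundle$survival[[nm]]
      emit_csv(data.frame(group = rep(c("above", "below"),
                                      c(length(s$km_above$time),
                                        length(s$km_below$time))),
                          time = c(s$km_above$time, s$km_below$time),
                          n_risk = c(s$km_above$n_risk, s$km_below$n_risk),
                          n_event = c(s$km_above$n_event, s$km_below$n_event),
                          surv = c(s$km_above$surv, s$km_below$surv)),
               paste0("km_", nm, ".csv"))
    }
  }

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  rownames(manifest) <- NULL
  emit_json(manifest, "manifest.json")
  invisible(manifest)
}
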