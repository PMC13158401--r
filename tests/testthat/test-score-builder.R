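test_that("Youden cut-offs match hand anchors and the exhaustive scan", {
  # perfect separation
  cs <- youden_cutoff(c(1, 2, 2, 3, 4, 5, 6, 7),
                      c(0, 0, 0, 0, 1, 1, 1, 1))
  expect_equal(cs$cutoff, 3.5)
  expect_equal(cs$J, 1)

  # overlap: cutoff 3.5, J = 0.75 (sens 1.0, spec 0.75)
  cs2 <- youden_cutoff(c(1, 2, 3, 6, 4, 5, 6, 7),
                       c(0, 0, 0, 0, 1, 1, 1, 1))
  expect_equal(cs2$cutoff, 3.5)
  expect_equal(cs2$J, 0.75)
  expect_equal(cs2$sensitivity, 1)
  expect_equal(cs2$specificity, 0.75)

  # interleaved labels: J equals the exhaustive-scan maximum, <= 0.5 here
  v <- 1:8
  lab <- rep(c(0, 1), 4)
  cs3 <- youden_cutoff(v, lab)
  or3 <- youden_oracle(v, lab)
  expect_equal(cs3$cutoff, or3$cutoff)
  expect_equal(cs3$J, or3$J)
  expect_lte(cs3$J, 0.5)

  # oracle agreement across random tied instances, both directions
  for (s in 1:50) {
    withr::with_seed(500 + s, {
      inst <- random_tied_instance()
      dir <- sample(c("above_scores_point", "below_scores_point"), 1)
    })
    if (length(unique(inst$scores)) < 2) next
    got <- youden_cutoff(inst$scores, inst$labels, dir)
    want <- youden_oracle(inst$scores, inst$labels, dir)
    expect_equal(got$cutoff, want$cutoff)
    expect_equal(got$J, want$J)
  }

  expect_error(youden_cutoff(c(1, 2, 3), c(1, 1, 1)), "single-class")
  expect_error(youden_cutoff(c(2, 2, 2, 2), c(0, 0, 1, 1)), "identical")
})

test_that("fixed-cut-off variants carry their shipped constants", {
  co <- generate_cohort(paper_like_config(seed = 23))
  train <- impute_stratified_median(co, "paper_faithful")

  pm <- build_additive_model(train, "prism", "fixed_text_rule")
  expect_equal(pm$threshold, 4L)
  want <- preset_cutoffs("prism")
  expect_equal(setNames(pm$cutoffs$cutoff, pm$cutoffs$marker),
               want[pm$cutoffs$marker])
  expect_true(all(pm$cutoffs$source == "prism_table"))

  pa <- build_additive_model(train, "prism_plus_afp", "fixed_text_rule")
  expect_equal(pa$cutoffs$cutoff[pa$cutoffs$marker == "afp_ng_ml"], 20)

  hf <- build_additive_model(train, "hybrid_fixed_afp", "youden_on_total")
  expect_equal(hf$cutoffs$cutoff[hf$cutoffs$marker == "afp_ng_ml"], 20)
  expect_equal(hf$cutoffs$source[hf$cutoffs$marker == "afp_ng_ml"],
               "fixed_guideline")
  # the other cut-offs are training-derived Youden cuts
  expect_true(all(hf$cutoffs$source[hf$cutoffs$marker != "afp_ng_ml"] ==
                    "youden"))
  expect_error(build_additive_model(train, "no_such_variant"),
               "unknown score variant")
})

test_that("derived cut-offs equal the per-marker Youden oracle", {
  co <- generate_cohort(paper_like_config(seed = 29))
  train <- impute_stratified_median(co, "paper_faithful")
  hm <- build_additive_model(train, "hybrid_with_afp", "youden_on_total")
  m <- marker_matrix(train, panel_markers("hybrid_with_afp"))
  for (k in seq_len(nrow(hm$cutoffs))) {
    nm <- hm$cutoffs$marker[k]
    want <- youden_oracle(m[, nm], train$label)
    expect_equal(hm$cutoffs$cutoff[k], want$cutoff, info = nm)
  }
  # determinism: identical training data -> identical model
  hm2 <- build_additive_model(train, "hybrid_with_afp", "youden_on_total")
  expect_identical(hm, hm2)
})

test_that("additive scoring counts strict exceedances and classifies by total", {
  co <- generate_cohort(paper_like_config(seed = 23))
  train <- impute_stratified_median(co, "paper_faithful")
  pm <- build_additive_model(train, "prism", "fixed_text_rule")

  patient <- function(alp, ca, crp, cd9, cd81) {
    df <- tiny_cohort_df()[1, ]
    df$label <- 0
    df$alp_u_l <- alp
    df$ca19_9_u_ml <- ca
    df$crp <- crp
    df$cd9_cd133_2_per_ml <- cd9
    df$cd81_cd133_2_per_ml <- cd81
    cohort_table(df)
  }
  # iCCA-typical marker profile clears every fixed cut-off: 5 points
  sc <- score_cohort(pm, patient(690, 150.8, 2.83, 6.0e6, 3.0e6))
  expect_equal(sc$points, 5L)
  expect_equal(sc$predicted, 1L)
  # everything below every cut-off: 0 points, HCC
  sc0 <- score_cohort(pm, patient(100, 5, 0.2, 1e6, 0.5e6))
  expect_equal(sc0$points, 0L)
  expect_equal(sc0$predicted, 0L)
  # a value exactly at its cut-off contributes no point
  sc_edge <- score_cohort(pm, patient(439, 5, 0.2, 1e6, 0.5e6))
  expect_equal(sc_edge$points, 0L)

  # score bounds over the whole cohort
  full <- score_cohort(pm, train)
  expect_true(all(full$points >= 0 & full$points <= 5))

  # missing model marker demands imputation
  df_na <- as.data.frame(co)
  df_na$crp[1] <- NA
  expect_error(score_cohort(pm, cohort_table(df_na[, names(df_na)])),
               "impute")
})

test_that("scores are invariant under a monotone re-scaling of a marker", {
  co <- generate_cohort(paper_like_config(seed = 37))
  train <- impute_stratified_median(co, "paper_faithful")
  hm <- build_additive_model(train, "hybrid_without_afp", "youden_on_total")
  base <- score_cohort(hm, train)

  # apply x -> log(1 + x) jointly to CRP values and the CRP cut-off
  hm2 <- hm
  k <- which(hm2$cutoffs$marker == "crp")
  hm2$cutoffs$cutoff[k] <- log1p(hm2$cutoffs$cutoff[k])
  df2 <- as.data.frame(train)
  df2$crp <- log1p(df2$crp)
  tr2 <- cohort_table(df2[, names(df2)])
  expect_equal(score_cohort(hm2, tr2)$points, base$points)
})

test_that("scorecard rendering includes cut-offs, units and the total rule", {
  co <- generate_cohort(paper_like_config(seed = 23))
  train <- impute_stratified_median(co, "paper_faithful")
  pm <- build_additive_model(train, "prism", "fixed_text_rule")
  txt <- format_scorecard(pm)
  expect_true(any(grepl("439", txt)))
  expect_true(any(grepl("16.3", txt)))
  expect_true(any(grepl("total >= 4", txt)))
  js <- jsonlite::fromJSON(scorecard_json(pm))
  expect_equal(js$threshold, 4)
  expect_equal(nrow(js$cutoffs), 5)
})
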