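test_that("cohort CSV parsing handles complete, missing and invalid input", {
  df <- tiny_cohort_df()
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort_table(df), path)
  co <- read_cohort(path)
  expect_s3_class(co, "cohort")
  expect_equal(nrow(co), 3)
  expect_false(anyNA(marker_matrix(co)))
  expect_equal(co$patient_id, df$patient_id)

  # empty serology cell becomes a missing value
  df2 <- df
  df2$albumin[2] <- NA
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort_table(df2), path2)
  co2 <- read_cohort(path2)
  expect_true(is.na(co2$albumin[2]))
  expect_equal(sum(is.na(marker_matrix(co2))), 1)

  # negative EV value rejected
  df3 <- df
  df3$cd9_cd133_2_per_ml[1] <- -5
  expect_error(cohort_table(df3), "negative")
  # missing EV value rejected
  df4 <- df
  df4$cd81_cd133_2_per_ml[3] <- NA
  expect_error(cohort_table(df4), "complete-by-design")
  # unknown column rejected
  path5 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(cbind(df, extra = 1), path5, row.names = FALSE)
  expect_error(read_cohort(path5), "unknown column")
  # os_days without event rejected
  df6 <- cbind(df, os_days = c(100, 200, 300))
  expect_error(cohort_table(df6), "together")
})

test_that("cohort CSV round-trips to full precision", {
  co <- generate_cohort(paper_like_config(seed = 11))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(marker_matrix(back), marker_matrix(co), tolerance = 0)
  expect_equal(back$os_days, co$os_days, tolerance = 0)
  expect_equal(back$event, co$event)
})

test_that("standardization fits, applies, inverts, and rejects constants", {
  df <- tiny_cohort_df()
  df$label <- c(0, 1, 1)
  co <- cohort_table(df)
  zs <- standardize(co)
  m <- marker_matrix(zs$table)
  expect_equal(unname(colMeans(m)), rep(0, 9), tolerance = 1e-12)
  expect_equal(unname(apply(m, 2, sd)), rep(1, 9), tolerance = 1e-12)

  # two-value column {1, 3}: sample sd sqrt(2), symmetric about 0
  expect_equal(sd(c(1, 3)), sqrt(2))

  # applying fixed stats is plain arithmetic: (5 - 2) / 1 = 3
  stats5 <- structure(list(mean = setNames(rep(2, 9), colnames(m)),
                           sd = setNames(rep(1, 9), colnames(m))),
                      class = "standardization_stats")
  df5 <- df
  for (nm in colnames(m)) df5[[nm]] <- rep(5, 3)
  z5 <- standardize(cohort_table(df5), stats5)
  expect_equal(unname(marker_matrix(z5$table)[1, ]), rep(3, 9))

  # constant column is rejected by name
  dfc <- df
  dfc$crp <- rep(4, 3)
  expect_error(standardize(cohort_table(dfc)), "crp")

  # round trip back to native units
  back <- unstandardize(zs$table, zs$stats)
  expect_equal(marker_matrix(back), marker_matrix(co), tolerance = 1e-12)
})

test_that("median imputation fills by stratum and never touches observed values", {
  co <- generate_cohort(paper_like_config(seed = 3))
  df <- as.data.frame(co)
  df$albumin[df$label == 0][1:3] <- NA
  df$albumin[df$label == 0][4] <- 3
  df$albumin[df$label == 0][5] <- 4
  co2 <- cohort_table(df[, setdiff(names(df), c("os_days", "event"))])

  imp <- impute_stratified_median(co2, "paper_faithful")
  expect_false(anyNA(marker_matrix(imp)))
  hcc_obs <- df$albumin[df$label == 0]
  hcc_obs <- hcc_obs[!is.na(hcc_obs)]
  filled <- imp$albumin[co2$label == 0][1:3]
  expect_equal(filled, rep(median(hcc_obs), 3))
  # observed entries untouched
  seen <- !is.na(co2$albumin)
  expect_equal(imp$albumin[seen], co2$albumin[seen])

  # hand case: HCC albumin {3, 4, NA} -> 3.5
  dfh <- tiny_cohort_df()
  dfh$label <- c(0, 0, 1)
  dfh$albumin <- c(3, 4, 5)
  dfh$albumin[2] <- NA
  # only one observed HCC value (3) -> median 3
  imph <- impute_stratified_median(cohort_table(dfh), "paper_faithful")
  expect_equal(imph$albumin[2], 3)
  dfh$albumin <- c(3, 4, 5)
  coh <- cohort_table(dfh)
  expect_identical(impute_stratified_median(coh, "paper_faithful"), coh)

  # empty stratum errors; leakage_safe requires a reference
  dfe <- tiny_cohort_df()
  dfe$label <- c(0, 0, 1)
  dfe$albumin[1:2] <- NA
  expect_error(impute_stratified_median(cohort_table(dfe), "paper_faithful"),
               "no observed")
  expect_error(impute_stratified_median(co2, "leakage_safe"), "reference")
  # leakage_safe uses overall reference medians, ignoring labels
  impl <- impute_stratified_median(co2, "leakage_safe", reference = co2)
  all_obs <- co2$albumin[!is.na(co2$albumin)]
  expect_true(all(impl$albumin[is.na(co2$albumin)] == median(all_obs)))
})

test_that("stratified splitting partitions the cohort reproducibly", {
  co <- generate_cohort(paper_like_config(seed = 5))
  parts <- split_train_test(co, 0.8, seed = 99)
  expect_equal(nrow(parts$train), 40)
  expect_equal(nrow(parts$test), 10)
  expect_equal(sum(parts$train$label == 0), 20)
  expect_equal(sum(parts$train$label == 1), 20)
  expect_equal(sum(parts$test$label == 0), 5)
  expect_length(intersect(parts$train$patient_id, parts$test$patient_id), 0)
  expect_setequal(c(parts$train$patient_id, parts$test$patient_id),
                  co$patient_id)

  again <- split_train_test(co, 0.8, seed = 99)
  expect_identical(parts$train$patient_id, again$train$patient_id)

  dft <- tiny_cohort_df()
  expect_error(split_train_test(cohort_table(dft), 0.8, seed = 1),
               "split error")
})
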