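test_that("AUROC agrees between trapezoid and pair counting, with anchors", {
  # hand pair count: 6 concordant + 2 ties over 9 pairs = 0.7778
  r <- compute_auroc(c(1, 2, 3, 2, 3, 4), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$auroc, 7 / 9, tolerance = 1e-12)
  expect_equal(r$auroc, r$auroc_paircount, tolerance = 1e-12)
  # perfect ranking and all-tied degenerate cases
  expect_equal(compute_auroc(c(1, 2, 9, 10), c(0, 0, 1, 1))$auroc, 1)
  expect_equal(compute_auroc(rep(5, 6), rep(c(0, 1), 3))$auroc, 0.5)
  expect_error(compute_auroc(1:3, c(1, 1, 1)), "single-class")

  for (s in 1:50) {
    inst <- withr::with_seed(700 + s, random_tied_instance())
    r <- compute_auroc(inst$scores, inst$labels)
    expect_equal(r$auroc, r$auroc_paircount, tolerance = 1e-12)
    # sign reversal maps A -> 1 - A
    expect_equal(compute_auroc(-inst$scores, inst$labels)$auroc,
                 1 - r$auroc, tolerance = 1e-12)
    # label swap maps A -> 1 - A as well
    expect_equal(auroc_value(inst$scores, 1 - inst$labels),
                 1 - r$auroc, tolerance = 1e-12)
  }
})

test_that("DeLong comparison is null for self-comparison and matches pROC", {
  withr::with_seed(11, {
    y <- rep(c(0, 1), each = 15)
    a <- rnorm(30) + y
    b <- rnorm(30) + 0.5 * y
  })
  self <- delong_compare(a, a, y)
  expect_equal(self$z, 0)
  expect_equal(self$p, 1)
  expect_true(self$degenerate)

  d <- delong_compare(a, b, y)
  roc_of <- function(sc) {
    pROC::roc(y, sc, quiet = TRUE, direction = "<", levels = c(0, 1))
  }
  pr <- pROC::roc.test(roc_of(a), roc_of(b), method = "delong",
                       paired = TRUE)
  expect_equal(d$p, pr$p.value, tolerance = 1e-10)
  expect_equal(d$auroc_a, as.numeric(pROC::auc(roc_of(a))),
               tolerance = 1e-12)
  expect_error(delong_compare(a, b[-1], y[-1]), "length mismatch")
})

test_that("DeLong placements match hand mid-rank values on a 4-patient toy", {
  # positives {3, 1}, negatives {2, 1}
  scores <- c(3, 1, 2, 1)
  labels <- c(1, 1, 0, 0)
  pl <- evscore:::delong_placements(scores, labels)
  # V10: 3 beats both (1.0); 1 beats none, ties one (0.25)
  expect_equal(pl$v10, c(1, 0.25))
  # V01: 2 is beaten by 3 only (0.5); 1 is beaten by 3, tied with 1 (0.75)
  expect_equal(pl$v01, c(0.5, 0.75))
  expect_equal(pl$auroc, mean(c(1, 0.25)))
})

test_that("DeLong variance approximates the bootstrap variance", {
  withr::with_seed(99, {
    y <- rep(c(0, 1), each = 20)
    s <- rnorm(40) + 0.8 * y
  })
  d <- delong_compare(s, s, y)
  bs <- bootstrap_auroc(s, y, B = 10000, seed = 99)
  expect_lt(abs(d$se_a^2 / var(bs$distribution) - 1), 0.15)
})

test_that("confusion metrics reproduce the 2x2 arithmetic and flag degeneracy", {
  pred <- rep(c(1, 0, 1, 0), c(22, 3, 3, 22))
  truth <- rep(c(1, 1, 0, 0), c(22, 3, 3, 22))
  cm <- confusion_metrics(pred, truth)
  expect_equal(c(cm$tp, cm$fn, cm$fp, cm$tn), c(22, 3, 3, 22))
  expect_equal(cm$sensitivity, 0.88)
  expect_equal(cm$specificity, 0.88)
  expect_equal(cm$chi2, 50 * (22 * 22 - 3 * 3)^2 / 25^4)
  expect_lt(cm$p, 1e-4)

  perfect <- confusion_metrics(rep(c(1, 0), each = 5),
                               rep(c(1, 0), each = 5))
  expect_equal(c(perfect$sensitivity, perfect$specificity,
                 perfect$ppv, perfect$npv), rep(1, 4))

  allpos <- confusion_metrics(rep(1, 10), rep(c(1, 0), each = 5))
  expect_equal(allpos$specificity, 0)
  expect_true(is.na(allpos$npv))
  expect_true(is.na(allpos$chi2))

  # label swap exchanges sensitivity and specificity
  cm_swap <- confusion_metrics(1 - pred, 1 - truth)
  expect_equal(cm_swap$sensitivity, cm$specificity)
  expect_equal(cm_swap$specificity, cm$sensitivity)
})

test_that("univariate marker panel reproduces hand statistics", {
  df <- tiny_cohort_df()
  df <- rbind(df, df)
  df$patient_id <- paste0("P", 1:6)
  df$label <- rep(c(0, 1), each = 3)
  for (nm in default_marker_specs()$name) df[[nm]] <- c(1, 2, 3, 4, 5, 6)
  res <- univariate_marker_stats(cohort_table(df))
  row <- res[res$marker == "crp", ]
  # Welch t on {1,2,3} vs {4,5,6}: t = 3 / sqrt(2/3), df = 4, d = 3
  expect_equal(row$welch_t, 3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(row$welch_df, 4, tolerance = 1e-12)
  expect_equal(row$cohens_d, 3, tolerance = 1e-12)
  # exact Mann-Whitney two-sided p = 2/20
  expect_equal(row$mw_p, 0.1, tolerance = 1e-12)
  expect_equal(row$auroc, 1)
  expect_equal(row$fold_change, 5 / 2)

  # scaling a marker leaves its p-values, d and AUROC unchanged
  df10 <- df
  df10$crp <- df10$crp * 10
  res10 <- univariate_marker_stats(cohort_table(df10))
  r10 <- res10[res10$marker == "crp", ]
  expect_equal(r10$welch_p, row$welch_p)
  expect_equal(r10$mw_p, row$mw_p)
  expect_equal(r10$cohens_d, row$cohens_d)
  expect_equal(r10$auroc, row$auroc)

  # identical groups are fully null
  dfn <- df
  for (nm in default_marker_specs()$name) dfn[[nm]] <- c(1, 2, 3, 1, 2, 3)
  rn <- univariate_marker_stats(cohort_table(dfn))[1, ]
  expect_equal(rn$welch_t, 0, tolerance = 1e-12)
  expect_equal(rn$cohens_d, 0, tolerance = 1e-12)
  expect_equal(rn$auroc, 0.5)
})
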