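# shared fixtures, all built in code at test time

# minimal valid cohort data frame (3 patients, all columns populated)
tiny_cohort_df <- function() {
  data.frame(
    patient_id = c("A1", "A2", "A3"),
    label = c(0, 0, 1),
    afp_ng_ml = c(20, 5, 3),
    albumin = c(3.9, 4.1, 3.4),
    alp_u_l = c(250, 300, 700),
    ca19_9_u_ml = c(10, 14, 160),
    crp = c(0.5, 0.7, 3.0),
    thrombocytes_e3_ul = c(130, 140, 240),
    cd9_cd133_2_per_ml = c(2.1e6, 2.6e6, 6.2e6),
    cd63_cd133_2_per_ml = c(0.9e6, 1.2e6, 4.5e6),
    cd81_cd133_2_per_ml = c(0.5e6, 0.7e6, 7.1e6),
    stringsAsFactors = FALSE
  )
}

# generator profile with five informative markers at study-like fold-changes
# and four markers carrying no class signal at all
planted_null_config <- function(seed, n_per_class = 25) {
  generator_config(
    markers = data.frame(
      name = default_marker_specs()$name,
      log_median_hcc = log(c(10, 3.8, 271, 20, 0.59, 180,
                             2.4e6, 1.0e6, 0.6e6)),
      log_median_icca = log(c(10, 3.8, 690, 20, 2.83, 180,
                              6.0e6, 4.2e6, 7.32e6)),
      log_sd_hcc = c(1, 0.15, 0.7853, 1, 1.2112, 0.5,
                     0.9174, 1.3735, 2.1016),
      log_sd_icca = c(1, 0.15, 0.7853, 1, 1.2112, 0.5,
                      0.9174, 1.3735, 2.1016),
      missing_rate = 0
    ),
    n_per_class = n_per_class,
    seed = seed
  )
}

planted_markers <- c("alp_u_l", "crp", "cd9_cd133_2_per_ml",
                     "cd63_cd133_2_per_ml", "cd81_cd133_2_per_ml")
null_markers <- c("afp_ng_ml", "albumin", "ca19_9_u_ml",
                  "thrombocytes_e3_ul")

# generator profile with no class signal anywhere (all markers null)
all_null_config <- function(seed, n_per_class = 25) {
  generator_config(
    markers = data.frame(
      name = default_marker_specs()$name,
      log_median_hcc = log(c(10, 3.8, 300, 20, 1, 180,
                             2e6, 1e6, 1e6)),
      log_median_icca = log(c(10, 3.8, 300, 20, 1, 180,
                              2e6, 1e6, 1e6)),
      log_sd_hcc = 1, log_sd_icca = 1, missing_rate = 0
    ),
    n_per_class = n_per_class,
    seed = seed
  )
}

# random scores with forced ties for ROC identity checks
random_tied_instance <- function(n_max = 30) {
  n1 <- sample(2:(n_max / 2), 1)
  n0 <- sample(2:(n_max / 2), 1)
  scores <- sample(1:6, n1 + n0, replace = TRUE) +
    sample(c(0, 0.5), n1 + n0, replace = TRUE)
  list(scores = scores, labels = rep(c(1, 0), c(n1, n0)))
}

# brute-force Youden scan over every candidate midpoint threshold; counts
# are compared as integers so ties are exact
youden_oracle <- function(values, labels, direction = "above_scores_point") {
  v <- sort(unique(values))
  span <- v[length(v)] - v[1]
  cand <- c(v[1] - span - 1, (v[-1] + v[-length(v)]) / 2,
            v[length(v)] + span + 1)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  best <- NULL
  for (c_m in cand) {
    s <- if (direction == "above_scores_point") values > c_m else values < c_m
    sn <- sum(s & labels == 1)
    pn <- sum(!s & labels == 0)
    js <- sn * n0 + pn * n1
    if (is.null(best) || js > best$js ||
        (js == best$js && pn > best$pn) ||
        (js == best$js && pn == best$pn && c_m < best$cutoff)) {
      best <- list(cutoff = c_m, J = sn / n1 + pn / n0 - 1,
                   js = js, pn = pn)
    }
  }
  best
}
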