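#' Youden-optimal cut-off for a single marker
#'
#' Scans candidate thresholds placed at the midpoints between consecutive
#' distinct sorted values, plus sentinels below and above the data range,
#' and returns the one maximizing the Youden index
#' `J = sensitivity + specificity - 1`. Sensitivity counts class-1 patients
#' on the scoring side of the cut (strictly above for
#' `above_scores_point`, strictly below otherwise). Ties on J are broken
#' toward higher specificity, then toward the lower threshold.
#'
#' @param values numeric marker values (no missing entries).
#' @param labels binary vector (both classes present).
#' @param direction `"above_scores_point"` (default) or
#'   `"below_scores_point"`.
#' @return A `cutoff_spec` list: `cutoff`, `J`, `sensitivity`,
#'   `specificity`, `direction`, `source = "youden"`.
#' @export
youden_cutoff <- function(values, labels,
                          direction = c("above_scores_point",
                                        "below_scores_point")) {
  direction <- match.arg(direction)
  if (anyNA(values)) stop("youden error: missing values")
  if (length(unique(labels)) < 2) stop("youden error: single-class labels")
  v <- sort(unique(values))
  if (length(v) < 2) {
    stop("youden error: all values identical, no informative cut exists")
  }
  span <- v[length(v)] - v[1]
  cand <- c(v[1] - span - 1, (v[-1] + v[-length(v)]) / 2,
            v[length(v)] + span + 1)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  scoring_side <- function(c_m) {
    if (direction == "above_scores_point") values > c_m else values < c_m
  }
  sens_n <- integer(length(cand))
  spec_n <- integer(length(cand))
  for (k in seq_along(cand)) {
    s <- scoring_side(cand[k])
    sens_n[k] <- sum(s & labels == 1)
    spec_n[k] <- sum(!s & labels == 0)
  }
  # compare J = sens + spec - 1 in exact integer arithmetic (common
  # denominator n1 * n0) so ties are broken deterministically, free of
  # floating-point noise
  j_scaled <- sens_n * n0 + spec_n * n1
  best <- order(-j_scaled, -spec_n, cand)[1]
  structure(list(cutoff = cand[best],
                 J = sens_n[best] / n1 + spec_n[best] / n0 - 1,
                 sensitivity = sens_n[best] / n1,
                 specificity = spec_n[best] / n0,
                 direction = direction, source = "youden"),
            class = "cutoff_spec")
}

#' Build an additive point-score model
#'
#' Assembles the "paper-and-pencil" scoring object for a variant: one
#' cut-off per panel marker plus an integer total-score threshold `T`
#' (classify iCCA when total points >= `T`).
#'
#' Cut-off sources by variant: the hybrid variants derive every cut-off by
#' [youden_cutoff()] on the training data, except that `hybrid_fixed_afp`
#' fixes AFP at the guideline 20 ng/ml; the `prism` variants use the shipped
#' fixed constants (ALP 439 U/L, CA19-9 16.3 U/ml, CRP 0.87, CD9+ 3.2e6/ml,
#' CD81+ 1.06e6/ml), with `prism_plus_afp` adding AFP at 20 ng/ml.
#'
#' The threshold `T` comes from a Youden scan of the training total scores
#' (`threshold_source = "youden_on_total"`, default) or is fixed at 4
#' (`"fixed_text_rule"`: 0-3 points HCC, 4+ points iCCA).
#'
#' @param train training `cohort`, imputed, markers in native units.
#' @param variant one of the variants of [panel_markers()].
#' @param threshold_source `"youden_on_total"` or `"fixed_text_rule"`.
#' @return A `score_model`: `variant`, `cutoffs` data frame (`marker`,
#'   `units`, `cutoff`, `source`, `direction`, `J`), `threshold`,
#'   `threshold_source`.
#' @export
build_additive_model <- function(train, variant,
                                 threshold_source = c("youden_on_total",
                                                      "fixed_text_rule")) {
  threshold_source <- match.arg(threshold_source)
  panel <- panel_markers(variant)
  specs <- cohort_specs(train)
  m <- marker_matrix(train, panel)
  if (anyNA(m)) stop("score model error: training markers must be imputed")
  fixed <- switch(variant,
    prism = preset_cutoffs("prism"),
    prism_plus_afp = c(afp_ng_ml = 20, preset_cutoffs("prism")),
    hybrid_fixed_afp = c(afp_ng_ml = 20),
    NULL)
  rows <- lapply(panel, function(nm) {
    dir <- specs$score_direction[match(nm, specs$name)]
    if (!is.null(fixed) && nm %in% names(fixed)) {
      data.frame(marker = nm, units = specs$units[match(nm, specs$name)],
                 cutoff = unname(fixed[nm]),
                 source = if (startsWith(variant, "prism") &&
                              nm != "afp_ng_ml") "prism_table"
                          else "fixed_guideline",
                 direction = dir, J = NA_real_, stringsAsFactors = FALSE)
    } else {
      cs <- youden_cutoff(m[, nm], train$label, direction = dir)
      data.frame(marker = nm, units = specs$units[match(nm, specs$name)],
                 cutoff = cs$cutoff, source = "youden",
                 direction = dir, J = cs$J, stringsAsFactors = FALSE)
    }
  })
  cutoffs <- do.call(rbind, rows)
  model <- structure(list(variant = variant, cutoffs = cutoffs,
                          threshold = 4L,
                          threshold_source = threshold_source),
                     class = "score_model")
  if (threshold_source == "youden_on_total") {
    pts <- score_points(model, m)
    model$threshold <- tryCatch({
      cs <- youden_cutoff(pts, train$label, direction = "above_scores_point")
      max(1L, min(nrow(cutoffs), as.integer(ceiling(cs$cutoff))))
    }, error = function(e) {
      # degenerate training totals (all identical): fall back to the fixed
      # text rule, clamped to the panel size
      max(1L, min(nrow(cutoffs), 4L))
    })
  }
  model
}

# integer points for a marker matrix already restricted to the panel
score_points <- function(model, m) {
  pts <- integer(nrow(m))
  for (k in seq_len(nrow(model$cutoffs))) {
    nm <- model$cutoffs$marker[k]
    c_m <- model$cutoffs$cutoff[k]
    side <- if (model$cutoffs$direction[k] == "above_scores_point") {
      m[, nm] > c_m
    } else {
      m[, nm] < c_m
    }
    pts <- pts + as.integer(side)
  }
  pts
}

#' Score a cohort with an additive model
#'
#' Each marker strictly beyond its cut-off (in the scoring direction)
#' contributes one point; the patient is classified as iCCA when the total
#' reaches the model threshold. A value exactly at a cut-off contributes no
#' point.
#'
#' @param model a `score_model`.
#' @param table a `cohort`, imputed, markers in native units.
#' @return Data frame: `patient_id`, `points`, `predicted` (0 = HCC,
#'   1 = iCCA).
#' @export
score_cohort <- function(model, table) {
  panel <- model$cutoffs$marker
  m <- marker_matrix(table, panel)
  if (anyNA(m)) {
    stop("scoring error: missing values among model markers; impute first")
  }
  specs <- cohort_specs(table)
  units_now <- specs$units[match(panel, specs$name)]
  if (any(units_now != model$cutoffs$units)) {
    stop("scoring error: marker units differ from the model's units")
  }
  pts <- score_points(model, m)
  data.frame(patient_id = table$patient_id, points = pts,
             predicted = as.integer(pts >= model$threshold),
             stringsAsFactors = FALSE)
}

#' @export
print.score_model <- function(x, ...) {
  cat(format_scorecard(x), sep = "\n")
  invisible(x)
}

#' Human-readable scorecard
#'
#' Renders a `score_model` as the text block a clinician could use at the
#' bedside: one line per marker with units and cut-off, and the
#' classification rule on the total.
#'
#' @param model a `score_model`.
#' @return Character vector of scorecard lines.
#' @export
format_scorecard <- function(model) {
  lines <- c(sprintf("Additive score — variant: %s", model$variant),
             sprintf("%-22s %-14s %-14s %s", "marker", "units", "cut-off",
                     "1 point if"))
  for (k in seq_len(nrow(model$cutoffs))) {
    r <- model$cutoffs[k, ]
    lines <- c(lines, sprintf("%-22s %-14s %-14.6g %s", r$marker, r$units,
                              r$cutoff,
                              if (r$direction == "above_scores_point")
                                "above" else "below"))
  }
  c(lines,
    sprintf("Total score 0-%d; classify iCCA if total >= %d (%s), else HCC.",
            nrow(model$cutoffs), model$threshold, model$threshold_source))
}

#' Serialize a score model to JSON
#'
#' @param model a `score_model`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
scorecard_json <- function(model, path = NULL) {
  obj <- list(variant = model$variant,
              cutoffs = model$cutoffs,
              threshold = model$threshold,
              threshold_source = model$threshold_source,
              rule = "classify iCCA iff total points >= threshold")
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
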