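#' Marker specifications for the LR-M panel
#'
#' The nine-marker panel combines six routine serological parameters with
#' three CD133/2-positive small extracellular vesicle (EV) subpopulations
#' captured by their tetraspanin co-markers (CD9, CD63, CD81). Each spec
#' records the native units, whether the marker belongs to the serology or
#' EV class, the direction in which a value scores a point in an additive
#' model, and whether missing entries are tolerated. EV counts come from a
#' complete assay, so EV columns never allow missingness.
#'
#' @param name,units,marker_class,score_direction,allow_missing vectors of
#'   equal length describing each marker.
#' @return A data frame with one row per marker and class `marker_spec`.
#' @export
marker_specs <- function(name, units, marker_class,
                         score_direction = "above_scores_point",
                         allow_missing = marker_class == "serology") {
  stopifnot(length(name) >= 1)
  specs <- data.frame(
    name = as.character(name),
    units = as.character(units),
    marker_class = match.arg(marker_class, c("serology", "ev"),
                             several.ok = TRUE),
    score_direction = rep_len(score_direction, length(name)),
    allow_missing = rep_len(as.logical(allow_missing), length(name)),
    stringsAsFactors = FALSE
  )
  bad_dir <- !specs$score_direction %in%
    c("above_scores_point", "below_scores_point")
  if (any(bad_dir)) {
    stop("invalid score_direction for marker(s): ",
         paste(specs$name[bad_dir], collapse = ", "))
  }
  if (any(specs$marker_class == "ev" & specs$allow_missing)) {
    stop("EV markers must have allow_missing = FALSE")
  }
  if (anyDuplicated(specs$name)) stop("duplicated marker names")
  class(specs) <- c("marker_spec", "data.frame")
  specs
}

#' Default marker panel
#'
#' AFP, albumin, ALP, CA19-9, CRP and thrombocytes (serology; missing entries
#' permitted) plus CD9+, CD63+ and CD81+ CD133/2+ small-EV concentrations
#' (complete by design). All markers default to scoring a point when the value
#' lies strictly above the cut-off; AFP is included with the same literal rule
#' even though it runs higher in HCC (see the methods vignette).
#'
#' @return A `marker_spec` data frame with nine rows.
#' @export
default_marker_specs <- function() {
  marker_specs(
    name = c("afp_ng_ml", "albumin", "alp_u_l", "ca19_9_u_ml", "crp",
             "thrombocytes_e3_ul", "cd9_cd133_2_per_ml",
             "cd63_cd133_2_per_ml", "cd81_cd133_2_per_ml"),
    units = c("ng/ml", "g/dl", "U/L", "U/ml", "mg/l", "1e3/ul",
              "particles/ml", "particles/ml", "particles/ml"),
    marker_class = c(rep("serology", 6), rep("ev", 3))
  )
}

#' Marker panels of the shipped score variants
#'
#' The hybrid panels pair CA19-9, CRP and ALP with the CD9+ and CD81+
#' CD133/2+ EV subpopulations, with AFP optional; the 5-point fixed-cut-off
#' panel drops AFP (an AFP add-on variant re-adds it at the guideline 20
#' ng/ml threshold).
#'
#' @param variant one of `"hybrid_with_afp"`, `"hybrid_without_afp"`,
#'   `"hybrid_fixed_afp"`, `"prism"`, `"prism_plus_afp"`.
#' @return Character vector of marker names.
#' @export
panel_markers <- function(variant) {
  base5 <- c("alp_u_l", "ca19_9_u_ml", "crp",
             "cd9_cd133_2_per_ml", "cd81_cd133_2_per_ml")
  switch(variant,
    hybrid_with_afp = c("afp_ng_ml", base5),
    hybrid_without_afp = base5,
    hybrid_fixed_afp = c("afp_ng_ml", base5),
    prism = base5,
    prism_plus_afp = c("afp_ng_ml", base5),
    stop("unknown score variant: ", variant)
  )
}

#' Published cut-off presets
#'
#' Named cut-off sets shipped with the package: the ROC-Youden cut-offs of
#' the hybrid panels (with and without AFP), and the fixed 5-point cut-offs
#' used by the computation-free scorecard. These are reference constants for
#' replication; `build_additive_model()` re-derives cut-offs from training
#' data unless a fixed source is requested.
#'
#' @param preset one of `"hybrid_with_afp"`, `"hybrid_without_afp"`,
#'   `"prism"`.
#' @return Named numeric vector of cut-offs in native units.
#' @export
preset_cutoffs <- function(preset) {
  switch(preset,
    hybrid_with_afp = c(
      afp_ng_ml = 400, alp_u_l = 456, ca19_9_u_ml = 117, crp = 0.88,
      cd9_cd133_2_per_ml = 5.292e6, cd81_cd133_2_per_ml = 2.45055e6),
    hybrid_without_afp = c(
      alp_u_l = 456, ca19_9_u_ml = 117.9, crp = 0.88,
      cd9_cd133_2_per_ml = 5.292e6, cd81_cd133_2_per_ml = 2.45055e6),
    prism = c(
      alp_u_l = 439, ca19_9_u_ml = 16.3, crp = 0.87,
      cd9_cd133_2_per_ml = 3.2e6, cd81_cd133_2_per_ml = 1.06e6),
    stop("unknown preset: ", preset)
  )
}
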