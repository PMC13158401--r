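#' Construct and validate a cohort table
#'
#' A cohort table is a data frame with one row per patient: `patient_id`,
#' a binary `label` (0 = HCC, 1 = iCCA), one column per marker in native
#' units, and optionally `os_days` (overall survival in days) together with
#' `event` (1 = death, 0 = censored). Marker values must be non-negative;
#' missing entries are allowed only where the marker spec permits them
#' (never in EV columns).
#'
#' @param df data frame holding the columns described above.
#' @param specs a `marker_spec` data frame; defaults to the nine-marker
#'   LR-M panel.
#' @return The validated data frame with class `cohort` and the specs
#'   attached as attribute `marker_specs`.
#' @export
cohort_table <- function(df, specs = default_marker_specs()) {
  df <- as.data.frame(df)
  required <- c("patient_id", "label", specs$name)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("cohort format error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!all(df$label %in% c(0, 1))) {
    stop("cohort validation error: label must take values in {0, 1}")
  }
  has_os <- "os_days" %in% names(df)
  has_event <- "event" %in% names(df)
  if (has_os != has_event) {
    stop("cohort format error: os_days and event must be present together")
  }
  if (has_os) {
    if (any(df$os_days < 0, na.rm = TRUE)) {
      stop("cohort validation error: os_days must be non-negative")
    }
    if (!all(df$event %in% c(0, 1, NA))) {
      stop("cohort validation error: event must be 0/1")
    }
  }
  for (k in seq_len(nrow(specs))) {
    nm <- specs$name[k]
    v <- df[[nm]]
    if (!is.numeric(v)) {
      stop("cohort format error: non-numeric marker column ", nm)
    }
    if (any(v < 0, na.rm = TRUE)) {
      stop("cohort validation error: negative value in marker ", nm)
    }
    if (!specs$allow_missing[k] && anyNA(v)) {
      stop("cohort validation error: missing entry in complete-by-design ",
           "marker ", nm)
    }
  }
  structure(df, class = c("cohort", "data.frame"), marker_specs = specs)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("LR-M cohort: %d patients (HCC %d / iCCA %d), %d markers%s\n",
              nrow(x), sum(x$label == 0), sum(x$label == 1),
              nrow(attr(x, "marker_specs")),
              if ("os_days" %in% names(x)) ", survival columns present" else ""))
  print(as.data.frame(utils::head(x, 6)))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Marker specs attached to a cohort
#' @param table a `cohort` object.
#' @return The `marker_spec` data frame.
#' @export
cohort_specs <- function(table) {
  specs <- attr(table, "marker_specs")
  if (is.null(specs)) specs <- default_marker_specs()
  specs
}

#' Marker matrix of a cohort in native units
#' @param table a `cohort` object.
#' @param markers optional subset of marker names (default: all).
#' @return Numeric matrix, patients x markers, rownames = patient ids.
#' @export
marker_matrix <- function(table, markers = cohort_specs(table)$name) {
  m <- as.matrix(as.data.frame(table)[, markers, drop = FALSE])
  rownames(m) <- table$patient_id
  storage.mode(m) <- "double"
  m
}

# row subset preserving class and specs
subset_cohort <- function(table, idx) {
  out <- as.data.frame(table)[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("cohort", "data.frame"),
            marker_specs = cohort_specs(table))
}

# replace marker columns from a matrix, preserving everything else
replace_markers <- function(table, m) {
  df <- as.data.frame(table)
  df[, colnames(m)] <- m
  structure(df, class = c("cohort", "data.frame"),
            marker_specs = cohort_specs(table))
}

#' Read a cohort CSV
#'
#' Expects a UTF-8 comma-separated file with a header row containing
#' `patient_id`, `label`, every marker named in `specs` and optionally
#' `os_days`/`event`. Empty cells become missing values; row order is
#' preserved. Unknown columns are a format error.
#'
#' @param path path to the CSV file.
#' @param specs `marker_spec` data frame (default: nine-marker panel).
#' @return A validated `cohort` object.
#' @export
read_cohort <- function(path, specs = default_marker_specs()) {
  if (!file.exists(path)) stop("cohort format error: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  allowed <- c("patient_id", "label", specs$name, "os_days", "event")
  unknown <- setdiff(names(df), allowed)
  if (length(unknown)) {
    stop("cohort format error: unknown column(s): ",
         paste(unknown, collapse = ", "))
  }
  cohort_table(df, specs)
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: comma-separated, header row, missing values
#' as empty cells, full double precision.
#'
#' @param table a `cohort` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  df <- as.data.frame(table)
  for (j in which(vapply(df, is.numeric, logical(1)))) {
    v <- df[[j]]
    df[[j]] <- ifelse(is.na(v), NA_character_, sprintf("%.17g", v))
  }
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}
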