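# Cohort CSV and JSON report serialization. The CSV schema is fixed:
# node_id, patient_id, swe_hardness_kpa, roundness_index,
# cortical_thickness_mm, indefinite_margins, hypoechogenicity,
# loss_fatty_hilum, peripheral_infiltration, peripheral_vascularization
# [, malignant]. Decimal point ".", no imputation: malformed rows are
# rejected with the row and column named.

#' Read a lymph-node cohort from CSV
#'
#' @param path Path to a cohort CSV with the canonical header.
#' @return Validated cohort data frame (with `malignant` when present).
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(cohort_columns(), names(df))
  if (length(missing_cols)) {
    stop("cohort CSV is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  num_cols <- setdiff(names(df), .id_cols)
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      stop("non-numeric value in column '", col, "' at row ",
           which(is.na(v))[1])
    }
    df[[col]] <- v
  }
  bin_cols <- intersect(c(.binary_cols, "malignant"), names(df))
  for (col in bin_cols) {
    bad <- which(!df[[col]] %in% c(0, 1))
    if (length(bad)) {
      stop("column '", col, "' must be 0/1; offending row ", bad[1],
           " has value ", df[[col]][bad[1]])
    }
  }
  validate_cohort(df)
  df
}

#' Write a cohort to CSV
#'
#' @param cohort Validated cohort.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Flatten a metrics_report's per-set entries into data-frame rows.
.report_rows <- function(model_name, sets) {
  do.call(rbind, lapply(names(sets), function(s) {
    m <- sets[[s]]
    data.frame(model = model_name, set = s,
               sensitivity = m$sensitivity, specificity = m$specificity,
               ppv = m$ppv, npv = m$npv, accuracy = m$accuracy,
               tp = m$tp, fp = m$fp, tn = m$tn, fn = m$fn)
  }))
}

#' Tabulate a study report's model accuracies
#'
#' One row per model and evaluation set with the five diagnostic rates and
#' the confusion counts, mirroring a published model-accuracy table.
#'
#' @param report A `study_report` from [run_full_study()].
#' @return Data frame.
#' @export
report_accuracy_table <- function(report) {
  stopifnot(inherits(report, "study_report"))
  rows <- do.call(rbind, lapply(report$models, function(m) .report_rows(m$model, m$sets)))
  if (!is.null(report$baselines)) {
    rows <- rbind(rows,
      .report_rows("naive_bayes", report$baselines$naive_bayes$sets),
      .report_rows("lda", list(original = report$baselines$lda$original,
                               cross_validated = report$baselines$lda$cross_validated)))
  }
  rownames(rows) <- NULL
  rows
}

#' Serialize a study report
#'
#' `format = "json"` writes a schema-versioned JSON document with the
#' feature screening table, per-model metrics, model specifications and
#' baseline results. `format = "csv"` writes the model-accuracy table with
#' rates printed to 3 decimals.
#'
#' @param report A `study_report`.
#' @param path Output path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "study_report"))
  if (format == "csv") {
    tab <- report_accuracy_table(report)
    rates <- c("sensitivity", "specificity", "ppv", "npv", "accuracy")
    tab[rates] <- lapply(tab[rates], function(v) sprintf("%.3f", v))
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  } else {
    spec_json <- lapply(report$specs, function(s) list(
      name = s$name,
      cuts = list(swe_cut = s$cuts$swe_cut, neg_ri_cut = s$cuts$neg_ri_cut,
                  ct_cut = s$cuts$ct_cut),
      weights = as.list(s$weights), score_cut = s$score_cut))
    doc <- list(
      schema_version = "1.0",
      n = report$n, seed = report$seed, policy = report$policy,
      feature_table = report$feature_table,
      model_specs = spec_json,
      accuracy = report_accuracy_table(report),
      tier1_fraction = report$models$two_tier$sets$whole$tier1_fraction)
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
  }
  invisible(path)
}
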