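#' @keywords internal
"_PACKAGE"

# Canonical cohort column layout. Continuous features carry clinical units
# (kPa, mm, dimensionless ratio); the five native binary features are 0/1.
.continuous_cols <- c("swe_hardness_kpa", "roundness_index", "cortical_thickness_mm")
.binary_cols <- c("indefinite_margins", "hypoechogenicity", "loss_fatty_hilum",
                  "peripheral_infiltration", "peripheral_vascularization")
.id_cols <- c("node_id", "patient_id")

# Order of the 8 analysis features as used throughout reports and matrices:
# larger = more suspicious for every feature (roundness enters as -RI).
.feature_order <- c("swe_hardness", "neg_roundness_index", "loss_fatty_hilum",
                    "indefinite_margins", "hypoechogenicity", "cortical_thickness",
                    "peripheral_infiltration", "peripheral_vascularization")

#' Column names of a lymph-node cohort
#'
#' @return Character vector of required cohort columns (the optional
#'   `malignant` histology label is not included).
#' @export
cohort_columns <- function() c(.id_cols, .continuous_cols, .binary_cols)

#' Validate a lymph-node cohort data frame
#'
#' Checks the per-node record invariants: positive continuous features
#' (shear-wave stiffness in kPa, roundness index, cortical thickness in mm),
#' strictly 0/1 binary features, and an optional 0/1 `malignant` label.
#'
#' @param cohort A data frame with the columns of [cohort_columns()], plus
#'   optionally `malignant`.
#' @param require_label If `TRUE`, a `malignant` column must be present.
#' @return The validated cohort, invisibly usable downstream.
#' @export
validate_cohort <- function(cohort, require_label = FALSE) {
  stopifnot(is.data.frame(cohort))
  missing_cols <- setdiff(cohort_columns(), names(cohort))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (require_label && !"malignant" %in% names(cohort)) {
    stop("cohort has no 'malignant' label column, required for this operation")
  }
  for (col in .continuous_cols) {
    v <- cohort[[col]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
      stop("column '", col, "' must be finite numeric with no missing values")
    }
    if (any(v <= 0)) stop("column '", col, "' must be strictly positive")
  }
  label_cols <- intersect(c(.binary_cols, "malignant"), names(cohort))
  for (col in label_cols) {
    v <- cohort[[col]]
    if (anyNA(v) || !all(v %in% c(0, 1))) {
      bad <- which(is.na(v) | !(v %in% c(0, 1)))
      stop("column '", col, "' must be exactly 0 or 1 (first bad row: ", bad[1], ")")
    }
  }
  invisible(cohort)
}

#' Continuous-feature cut-off set
#'
#' Bundles the three binarization cut-offs of an LNMS model: stiffness in kPa,
#' the cut applied to the negative roundness index (so that larger = more
#' suspicious), and cortical thickness in mm.
#'
#' @param swe_cut Stiffness cut-off, kPa (> 0).
#' @param neg_ri_cut Cut-off on the negated roundness index (< 0).
#' @param ct_cut Cortical-thickness cut-off, mm (> 0).
#' @return An object of class `cutoff_set`.
#' @examples
#' cutoff_set(142, -1.55, 3.5)  # Model A defaults
#' @export
cutoff_set <- function(swe_cut, neg_ri_cut, ct_cut) {
  vals <- c(swe_cut = swe_cut, neg_ri_cut = neg_ri_cut, ct_cut = ct_cut)
  if (any(!is.finite(vals))) stop("all cut-offs must be finite")
  if (swe_cut <= 0) stop("swe_cut must be positive (kPa)")
  if (ct_cut <= 0) stop("ct_cut must be positive (mm)")
  if (neg_ri_cut >= 0) stop("neg_ri_cut applies to -roundness_index and must be negative")
  structure(list(swe_cut = swe_cut, neg_ri_cut = neg_ri_cut, ct_cut = ct_cut),
            class = "cutoff_set")
}

#' @export
print.cutoff_set <- function(x, ...) {
  cat(sprintf("Cut-off set: SWEH > %g kPa, -RI > %g, CT > %g mm\n",
              x$swe_cut, x$neg_ri_cut, x$ct_cut))
  invisible(x)
}

#' Binarize a continuous feature at a cut-off
#'
#' Strict-inequality dichotomization: suspicious (1) iff `value > cut`.
#' Ties fall on the non-suspicious side; published cut-offs sit at
#' half-steps between achievable values, so ties cannot occur in practice.
#'
#' @param value Numeric vector of feature values.
#' @param cut Single finite cut-off.
#' @return Integer 0/1 vector.
#' @export
binarize_feature <- function(value, cut) {
  if (length(cut) != 1L || !is.finite(cut)) stop("cut must be a single finite number")
  if (anyNA(value) || any(!is.finite(value))) stop("value must be finite")
  as.integer(value > cut)
}

#' Binarize a cohort's features into the 8 score inputs
#'
#' Applies the cut-off set to the three continuous features and passes the
#' five native binary features through unchanged. The roundness index is
#' negated before comparison so that, as for every other feature, larger
#' means more suspicious.
#'
#' @param cohort A validated cohort data frame (one or more rows).
#' @param cuts A [cutoff_set()].
#' @return A data frame with columns `b_sweh`, `b_ri`, `lfh`, `um`, `hy`,
#'   `b_ct`, `pi`, `pv`, each 0/1, one row per node.
#' @export
binarize_cohort <- function(cohort, cuts) {
  validate_cohort(cohort)
  stopifnot(inherits(cuts, "cutoff_set"))
  data.frame(
    b_sweh = binarize_feature(cohort$swe_hardness_kpa, cuts$swe_cut),
    b_ri   = binarize_feature(-cohort$roundness_index, cuts$neg_ri_cut),
    lfh    = as.integer(cohort$loss_fatty_hilum),
    um     = as.integer(cohort$indefinite_margins),
    hy     = as.integer(cohort$hypoechogenicity),
    b_ct   = binarize_feature(cohort$cortical_thickness_mm, cuts$ct_cut),
    pi     = as.integer(cohort$peripheral_infiltration),
    pv     = as.integer(cohort$peripheral_vascularization)
  )
}

# Feature matrix in the canonical 8-feature order (columns named by
# .feature_order), used by the correlation and discriminant machinery.
feature_matrix <- function(cohort) {
  validate_cohort(cohort)
  m <- cbind(
    swe_hardness = cohort$swe_hardness_kpa,
    neg_roundness_index = -cohort$roundness_index,
    loss_fatty_hilum = cohort$loss_fatty_hilum,
    indefinite_margins = cohort$indefinite_margins,
    hypoechogenicity = cohort$hypoechogenicity,
    cortical_thickness = cohort$cortical_thickness_mm,
    peripheral_infiltration = cohort$peripheral_infiltration,
    peripheral_vascularization = cohort$peripheral_vascularization
  )
  m
}
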