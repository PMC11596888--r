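# LNMS weights. Models A and B share the weight pattern (stiffness and
# roundness carry weight 2); Model C drops stiffness so the score works on
# ultrasound machines without shear-wave elastography. Peripheral
# infiltration and vascularization are never part of any score.
.lnms_weights <- list(
  A = c(b_sweh = 2, b_ri = 2, lfh = 1, um = 1, hy = 1, b_ct = 1),
  B = c(b_sweh = 2, b_ri = 2, lfh = 1, um = 1, hy = 1, b_ct = 1),
  C = c(b_ri = 2, lfh = 1, um = 1, hy = 1, b_ct = 1)
)

# Published defaults: cut-off sets and score cut-offs per model.
.default_cuts <- list(
  A = list(cuts = c(142, -1.55, 3.50), score_cut = 3.50),
  B = list(cuts = c(137, -2.25, 3.50), score_cut = 4.50),
  C = list(cuts = c(137, -2.25, 3.50), score_cut = 2.50)
)

#' Specify an LNMS scoring model
#'
#' An LNMS (Lymph Node Malignity Score) model is a weighted integer sum of
#' binarized ultrasound/elastography features. Models A and B use weights
#' 2/2/1/1/1/1 on (binarized stiffness, binarized roundness, loss of fatty
#' hilum, indefinite margins, hypoechogenicity, binarized cortical
#' thickness); Model C omits stiffness. The two-tier Cassandra rule wraps
#' Model B. Calling `model_spec("A")` etc. with no further arguments yields
#' the published calibration.
#'
#' @param name One of `"A"`, `"B"`, `"C"`, `"two_tier"`.
#' @param cuts Optional [cutoff_set()]; defaults to the model's published
#'   cut-offs (two_tier uses Model B's).
#' @param score_cut Optional half-integer score cut-off; defaults to the
#'   published value (3.50, 4.50, 2.50 for A, B, C).
#' @param tier1_ri_cut For `two_tier` only: the roundness cut (on -RI) used
#'   in the first tier. Defaults to Model B's -2.25; set to -1.55 to use the
#'   stricter roundness variant.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(name = c("A", "B", "C", "two_tier"),
                       cuts = NULL, score_cut = NULL, tier1_ri_cut = NULL) {
  name <- match.arg(name)
  base <- if (name == "two_tier") "B" else name
  if (is.null(cuts)) {
    d <- .default_cuts[[base]]$cuts
    cuts <- cutoff_set(d[1], d[2], d[3])
  }
  stopifnot(inherits(cuts, "cutoff_set"))
  if (is.null(score_cut)) score_cut <- .default_cuts[[base]]$score_cut
  if (!is.finite(score_cut)) stop("score_cut must be finite")
  w <- .lnms_weights[[base]]
  if (name == "two_tier" && is.null(tier1_ri_cut)) tier1_ri_cut <- cuts$neg_ri_cut
  structure(list(name = name, cuts = cuts, weights = w,
                 included_features = names(w),
                 score_cut = score_cut, max_score = sum(w),
                 tier1_ri_cut = tier1_ri_cut),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("LNMS model %s: score = %s; score cut-off %g (max %d)\n",
              x$name,
              paste(sprintf("%d*%s", x$weights, names(x$weights)), collapse = " + "),
              x$score_cut, x$max_score))
  print(x$cuts)
  invisible(x)
}

#' Compute the LNMS integer score
#'
#' Weighted integer sum of the model's included binary features.
#'
#' @param bin A data frame from [binarize_cohort()] (or any data frame with
#'   the model's included 0/1 columns).
#' @param spec A [model_spec()] for model A, B, or C.
#' @return Integer vector of scores, one per row, in `[0, max_score]`.
#' @export
compute_lnms <- function(bin, spec) {
  stopifnot(inherits(spec, "model_spec"))
  base <- if (spec$name == "two_tier") "B" else spec$name
  w <- spec$weights
  missing_cols <- setdiff(names(w), names(bin))
  if (length(missing_cols)) stop("binary input lacks column(s): ",
                                 paste(missing_cols, collapse = ", "))
  m <- as.matrix(bin[, names(w), drop = FALSE])
  if (anyNA(m) || !all(m %in% c(0, 1))) stop("binary features must be 0/1")
  as.integer(m %*% w)
}

#' Classify an integer score against its cut-off
#'
#' @param score Integer score vector.
#' @param score_cut Half-integer cut-off; malignant (1) iff `score > score_cut`.
#' @return Integer 0/1 predictions.
#' @export
classify_score <- function(score, score_cut) {
  stopifnot(length(score_cut) == 1L, is.finite(score_cut))
  as.integer(score > score_cut)
}

#' Score a cohort with an LNMS model
#'
#' Convenience wrapper: binarize, score, classify.
#'
#' @param cohort Validated cohort.
#' @param spec A [model_spec()] for A, B, or C (for the two-tier rule use
#'   [cassandra_two_tier()]).
#' @return Data frame `node_id`, `model`, `score`, `predicted_malignant`.
#' @export
score_cohort <- function(cohort, spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$name == "two_tier") return(cassandra_two_tier(cohort, spec))
  bin <- binarize_cohort(cohort, spec$cuts)
  s <- compute_lnms(bin, spec)
  data.frame(node_id = cohort$node_id, model = spec$name, score = s,
             predicted_malignant = classify_score(s, spec$score_cut))
}

#' Apply the two-tier Cassandra decision rule
#'
#' Tier 1 inspects only the two strongest predictors under Model B cut-offs:
#' binarized stiffness and binarized roundness. If both are suspicious the
#' node is called malignant outright; if both are non-suspicious it is
#' called benign. Only mixed nodes enter tier 2, where the full Model B
#' score and its cut-off decide. The would-be Model B score is recorded for
#' every node, including tier-1 calls, for audit reporting.
#'
#' @param cohort Validated cohort.
#' @param spec_b A Model B (or `two_tier`) [model_spec()].
#' @return Data frame `node_id`, `model`, `score` (LNMS under Model B),
#'   `tier` (1 or 2), `predicted_malignant`.
#' @export
cassandra_two_tier <- function(cohort, spec_b = model_spec("two_tier")) {
  stopifnot(inherits(spec_b, "model_spec"))
  if (!spec_b$name %in% c("B", "two_tier")) {
    stop("the two-tier rule is defined on Model B cut-offs")
  }
  tier1_ri_cut <- spec_b$tier1_ri_cut
  if (is.null(tier1_ri_cut)) tier1_ri_cut <- spec_b$cuts$neg_ri_cut
  bin <- binarize_cohort(cohort, spec_b$cuts)
  b_ri_tier1 <- binarize_feature(-cohort$roundness_index, tier1_ri_cut)
  s <- compute_lnms(bin, spec_b)
  both_pos <- bin$b_sweh == 1L & b_ri_tier1 == 1L
  both_neg <- bin$b_sweh == 0L & b_ri_tier1 == 0L
  tier <- ifelse(both_pos | both_neg, 1L, 2L)
  pred <- ifelse(both_pos, 1L,
          ifelse(both_neg, 0L, classify_score(s, spec_b$score_cut)))
  data.frame(node_id = cohort$node_id, model = "two_tier", score = s,
             tier = tier, predicted_malignant = as.integer(pred))
}

# All 2^6 binary feature vectors over the LNMS inputs (pi/pv held at 0);
# exported for exhaustive enumeration checks of the score algebra.

#' Enumerate all binary score inputs
#'
#' Every combination of the six LNMS input features (the two derived
#' binaries and four native ones; peripheral infiltration/vascularization,
#' which never enter a score, fixed at 0).
#'
#' @return A 64-row data frame with columns `b_sweh`, `b_ri`, `lfh`, `um`,
#'   `hy`, `b_ct`, `pi`, `pv`.
#' @export
enumerate_binary_inputs <- function() {
  g <- expand.grid(b_sweh = 0:1, b_ri = 0:1, lfh = 0:1, um = 0:1,
                   hy = 0:1, b_ct = 0:1)
  g$pi <- 0L
  g$pv <- 0L
  g
}
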