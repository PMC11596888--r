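# End-to-end study pipeline: stratified 50/50 split, per-feature training
# ROC screening, cut-off calibration per policy, model evaluation on
# training / validation / whole sample, baseline classifiers, and the
# combined study report.

#' Split a cohort into training and validation sets
#'
#' Deterministic seeded split, stratified by the malignancy label by
#' default so both halves carry the cohort's prevalence.
#'
#' @param cohort Labelled cohort with at least 4 records and both classes.
#' @param fraction_training Fraction assigned to training (default 0.5).
#' @param stratified Stratify by label (default `TRUE`).
#' @param seed Integer seed.
#' @return List `training`, `validation` (disjoint, exhaustive).
#' @export
split_cohort <- function(cohort, fraction_training = 0.5, stratified = TRUE,
                         seed = 1) {
  validate_cohort(cohort, require_label = TRUE)
  if (fraction_training <= 0 || fraction_training >= 1) {
    stop("fraction_training must lie strictly between 0 and 1")
  }
  n <- nrow(cohort)
  if (n < 4 || length(unique(cohort$malignant)) < 2) {
    stop("need at least 4 records with both classes")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  idx <- if (stratified) {
    unlist(lapply(c(0, 1), function(cls) {
      rows <- which(cohort$malignant == cls)
      sample(rows, round(length(rows) * fraction_training))
    }))
  } else {
    sample(seq_len(n), round(n * fraction_training))
  }
  training <- cohort[sort(idx), , drop = FALSE]
  validation <- cohort[setdiff(seq_len(n), idx), , drop = FALSE]
  if (length(unique(training$malignant)) < 2 || length(unique(validation$malignant)) < 2) {
    stop("a class is absent from one half after the split; cohort too small")
  }
  list(training = training, validation = validation)
}

#' Per-feature training ROC screening table
#'
#' One ROC summary per feature on the training set (roundness as -RI):
#' AUC, Hanley-McNeil SE, the p-value of AUC = 0.5, Gini, max K-S with its
#' cut-off, plus the tie-corrected Mann-Whitney z and its Bonferroni
#' significance flag at alpha = 0.006. Features whose AUC p-value is below
#' `screen_alpha` (default 0.001) are marked `retained`.
#'
#' @param training Labelled training cohort.
#' @param screen_alpha ROC screening level (default 0.001).
#' @param bonferroni_alpha Mann-Whitney significance level (default 0.006).
#' @return Data frame, one row per feature.
#' @export
feature_roc_table <- function(training, screen_alpha = 0.001,
                              bonferroni_alpha = 0.006) {
  validate_cohort(training, require_label = TRUE)
  m <- feature_matrix(training)
  g <- training$malignant
  rows <- lapply(colnames(m), function(f) {
    roc <- roc_summary(m[, f], g)
    mw <- mann_whitney_z(m[g == 0, f], m[g == 1, f])
    data.frame(feature = f, auc = roc$auc, se = roc$se_auc,
               gini = roc$gini, max_ks = roc$max_ks, cutoff = roc$ks_cut,
               p_roc = roc$p_value, mw_z = mw$z, p_mw = mw$p,
               significant = mw$p < bonferroni_alpha,
               retained = roc$p_value < screen_alpha)
  })
  do.call(rbind, rows)
}

#' Calibrate an LNMS model's cut-offs on a training set
#'
#' Continuous cut-offs per policy: `"fixed"` uses the published values;
#' `"youden"` maximizes Youden's J per feature; `"min_sens"` takes the
#' largest cut keeping per-feature sensitivity at or above `min_sens`
#' (0.95), the policy that minimizes false negatives. Stiffness cuts are
#' floored to whole kPa. The score cut-off is then set where the training
#' score's K-S statistic peaks. Peripheral infiltration and vascularization
#' never enter the score.
#'
#' @param training Labelled training cohort.
#' @param policy `"fixed"`, `"youden"`, or `"min_sens"`.
#' @param model `"A"`, `"B"`, `"C"`, or `"two_tier"`.
#' @param min_sens Sensitivity floor for `"min_sens"` (default 0.95).
#' @return A calibrated [model_spec()].
#' @export
calibrate_model <- function(training, policy = c("fixed", "youden", "min_sens"),
                            model = c("A", "B", "C", "two_tier"),
                            min_sens = 0.95) {
  policy <- match.arg(policy)
  model <- match.arg(model)
  if (policy == "fixed") return(model_spec(model))
  validate_cohort(training, require_label = TRUE)
  g <- training$malignant
  pick <- function(values, round_int = FALSE) {
    if (policy == "youden") youden_cutoff(values, g, round_cut_to_int = round_int)
    else sens_constrained_cutoff(values, g, min_sens = min_sens,
                                 round_cut_to_int = round_int)
  }
  cuts <- cutoff_set(
    swe_cut = pick(training$swe_hardness_kpa, round_int = TRUE),
    neg_ri_cut = pick(-training$roundness_index),
    ct_cut = pick(training$cortical_thickness_mm)
  )
  spec <- model_spec(model, cuts = cuts, score_cut = 0.5)
  base <- if (model == "two_tier") "B" else model
  scores <- compute_lnms(binarize_cohort(training, cuts), model_spec(base, cuts = cuts, score_cut = 0.5))
  roc <- roc_summary(scores, g)
  model_spec(model, cuts = cuts, score_cut = roc$ks_cut)
}

#' Evaluate a calibrated model on training, validation and whole sample
#'
#' @param spec A [model_spec()].
#' @param training,validation Labelled cohorts.
#' @return Object of class `metrics_report`: per-set confusion metrics, the
#'   training-score ROC summary, and (two-tier only) per-set tier-1
#'   fractions.
#' @export
evaluate_model <- function(spec, training, validation) {
  stopifnot(inherits(spec, "model_spec"))
  whole <- rbind(training, validation)
  sets <- list(training = training, validation = validation, whole = whole)
  scored <- lapply(sets, score_cohort, spec = spec)
  per_set <- lapply(names(sets), function(s) {
    cm <- confusion_metrics(scored[[s]]$predicted_malignant, sets[[s]]$malignant)
    if (spec$name == "two_tier") cm$tier1_fraction <- mean(scored[[s]]$tier == 1L)
    cm
  })
  names(per_set) <- names(sets)
  structure(list(model = spec$name, sets = per_set,
                 training_roc = roc_summary(scored$training$score,
                                            training$malignant)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Model", x$model, "\n")
  for (s in names(x$sets)) {
    m <- x$sets[[s]]
    cat(sprintf("  %-10s sens %.3f  spec %.3f  ppv %.3f  npv %.3f  acc %.3f\n",
                s, m$sensitivity, m$specificity, m$ppv, m$npv, m$accuracy))
  }
  invisible(x)
}

#' Run the full scoring study on a cohort
#'
#' The complete analysis: stratified 50/50 split; per-feature training ROC
#' and Mann-Whitney screening; calibration of Models A (Youden policy),
#' B and C (sensitivity-constrained policy) and the two-tier rule, or the
#' published fixed cut-offs; evaluation of each on training, validation and
#' the whole sample; naive Bayes (trained on the training half, greedy
#' selection) and LDA (whole sample plus leave-one-out) baselines.
#'
#' @param cohort Labelled cohort.
#' @param policy Cut-off policy for A ( `"youden"` when `"derive"`), or
#'   `"fixed"` for the published cut-offs everywhere.
#' @param seed Seed driving the split.
#' @param fraction_training Training fraction (default 0.5).
#' @param run_baselines Include naive Bayes / LDA baselines (default TRUE).
#' @return Object of class `study_report`.
#' @export
run_full_study <- function(cohort, policy = c("fixed", "derive"), seed = 1,
                           fraction_training = 0.5, run_baselines = TRUE) {
  policy <- match.arg(policy)
  validate_cohort(cohort, require_label = TRUE)
  halves <- split_cohort(cohort, fraction_training, stratified = TRUE, seed = seed)
  tr <- halves$training; va <- halves$validation
  feat_table <- feature_roc_table(tr)

  specs <- if (policy == "fixed") {
    list(A = model_spec("A"), B = model_spec("B"), C = model_spec("C"),
         two_tier = model_spec("two_tier"))
  } else {
    list(A = calibrate_model(tr, "youden", "A"),
         B = calibrate_model(tr, "min_sens", "B"),
         C = calibrate_model(tr, "min_sens", "C"),
         two_tier = calibrate_model(tr, "min_sens", "two_tier"))
  }
  models <- lapply(specs, evaluate_model, training = tr, validation = va)

  baselines <- NULL
  if (run_baselines) {
    rank_order <- feat_table$feature[order(-feat_table$auc)]
    nb <- fit_naive_bayes(tr, features = rank_order, selection = "greedy")
    nb_sets <- list(training = tr, validation = va, whole = cohort)
    nb_metrics <- lapply(nb_sets, function(s)
      confusion_metrics(stats::predict(nb, s), s$malignant))
    lda_fit <- fit_lda(cohort)
    lda_orig <- confusion_metrics(stats::predict(lda_fit, cohort), cohort$malignant)
    lda_loo <- loo_cv(fit_lda, cohort)
    baselines <- list(
      naive_bayes = list(fit = nb, sets = nb_metrics),
      lda = list(fit = lda_fit, original = lda_orig,
                 cross_validated = lda_loo$metrics))
  }
  structure(list(seed = seed, policy = policy,
                 n = nrow(cohort),
                 feature_table = feat_table,
                 specs = specs, models = models,
                 baselines = baselines),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Cassandra study: n = %d, policy = %s, split seed = %d\n\n",
              x$n, x$policy, x$seed))
  cat("Per-feature training ROC:\n")
  tab <- x$feature_table
  tab[, sapply(tab, is.numeric)] <- round(tab[, sapply(tab, is.numeric)], 3)
  print(tab, row.names = FALSE)
  cat("\n")
  for (m in x$models) print(m)
  if (!is.null(x$baselines)) {
    nb <- x$baselines$naive_bayes
    cat(sprintf("Naive Bayes (selected: %s)\n", paste(nb$fit$selected, collapse = ", ")))
    for (s in names(nb$sets)) {
      cm <- nb$sets[[s]]
      cat(sprintf("  %-10s sens %.3f  spec %.3f  acc %.3f\n",
                  s, cm$sensitivity, cm$specificity, cm$accuracy))
    }
    lda <- x$baselines$lda
    cat(sprintf("LDA (canonical correlation %.3f)\n  original   acc %.3f\n  LOO-CV     acc %.3f\n",
                lda$fit$canonical_correlation, lda$original$accuracy,
                lda$cross_validated$accuracy))
  }
  invisible(x)
}
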