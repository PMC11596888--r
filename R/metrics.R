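#' Confusion-matrix diagnostic metrics
#'
#' Sensitivity, specificity, PPV, NPV, and overall accuracy from paired 0/1
#' predictions and labels. A rate whose denominator is empty (e.g. PPV with
#' no positive calls) is reported as `NA`, never as 0/0.
#'
#' @param pred,label Equal-length 0/1 vectors.
#' @return List with `tp`, `fp`, `tn`, `fn` and the five rates.
#' @export
confusion_metrics <- function(pred, label) {
  if (length(pred) != length(label)) stop("pred and label lengths differ")
  if (length(pred) == 0L) stop("empty input")
  if (!all(pred %in% c(0, 1)) || !all(label %in% c(0, 1))) {
    stop("pred and label must be 0/1")
  }
  tp <- sum(pred == 1 & label == 1)
  fp <- sum(pred == 1 & label == 0)
  tn <- sum(pred == 0 & label == 0)
  fn <- sum(pred == 0 & label == 1)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = rate(tp, tp + fn),
       specificity = rate(tn, tn + fp),
       ppv = rate(tp, tp + fp),
       npv = rate(tn, tn + fn),
       accuracy = (tp + tn) / length(pred))
}

# Empirical ROC with ties grouped: thresholds are midpoints between adjacent
# distinct score values, plus sentinels below/above the range. Positive call
# iff score > threshold.
.roc_points <- function(score, label) {
  v <- sort(unique(score))
  thr <- c(v[1] - 1, if (length(v) > 1) (v[-length(v)] + v[-1]) / 2, v[length(v)] + 1)
  n1 <- sum(label == 1)
  n0 <- sum(label == 0)
  tpr <- vapply(thr, function(t) sum(score > t & label == 1) / n1, 0)
  fpr <- vapply(thr, function(t) sum(score > t & label == 0) / n0, 0)
  list(thresholds = thr, tpr = tpr, fpr = fpr)
}

#' ROC summary of a score against a binary label
#'
#' AUC via the tie-aware rank (Mann-Whitney) formulation, equal to the
#' probability that a random malignant node outscores a random benign one
#' (ties counted half). The standard error is Hanley-McNeil; the p-value
#' tests AUC = 0.5 with a normal approximation on that SE. Gini = 2*AUC - 1;
#' the maximum Kolmogorov-Smirnov statistic is the largest TPR - FPR over
#' thresholds, reported with its threshold (midpoint between adjacent
#' achievable values, hence half-integers for integer scores).
#'
#' @param score Numeric score vector (larger = more suspicious).
#' @param label 0/1 labels; both classes must be present.
#' @return Object of class `roc_summary`: `thresholds`, `tpr`, `fpr`,
#'   `auc`, `se_auc`, `p_value`, `gini`, `max_ks`, `ks_cut`, `n1`, `n0`.
#' @export
roc_summary <- function(score, label) {
  if (length(score) != length(label)) stop("score and label lengths differ")
  if (!all(label %in% c(0, 1))) stop("label must be 0/1")
  n1 <- sum(label == 1)
  n0 <- sum(label == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute a ROC curve")
  r <- rank(score)                       # midranks
  auc <- (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  se <- hanley_mcneil_se(auc, n1, n0)
  p <- 2 * stats::pnorm(-abs(auc - 0.5) / se)
  pts <- .roc_points(score, label)
  ks <- pts$tpr - pts$fpr
  i <- which.max(ks)
  structure(list(thresholds = pts$thresholds, tpr = pts$tpr, fpr = pts$fpr,
                 auc = auc, se_auc = se, p_value = p,
                 gini = gini_index(auc),
                 max_ks = ks[i], ks_cut = pts$thresholds[i],
                 n1 = n1, n0 = n0),
            class = "roc_summary")
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf("AUC %.3f (SE %.3f, p = %.3g); Gini %.3f; max K-S %.3f at cut-off %.2f\n",
              x$auc, x$se_auc, x$p_value, x$gini, x$max_ks, x$ks_cut))
  invisible(x)
}

# Hanley & McNeil (1982) standard error of a nonparametric AUC.
hanley_mcneil_se <- function(auc, n1, n0) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) + (n0 - 1) * (q2 - auc^2)) /
         (n1 * n0))
}

#' Gini index of an AUC
#'
#' The linear rescaling `2 * auc - 1` of the ROC area.
#'
#' @param auc AUC in `[0, 1]`.
#' @return Gini index in `[-1, 1]`.
#' @export
gini_index <- function(auc) {
  stopifnot(all(auc >= 0 & auc <= 1))
  2 * auc - 1
}

#' Maximum Kolmogorov-Smirnov statistic of a ROC
#'
#' @param roc A [roc_summary()].
#' @return List `ks` (max TPR - FPR) and `cut` (its threshold).
#' @export
max_ks <- function(roc) {
  stopifnot(inherits(roc, "roc_summary"))
  list(ks = roc$max_ks, cut = roc$ks_cut)
}

# Shared threshold scan: sens/spec at every candidate cut (call = value > cut).
.cut_candidates <- function(values, label) {
  v <- sort(unique(values))
  thr <- c(v[1] - 1, if (length(v) > 1) (v[-length(v)] + v[-1]) / 2)
  n1 <- sum(label == 1)
  n0 <- sum(label == 0)
  sens <- vapply(thr, function(t) sum(values > t & label == 1) / n1, 0)
  spec <- vapply(thr, function(t) sum(values <= t & label == 0) / n0, 0)
  list(thr = thr, sens = sens, spec = spec)
}

#' Youden-optimal cut-off
#'
#' The threshold maximizing Youden's J = sensitivity + specificity - 1, with
#' a positive call for values strictly above the cut. The cut is reported as
#' the midpoint between the adjacent observed values. Ties in J are broken
#' toward higher sensitivity, then toward the lower cut (both favor fewer
#' false negatives).
#'
#' @param values Numeric feature values (larger = more suspicious).
#' @param label 0/1 labels; both classes required.
#' @param round_cut_to_int Floor the chosen cut to the integer below, for
#'   integer-valued measurements reported as whole numbers.
#' @return The selected cut-off (numeric scalar).
#' @export
youden_cutoff <- function(values, label, round_cut_to_int = FALSE) {
  if (!all(label %in% c(0, 1)) || sum(label == 1) == 0 || sum(label == 0) == 0) {
    stop("both classes must be present")
  }
  cc <- .cut_candidates(values, label)
  j <- cc$sens + cc$spec - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[order(-cc$sens[best], cc$thr[best])][1]
  cut <- cc$thr[best]
  if (round_cut_to_int) cut <- floor(cut)
  cut
}

#' Sensitivity-constrained cut-off
#'
#' The largest cut whose training sensitivity is at least `min_sens`,
#' i.e. maximal specificity subject to a sensitivity floor. Used to push a
#' score toward a minimal false-negative rate. With `min_sens = 1` the cut
#' falls below the smallest malignant value.
#'
#' @inheritParams youden_cutoff
#' @param min_sens Sensitivity floor in (0, 1].
#' @return The selected cut-off.
#' @export
sens_constrained_cutoff <- function(values, label, min_sens = 0.95,
                                    round_cut_to_int = FALSE) {
  if (!all(label %in% c(0, 1)) || sum(label == 1) == 0 || sum(label == 0) == 0) {
    stop("both classes must be present")
  }
  if (min_sens <= 0 || min_sens > 1) stop("min_sens must be in (0, 1]")
  cc <- .cut_candidates(values, label)
  ok <- cc$sens >= min_sens - 1e-12
  cut <- max(cc$thr[ok])   # lowest cut (sens = 1) always qualifies
  if (round_cut_to_int) cut <- floor(cut)
  cut
}

#' Tie-corrected Mann-Whitney U test
#'
#' U statistic with midrank ties, z by the normal approximation with the
#' tie-corrected variance, and a two-sided p-value. No continuity
#' correction; `u` counts pairs in which the second (malignant) group
#' exceeds the first, so `u / (n0 * n1)` equals the AUC of the pooled values
#' against group membership.
#'
#' @param x_benign,x_malignant Non-empty numeric vectors.
#' @return List `u`, `z`, `p`.
#' @export
mann_whitney_z <- function(x_benign, x_malignant) {
  n0 <- length(x_benign)
  n1 <- length(x_malignant)
  if (n0 == 0 || n1 == 0) stop("both groups must be non-empty")
  pooled <- c(x_benign, x_malignant)
  n <- n0 + n1
  r <- rank(pooled)
  u <- sum(r[(n0 + 1):n]) - n1 * (n1 + 1) / 2
  mu <- n0 * n1 / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  v <- n0 * n1 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (v <= 0) return(list(u = u, z = 0, p = 1))   # all values identical
  z <- (u - mu) / sqrt(v)
  list(u = u, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Spearman correlation matrix of cohort features
#'
#' Midrank Spearman correlations among the 8 analysis features (roundness as
#' -RI) and, when labelled, each feature against malignancy, with asymptotic
#' two-sided p-values from the t approximation. A constant column yields
#' `NA` correlations (flagged missing, not zero).
#'
#' @param cohort Validated cohort (>= 3 rows).
#' @return List `r` (correlation matrix) and `p` (p-value matrix).
#' @export
spearman_matrix <- function(cohort) {
  m <- feature_matrix(cohort)
  if ("malignant" %in% names(cohort)) m <- cbind(m, malignant = cohort$malignant)
  n <- nrow(m)
  if (n < 3) stop("need at least 3 records")
  rk <- apply(m, 2, rank)
  sds <- apply(rk, 2, stats::sd)
  r <- suppressWarnings(stats::cor(rk))
  r[sds == 0, ] <- NA
  r[, sds == 0] <- NA
  diag(r) <- ifelse(sds == 0, NA, 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-15))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- NA
  list(r = r, p = p)
}

#' Pooled within-groups correlation matrix
#'
#' Pearson correlations of the data centered within each outcome group with
#' deviations pooled across groups — the matrix a linear discriminant
#' analysis pools, equivalently partial correlations controlling for
#' malignancy. Removes the between-group signal, exposing residual feature
#' associations.
#'
#' @param cohort Validated, labelled cohort with >= 3 records per group.
#' @return Correlation matrix over the 8 features; entries involving a
#'   within-group-constant feature are `NA`.
#' @export
pooled_within_groups_corr <- function(cohort) {
  validate_cohort(cohort, require_label = TRUE)
  m <- feature_matrix(cohort)
  g <- cohort$malignant
  if (sum(g == 0) < 3 || sum(g == 1) < 3) stop("each group needs at least 3 records")
  cv <- pooled_within_cov(m, g)
  s <- sqrt(diag(cv))
  r <- cv / tcrossprod(s)
  r[!is.finite(r)] <- NA
  diag(r) <- ifelse(s > 0, 1, NA)
  r
}

# Pooled within-group covariance with divisor n - #groups (the LDA pooling).
pooled_within_cov <- function(m, g) {
  groups <- unique(g)
  dev <- m
  for (gr in groups) {
    idx <- g == gr
    dev[idx, ] <- sweep(m[idx, , drop = FALSE], 2, colMeans(m[idx, , drop = FALSE]))
  }
  crossprod(dev) / (nrow(m) - length(groups))
}
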