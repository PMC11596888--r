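test_that("confusion metrics match hand-computed contingencies", {
  pred <- c(rep(1, 3), rep(0, 1), rep(1, 2), rep(0, 4))
  label <- c(rep(1, 4), rep(0, 6))   # TP 3, FN 1, FP 2, TN 4
  m <- confusion_metrics(pred, label)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 2 / 3)
  expect_equal(m$ppv, 0.6)
  expect_equal(m$npv, 0.8)
  expect_equal(m$accuracy, 0.7)

  perfect <- confusion_metrics(label, label)
  expect_true(all(unlist(perfect[c("sensitivity", "specificity", "ppv", "npv",
                                   "accuracy")]) == 1))
  inverted <- confusion_metrics(1 - label, label)
  expect_equal(inverted$sensitivity, 0)
  expect_equal(inverted$specificity, 0)

  no_calls <- confusion_metrics(rep(0, 4), c(0, 0, 1, 1))
  expect_true(is.na(no_calls$ppv))   # flagged missing, never 0/0
  expect_error(confusion_metrics(1, c(0, 1)), "length")
  expect_error(confusion_metrics(integer(0), integer(0)), "empty")
})

test_that("rank-based AUC equals the all-pairs oracle", {
  expect_equal(roc_summary(c(1, 2, 8, 9), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_summary(rep(3, 10), rep(0:1, 5))$auc, 0.5)

  # hand-listed pairs with ties
  score <- c(1, 2, 2, 3, 3, 3, 4, 5, 5, 6)
  label <- c(0, 0, 1, 0, 1, 1, 0, 1, 0, 1)
  expect_equal(roc_summary(score, label)$auc, auc_all_pairs(score, label))

  set.seed(99)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    label <- c(0, 1, rbinom(n - 2, 1, 0.5))
    score <- sample(1:6, n, replace = TRUE)   # heavy ties
    expect_equal(roc_summary(score, label)$auc, auc_all_pairs(score, label),
                 tolerance = 1e-12)
  }
  expect_error(roc_summary(1:5, rep(1, 5)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(7)
  score <- round(rnorm(80), 1)
  label <- rbinom(80, 1, plogis(score))
  if (length(unique(label)) < 2) label[1:2] <- 0:1
  ours <- roc_summary(score, label)
  theirs <- pROC::auc(pROC::roc(label, score, quiet = TRUE, direction = "<"))
  expect_equal(ours$auc, as.numeric(theirs), tolerance = 1e-12)
})

test_that("Gini is the linear transform of AUC", {
  expect_equal(gini_index(0.978), 0.956)
  expect_equal(gini_index(0.5), 0)
  expect_equal(gini_index(1), 1)
  set.seed(12)
  score <- rnorm(40); label <- rep(0:1, 20)
  r <- roc_summary(score, label)
  expect_identical(r$gini, gini_index(r$auc))
})

test_that("max K-S equals Youden's J at the Youden-optimal cut", {
  r <- roc_summary(c(1, 2, 8, 9), c(0, 0, 1, 1))
  expect_equal(max_ks(r)$ks, 1)

  r <- roc_summary(c(0, 1, 2), c(0, 0, 1))
  expect_equal(max_ks(r)$ks, 1)
  expect_equal(max_ks(r)$cut, 1.5)

  set.seed(21)
  for (i in 1:50) {
    n <- sample(6:25, 1)
    label <- c(0, 1, rbinom(n - 2, 1, 0.5))
    score <- sample(0:8, n, replace = TRUE)
    r <- roc_summary(score, label)
    cut <- youden_cutoff(score, label)
    sens <- sum(score > cut & label == 1) / sum(label == 1)
    spec <- sum(score <= cut & label == 0) / sum(label == 0)
    expect_equal(r$max_ks, sens + spec - 1, tolerance = 1e-12)
  }
})

test_that("Youden cut-off equals exhaustive midpoint search", {
  expect_equal(youden_cutoff(c(1, 2, 8, 9), c(0, 0, 1, 1)), 5)

  brute <- function(values, label) {
    v <- sort(unique(values))
    cand <- c(v[1] - 1, (v[-length(v)] + v[-1]) / 2)
    j <- sapply(cand, function(t) {
      sum(values > t & label == 1) / sum(label == 1) +
        sum(values <= t & label == 0) / sum(label == 0) - 1
    })
    max(j)
  }
  set.seed(5)
  for (i in 1:30) {
    n <- sample(8:20, 1)
    label <- c(0, 1, rbinom(n - 2, 1, 0.5))
    values <- round(rnorm(n), 1)
    cut <- youden_cutoff(values, label)
    j_at <- sum(values > cut & label == 1) / sum(label == 1) +
      sum(values <= cut & label == 0) / sum(label == 0) - 1
    expect_equal(j_at, brute(values, label), tolerance = 1e-12)
  }
  # integer rounding convention floors to the printed whole-kPa style
  expect_equal(youden_cutoff(c(140, 141, 142, 143, 150, 151), c(0, 0, 0, 1, 1, 1),
                             round_cut_to_int = TRUE), 142)
})

test_that("sensitivity-constrained cut-off maximizes specificity under the floor", {
  values <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  label  <- c(0, 0, 0, 0, 1, 0, 1, 1, 1, 1)
  # brute force over midpoints
  v <- sort(unique(values))
  cand <- c(v[1] - 1, (v[-length(v)] + v[-1]) / 2)
  sens <- sapply(cand, function(t) sum(values > t & label == 1) / sum(label == 1))
  expect_equal(sens_constrained_cutoff(values, label, 0.95), max(cand[sens >= 0.95]))
  expect_equal(sens_constrained_cutoff(values, label, 0.8), max(cand[sens >= 0.8]))

  # min_sens = 1 leaves every malignant value above the cut
  cut1 <- sens_constrained_cutoff(values, label, 1)
  expect_lt(cut1, min(values[label == 1]))

  set.seed(17)
  for (i in 1:30) {
    n <- sample(8:25, 1)
    label <- c(0, 1, rbinom(n - 2, 1, 0.4))
    values <- rnorm(n)
    cut <- sens_constrained_cutoff(values, label, 0.95)
    expect_gte(sum(values > cut & label == 1) / sum(label == 1), 0.95)
  }
})

test_that("tie-corrected Mann-Whitney matches enumeration and wilcox.test", {
  same <- mann_whitney_z(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$z, 0, tolerance = 1e-9)

  # 3-vs-3 toy: U by exhaustive pair counting
  x0 <- c(1, 2, 2); x1 <- c(2, 3, 4)
  pairs <- outer(x1, x0, ">") + 0.5 * outer(x1, x0, "==")
  expect_equal(mann_whitney_z(x0, x1)$u, sum(pairs))

  set.seed(3)
  x0 <- sample(1:5, 12, replace = TRUE)
  x1 <- sample(2:7, 9, replace = TRUE)
  ours <- mann_whitney_z(x0, x1)
  ref <- wilcox.test(x1, x0, correct = FALSE, exact = FALSE)
  expect_equal(ours$u, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
})

test_that("AUC equals the Mann-Whitney U-based rank probability", {
  set.seed(41)
  for (i in 1:20) {
    x0 <- sample(0:4, 15, replace = TRUE)
    x1 <- sample(1:6, 11, replace = TRUE)
    u <- mann_whitney_z(x0, x1)$u
    auc <- roc_summary(c(x0, x1), rep(0:1, c(15, 11)))$auc
    expect_equal(auc, u / (15 * 11), tolerance = 1e-12)
  }
})

test_that("Spearman matrix uses midranks and flags constants", {
  set.seed(8)
  co <- make_cohort(sweh = runif(20, 110, 198), ri = runif(20, 1, 2.9),
                    ct = runif(20, 1, 7), um = rbinom(20, 1, 0.5),
                    hy = rbinom(20, 1, 0.5), lfh = rbinom(20, 1, 0.5),
                    pv = rbinom(20, 1, 0.5), malignant = rep(0:1, 10))
  sm <- spearman_matrix(co)
  expect_equal(diag(sm$r)[["swe_hardness"]], 1)
  # monotone-transform invariance of rank correlation
  co2 <- co; co2$swe_hardness_kpa <- log(co$swe_hardness_kpa)
  expect_equal(spearman_matrix(co2)$r, sm$r)
  # equals Pearson of midranks, and matches cor.test's estimate
  r_hand <- cor(rank(co$swe_hardness_kpa), rank(co$cortical_thickness_mm))
  expect_equal(sm$r["swe_hardness", "cortical_thickness"], r_hand)
  ref <- suppressWarnings(cor.test(co$swe_hardness_kpa, co$cortical_thickness_mm,
                                   method = "spearman"))
  expect_equal(unname(sm$r["swe_hardness", "cortical_thickness"]),
               unname(ref$estimate))
  # the all-zero PI column is flagged missing
  expect_true(all(is.na(sm$r["peripheral_infiltration", ])))
})

test_that("pooled within-groups correlation matches a hand-computed example", {
  co <- make_cohort(sweh = c(120, 130, 140, 150, 165, 175),
                    ri = c(2.5, 2.0, 2.2, 1.6, 1.2, 1.4),
                    ct = c(2, 3, 4, 3, 5, 6),
                    malignant = c(0, 0, 0, 1, 1, 1))
  r <- pooled_within_groups_corr(co)
  # hand computation: center each group, pool deviations, correlate
  dev <- function(v, g) unlist(tapply(v, g, function(x) x - mean(x)))
  g <- co$malignant
  hand <- cor(dev(co$swe_hardness_kpa, g), dev(co$cortical_thickness_mm, g))
  expect_equal(unname(r["swe_hardness", "cortical_thickness"]), hand)
  expect_error(pooled_within_groups_corr(co[-1, ]), "at least 3")
})

test_that("within-group independent features have near-zero pooled correlation", {
  set.seed(55)
  n <- 2000
  co <- make_cohort(sweh = runif(n, 110, 198), ri = runif(n, 1, 2.9),
                    ct = runif(n, 1, 7), um = rbinom(n, 1, 0.5),
                    malignant = rep(0:1, n / 2))
  r <- pooled_within_groups_corr(co)
  mc_se <- 1 / sqrt(n)
  expect_lt(abs(r["swe_hardness", "cortical_thickness"]), 3 * mc_se)
  expect_lt(abs(r["neg_roundness_index", "indefinite_margins"]), 3 * mc_se)
})
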