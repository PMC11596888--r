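# Helper: labelled cohort with signal in the continuous features.
sim_cohort <- function(n, shift = 2, seed = 1) {
  set.seed(seed)
  g <- rep(0:1, length.out = n)
  make_cohort(sweh = 130 + shift * 10 * g + rnorm(n, 0, 8),
              ri = 2 - 0.3 * shift * g + abs(rnorm(n, 0, 0.2)) + 0.5,
              ct = 3 + 0.5 * shift * g + abs(rnorm(n, 0, 0.8)),
              um = rbinom(n, 1, 0.3 + 0.3 * g),
              hy = rbinom(n, 1, 0.3 + 0.3 * g),
              lfh = rbinom(n, 1, 0.2 + 0.5 * g),
              pi = rbinom(n, 1, 0.05 * g),
              pv = rbinom(n, 1, 0.3 + 0.1 * g),
              malignant = g)
}

test_that("1-D equal-variance LDA puts the boundary at the prior-adjusted midpoint", {
  set.seed(2)
  n <- 400
  co <- make_cohort(sweh = c(rnorm(n / 2, 120, 10), rnorm(n / 2, 160, 10)),
                    ri = 2, ct = 3, malignant = rep(0:1, each = n / 2))
  fit <- fit_lda(co, features = "swe_hardness")
  sc <- predict(fit, co, type = "score")
  # equal priors: score changes sign at the midpoint of the two class means
  mid <- mean(c(mean(co$swe_hardness_kpa[co$malignant == 0]),
                mean(co$swe_hardness_kpa[co$malignant == 1])))
  expect_true(all(predict(fit, co) == as.integer(co$swe_hardness_kpa >
                                                   mid - 1e-9) |
                    abs(co$swe_hardness_kpa - mid) < 1))
  expect_equal(sum(sc > 0), sum(co$swe_hardness_kpa > mid))
})

test_that("LDA direction solves the pooled linear system", {
  co <- make_cohort(sweh = c(120, 125, 130, 135, 150, 160, 155, 165),
                    ri = c(2.6, 2.2, 2.4, 2.0, 1.5, 1.2, 1.4, 1.1),
                    ct = 3, malignant = c(0, 0, 0, 0, 1, 1, 1, 1))
  fit <- fit_lda(co, features = c("swe_hardness", "neg_roundness_index"))
  m <- cbind(co$swe_hardness_kpa, -co$roundness_index)
  g <- co$malignant
  d0 <- scale(m[g == 0, ], scale = FALSE); d1 <- scale(m[g == 1, ], scale = FALSE)
  S <- (crossprod(d0) + crossprod(d1)) / (8 - 2)
  w_hand <- solve(S, colMeans(m[g == 1, ]) - colMeans(m[g == 0, ]))
  expect_equal(unname(fit$direction), unname(w_hand), tolerance = 1e-10)
})

test_that("LDA predictions agree with an independent implementation", {
  co <- sim_cohort(200, seed = 10)
  fit <- fit_lda(co)
  m <- feature_matrix(co)
  ref <- MASS::lda(m, grouping = co$malignant)
  ref_pred <- as.integer(as.character(predict(ref, m)$class))
  expect_equal(predict(fit, co), ref_pred)
  # direction is proportional to the reference scaling vector
  ratio <- fit$direction / drop(ref$scaling)
  expect_lt(diff(range(ratio)), 1e-6 * max(abs(ratio)))
})

test_that("canonical correlation equals the label-score correlation", {
  co <- sim_cohort(300, seed = 3)
  fit <- fit_lda(co)
  sc <- predict(fit, co, type = "score")
  expect_equal(fit$canonical_correlation, abs(cor(sc, co$malignant)),
               tolerance = 1e-10)
})

test_that("LDA with no class signal reaches only the larger prior", {
  set.seed(44)
  n <- 3000
  co <- make_cohort(sweh = rnorm(n, 140, 12), ri = runif(n, 1, 2.9),
                    ct = runif(n, 1, 7),
                    malignant = rep(c(0, 1), c(2000, 1000)))
  fit <- fit_lda(co, features = c("swe_hardness", "neg_roundness_index",
                                  "cortical_thickness"))
  acc <- mean(predict(fit, co) == co$malignant)
  expect_lt(abs(acc - 2 / 3), 0.03)
})

test_that("naive Bayes follows the posterior product rule", {
  # single strong binary feature: prediction follows the feature
  co <- make_cohort(sweh = 140, ri = 2, ct = 3,
                    lfh = c(rep(1, 9), rep(0, 1), rep(0, 9), rep(1, 1)),
                    malignant = rep(1:0, each = 10))
  fit <- fit_naive_bayes(co, features = "loss_fatty_hilum", selection = "all")
  expect_equal(predict(fit, co), co$loss_fatty_hilum)

  # two independent binaries: posterior equals the hand product rule on the grid
  set.seed(9)
  n <- 400
  g <- rep(0:1, each = n / 2)
  co <- make_cohort(sweh = 140, ri = 2, ct = 3,
                    um = rbinom(n, 1, 0.2 + 0.6 * g),
                    hy = rbinom(n, 1, 0.3 + 0.4 * g),
                    malignant = g)
  fit <- fit_naive_bayes(co, features = c("indefinite_margins", "hypoechogenicity"),
                         selection = "all")
  p_um <- fit$params$malignant$indefinite_margins$p
  q_um <- fit$params$benign$indefinite_margins$p
  p_hy <- fit$params$malignant$hypoechogenicity$p
  q_hy <- fit$params$benign$hypoechogenicity$p
  grid <- expand.grid(um = 0:1, hy = 0:1)
  for (k in seq_len(nrow(grid))) {
    rec <- make_cohort(sweh = 140, ri = 2, ct = 3,
                       um = grid$um[k], hy = grid$hy[k])
    lik1 <- (p_um^grid$um[k] * (1 - p_um)^(1 - grid$um[k])) *
      (p_hy^grid$hy[k] * (1 - p_hy)^(1 - grid$hy[k])) * fit$priors["malignant"]
    lik0 <- (q_um^grid$um[k] * (1 - q_um)^(1 - grid$um[k])) *
      (q_hy^grid$hy[k] * (1 - q_hy)^(1 - grid$hy[k])) * fit$priors["benign"]
    expect_equal(unname(predict(fit, rec, type = "posterior")),
                 unname(lik1 / (lik1 + lik0)), tolerance = 1e-12)
  }
})

test_that("Gaussian naive Bayes agrees with an independent implementation", {
  co <- sim_cohort(150, seed = 12)
  feats <- c("swe_hardness", "neg_roundness_index", "cortical_thickness")
  fit <- fit_naive_bayes(co, features = feats, selection = "all")
  m <- as.data.frame(feature_matrix(co)[, feats])
  ref <- e1071::naiveBayes(m, as.factor(co$malignant))
  ref_pred <- as.integer(as.character(predict(ref, m)))
  expect_equal(predict(fit, co), ref_pred)
})

test_that("greedy selection never falls below the best single feature", {
  for (seed in 1:5) {
    co <- sim_cohort(120, seed = seed)
    m <- feature_matrix(co)
    fit_all <- fit_naive_bayes(co, selection = "greedy")
    acc_sel <- mean(predict(fit_all, co) == co$malignant)
    singles <- vapply(colnames(m), function(f) {
      f1 <- fit_naive_bayes(co, features = f, selection = "all")
      mean(predict(f1, co) == co$malignant)
    }, 0)
    expect_gte(acc_sel, max(singles) - 1e-12)
  }
})

test_that("leave-one-out cross-validation aggregates held-out calls", {
  # perfectly separable data: LOO accuracy 1
  co <- make_cohort(sweh = c(120 + 1:12, 170 + 1:12), ri = 2, ct = 3,
                    malignant = rep(0:1, each = 12))
  fitter <- function(d) fit_lda(d, features = "swe_hardness")
  res <- loo_cv(fitter, co)
  expect_equal(res$metrics$accuracy, 1)

  # n = 5: matches a manual fold-of-1 loop
  co5 <- make_cohort(sweh = c(120, 150, 135, 160, 125), ri = 2, ct = 3,
                     lfh = c(0, 1, 0, 1, 0), malignant = c(0, 1, 0, 1, 0))
  nb_fitter <- function(d) fit_naive_bayes(d, features = "loss_fatty_hilum",
                                           selection = "all")
  res5 <- loo_cv(nb_fitter, co5)
  manual <- sapply(1:5, function(i) {
    predict(nb_fitter(co5[-i, ]), co5[i, ])
  })
  expect_equal(res5$predictions, as.integer(manual))
  expect_error(loo_cv(nb_fitter, co5[1:2, ]), "at least 3")
})

test_that("LOO accuracy does not beat resubstitution on average", {
  set.seed(77)
  diffs <- replicate(12, {
    co <- sim_cohort(40, shift = 1, seed = sample.int(1e6, 1))
    fitter <- function(d) fit_lda(d, features = c("swe_hardness",
                                                  "cortical_thickness"))
    fit <- fitter(co)
    resub <- mean(predict(fit, co) == co$malignant)
    loo <- loo_cv(fitter, co)$metrics$accuracy
    resub - loo
  })
  expect_gte(mean(diffs), -0.01)   # sampling tolerance
})
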