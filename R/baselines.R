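# First-principles baseline classifiers: two-group linear discriminant
# analysis with group-size priors and a pooled covariance matrix, and a
# mixed Gaussian/Bernoulli naive Bayes with greedy forward feature
# selection. Both are written out explicitly so their internals (canonical
# coefficients, pooled matrix, posteriors) are inspectable.

#' Fit a two-group linear discriminant
#'
#' Classical LDA: pooled within-group covariance (divisor n - 2), group
#' means, priors proportional to group sizes. The discriminant direction is
#' the pooled-covariance inverse applied to the mean difference;
#' standardized canonical coefficients scale the raw direction by the
#' pooled within-group standard deviations. The canonical correlation is
#' derived from the generalized eigenvalue of the between/within problem.
#' A small ridge (1e-8 * trace / p) is added if the pooled matrix is
#' numerically singular.
#'
#' @param cohort Labelled cohort.
#' @param features Feature names (subset of the canonical 8); default all.
#' @return Object of class `cassandra_lda` with elements `means`,
#'   `pooled_cov`, `priors`, `direction`, `std_coefficients`,
#'   `canonical_correlation`, `features`.
#' @export
fit_lda <- function(cohort, features = .feature_order) {
  validate_cohort(cohort, require_label = TRUE)
  m <- feature_matrix(cohort)[, features, drop = FALSE]
  g <- cohort$malignant
  n0 <- sum(g == 0); n1 <- sum(g == 1); n <- n0 + n1
  p <- ncol(m)
  if (n0 < p + 1 || n1 < p + 1) stop("each group needs at least features + 1 records")
  mu0 <- colMeans(m[g == 0, , drop = FALSE])
  mu1 <- colMeans(m[g == 1, , drop = FALSE])
  S <- pooled_within_cov(m, g)
  sol <- tryCatch(solve(S, mu1 - mu0), error = function(e) NULL)
  if (is.null(sol) || kappa(S) > 1e12) {
    S <- S + diag(1e-8 * sum(diag(S)) / p, p)
    sol <- tryCatch(solve(S, mu1 - mu0), error = function(e) {
      sds <- sqrt(diag(S))
      collinear <- names(sds)[sds < 1e-12]
      stop("pooled covariance is singular; offending feature(s): ",
           paste(if (length(collinear)) collinear else features, collapse = ", "))
    })
  }
  priors <- c(benign = n0 / n, malignant = n1 / n)
  # between-groups SSP and the canonical correlation of the discriminant
  mu <- (n0 * mu0 + n1 * mu1) / n
  B <- n0 * tcrossprod(mu0 - mu) + n1 * tcrossprod(mu1 - mu)
  W <- (n - 2) * S
  lambda <- drop(crossprod(sol, B %*% sol) / crossprod(sol, W %*% sol))
  structure(list(
    features = features,
    means = rbind(benign = mu0, malignant = mu1),
    pooled_cov = S, priors = priors, direction = sol,
    std_coefficients = sol * sqrt(diag(S)),
    canonical_correlation = sqrt(lambda / (1 + lambda))
  ), class = "cassandra_lda")
}

#' @export
print.cassandra_lda <- function(x, ...) {
  cat(sprintf("Two-group LDA on %d features; canonical correlation %.3f\n",
              length(x$features), x$canonical_correlation))
  print(round(x$std_coefficients, 3))
  invisible(x)
}

#' @rdname fit_lda
#' @param object A fitted `cassandra_lda`.
#' @param newdata Cohort data frame to classify.
#' @param type `"class"` for 0/1 predictions, `"score"` for the linear
#'   discriminant score (log posterior-odds of malignancy).
#' @param ... Unused.
#' @export
predict.cassandra_lda <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  m <- feature_matrix(newdata)[, object$features, drop = FALSE]
  w <- object$direction
  mid <- drop((object$means["benign", ] + object$means["malignant", ]) %*% w) / 2
  score <- drop(m %*% w) - mid + log(object$priors["malignant"] / object$priors["benign"])
  if (type == "score") return(unname(score))
  as.integer(score > 0)
}

#' Fit a mixed-type naive Bayes classifier
#'
#' Class-conditional independent margins: Gaussian for the continuous
#' features, Bernoulli with +0.5 pseudo-count smoothing for the binary
#' ones; priors by group size. `selection = "greedy"` picks predictors by
#' greedy forward selection on training accuracy (stopping when no addition
#' improves it); `"all"` keeps every candidate.
#'
#' @param cohort Labelled cohort.
#' @param features Candidate feature names; default all 8.
#' @param selection `"greedy"` or `"all"`.
#' @return Object of class `cassandra_nb`.
#' @export
fit_naive_bayes <- function(cohort, features = .feature_order,
                            selection = c("greedy", "all")) {
  selection <- match.arg(selection)
  validate_cohort(cohort, require_label = TRUE)
  m <- feature_matrix(cohort)[, features, drop = FALSE]
  g <- cohort$malignant
  if (sum(g == 0) == 0 || sum(g == 1) == 0) stop("both classes must be present")
  is_binary <- apply(m, 2, function(v) all(v %in% c(0, 1)))
  params <- lapply(c(benign = 0, malignant = 1), function(cls) {
    sub <- m[g == cls, , drop = FALSE]
    lapply(seq_along(features), function(i) {
      v <- sub[, i]
      if (is_binary[i]) {
        list(type = "bernoulli", p = (sum(v) + 0.5) / (length(v) + 1))
      } else {
        s <- stats::sd(v)
        if (s < 1e-9) s <- 1e-6 * max(abs(mean(v)), 1)  # variance ridge
        list(type = "gaussian", mean = mean(v), sd = s)
      }
    })
  })
  for (cls in names(params)) names(params[[cls]]) <- features
  fit <- structure(list(features = features, params = params,
                        priors = c(benign = mean(g == 0), malignant = mean(g == 1)),
                        selected = features),
                   class = "cassandra_nb")
  if (selection == "greedy") {
    fit$selected <- .nb_greedy_select(fit, m, g)
  }
  fit
}

# Greedy forward selection on training accuracy; ties keep the earlier
# candidate in `features` order (features are passed ranked by univariate
# discrimination).
.nb_greedy_select <- function(fit, m, g, min_gain = 1e-12) {
  remaining <- fit$features
  selected <- character(0)
  best_acc <- -Inf
  repeat {
    accs <- vapply(remaining, function(f) {
      mean(.nb_predict_matrix(fit, m, c(selected, f)) == g)
    }, 0)
    if (length(accs) == 0 || max(accs) <= best_acc + min_gain) break
    pick <- remaining[which.max(accs)]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    best_acc <- max(accs)
  }
  if (length(selected) == 0) selected <- fit$features[1]
  selected
}

.nb_log_lik <- function(fit, m, cls, feats) {
  ll <- rep(log(fit$priors[cls]), nrow(m))
  for (f in feats) {
    pr <- fit$params[[cls]][[f]]
    v <- m[, f]
    ll <- ll + if (pr$type == "bernoulli") {
      ifelse(v == 1, log(pr$p), log(1 - pr$p))
    } else {
      stats::dnorm(v, pr$mean, pr$sd, log = TRUE)
    }
  }
  ll
}

.nb_predict_matrix <- function(fit, m, feats) {
  as.integer(.nb_log_lik(fit, m, "malignant", feats) >
               .nb_log_lik(fit, m, "benign", feats))
}

#' @rdname fit_naive_bayes
#' @param object A fitted `cassandra_nb`.
#' @param newdata Cohort data frame to classify.
#' @param type `"class"` for 0/1 predictions, `"posterior"` for the
#'   malignancy posterior probability.
#' @param ... Unused.
#' @export
predict.cassandra_nb <- function(object, newdata, type = c("class", "posterior"), ...) {
  type <- match.arg(type)
  m <- feature_matrix(newdata)[, object$features, drop = FALSE]
  l1 <- .nb_log_lik(object, m, "malignant", object$selected)
  l0 <- .nb_log_lik(object, m, "benign", object$selected)
  if (type == "class") return(as.integer(l1 > l0))
  1 / (1 + exp(l0 - l1))
}

#' Leave-one-out cross-validation of a classifier
#'
#' Refits the supplied fitter n times, each excluding one record, and
#' aggregates the held-out predictions into confusion metrics.
#'
#' @param fitter Function `cohort -> fitted model` (the model must have a
#'   `predict` method returning 0/1 classes).
#' @param cohort Labelled cohort with at least 3 records.
#' @return List: `metrics` ([confusion_metrics()] of the held-out
#'   predictions) and `predictions` (per-record held-out calls).
#' @export
loo_cv <- function(fitter, cohort) {
  validate_cohort(cohort, require_label = TRUE)
  n <- nrow(cohort)
  if (n < 3) stop("leave-one-out needs at least 3 records")
  preds <- integer(n)
  for (i in seq_len(n)) {
    fit <- fitter(cohort[-i, , drop = FALSE])
    preds[i] <- stats::predict(fit, cohort[i, , drop = FALSE])
  }
  list(metrics = confusion_metrics(preds, cohort$malignant), predictions = preds)
}
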