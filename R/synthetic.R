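# Gaussian-copula generator of synthetic lymph-node cohorts.
#
# Each group (benign / malignant) draws an 8-dimensional latent normal with
# a shared latent correlation matrix; margins are transformed to
# truncated-and-rounded normals (continuous features) or thresholded at the
# prevalence quantile (binary features). The latent matrix is calibrated by
# per-pair numeric inversion so the *observed* pooled within-groups
# correlations hit their targets despite the attenuation that
# dichotomization and truncation induce.

#' Group-conditional marginal targets of the default cohort
#'
#' Published descriptive statistics of the 529-node cohort: per-group mean,
#' SD and range for the continuous features (stiffness in kPa, negative
#' roundness index, cortical thickness in mm, each on a measurement grid)
#' and per-group prevalences for the five binary features. Benign peripheral
#' infiltration is exactly degenerate at 0.
#'
#' @return Named list of per-feature marginal descriptions.
#' @export
default_marginals <- function() {
  cont <- function(m0, s0, lo0, hi0, m1, s1, lo1, hi1, grain) {
    list(type = "continuous",
         benign = list(mean = m0, sd = s0, min = lo0, max = hi0),
         malignant = list(mean = m1, sd = s1, min = lo1, max = hi1),
         grain = grain)
  }
  bin <- function(p0, p1) list(type = "binary", benign = p0, malignant = p1)
  list(
    swe_hardness        = cont(131.00, 11.89, 110, 160, 161.73, 14.08, 110, 198, 1),
    neg_roundness_index = cont(-2.02, 0.43, -2.9, -1.1, -1.35, 0.34, -2.8, -1.0, 0.1),
    loss_fatty_hilum    = bin(0.15, 0.76),
    indefinite_margins  = bin(0.25, 0.75),
    hypoechogenicity    = bin(0.33, 0.82),
    cortical_thickness  = cont(3.20, 1.37, 1, 7, 4.41, 1.17, 1, 7, 1),
    peripheral_infiltration    = bin(0.00, 0.11),
    peripheral_vascularization = bin(0.30, 0.43)
  )
}

#' Pooled within-groups correlation targets of the default cohort
#'
#' The published pooled within-groups (partial, controlling for malignancy)
#' correlation matrix over the 8 features, symmetric with unit diagonal.
#'
#' @return An 8x8 correlation matrix in the canonical feature order.
#' @export
default_corr_targets <- function() {
  f <- .feature_order
  r <- diag(8)
  dimnames(r) <- list(f, f)
  up <- rbind(
    # sweh        negri  lfh    um     hy     ct     pi     pv
    c(NA,          0.108, 0.258, 0.042, 0.108, 0.179, 0.071, 0.191),
    c(NA, NA,             0.174, 0.061, 0.123, 0.101, 0.004, 0.032),
    c(NA, NA, NA,               -0.031, 0.166, 0.135, 0.015, -0.081),
    c(NA, NA, NA, NA,                  -0.011, 0.106, 0.061, 0.108),
    c(NA, NA, NA, NA, NA,                     -0.037, 0.024, -0.270),
    c(NA, NA, NA, NA, NA, NA,                        -0.018, 0.130),
    c(NA, NA, NA, NA, NA, NA, NA,                            0.126),
    c(NA, NA, NA, NA, NA, NA, NA, NA))
  for (i in 1:7) for (j in (i + 1):8) r[i, j] <- r[j, i] <- up[i, j]
  r
}

#' Configure the synthetic cohort generator
#'
#' @param n_benign,n_malignant Group sizes (defaults 320 / 209).
#' @param marginals Per-feature marginal targets; see [default_marginals()].
#' @param corr_targets Pooled within-groups correlation targets (8x8
#'   symmetric, unit diagonal); see [default_corr_targets()].
#' @return Object of class `generator_config`. The latent correlation matrix
#'   and margin parameters are filled in by [calibrate_latent()] (called
#'   automatically by [generate_cohort()] when absent).
#' @export
generator_config <- function(n_benign = 320, n_malignant = 209,
                             marginals = default_marginals(),
                             corr_targets = default_corr_targets()) {
  stopifnot(n_benign >= 1, n_malignant >= 1)
  if (!isTRUE(all.equal(corr_targets, t(corr_targets))) ||
      any(abs(diag(corr_targets) - 1) > 1e-12)) {
    stop("corr_targets must be symmetric with unit diagonal")
  }
  if (any(abs(corr_targets[upper.tri(corr_targets)]) >= 1)) {
    stop("off-diagonal correlation targets must lie in (-1, 1)")
  }
  for (f in names(marginals)) {
    m <- marginals[[f]]
    if (m$type == "binary" &&
        (m$benign < 0 || m$benign > 1 || m$malignant < 0 || m$malignant > 1)) {
      stop("prevalence out of [0, 1] for feature ", f)
    }
  }
  structure(list(n_benign = n_benign, n_malignant = n_malignant,
                 marginals = marginals, corr_targets = corr_targets,
                 latent = NULL, margin_params = NULL, repair_adjustment = NULL),
            class = "generator_config")
}

# ---- truncated / discretized normal margins --------------------------------

# Discretized truncated normal: mass of each grid point k (grid step =
# grain, clamped to [a, b]) under N(mu, sigma) truncated to [a, b] with
# rounding to the nearest grid point.
.disc_pmf <- function(mu, sigma, grid, a, b, grain) {
  lo <- pmax(grid - grain / 2, a)
  hi <- pmin(grid + grain / 2, b)
  p <- stats::pnorm(hi, mu, sigma) - stats::pnorm(lo, mu, sigma)
  z <- stats::pnorm(b, mu, sigma) - stats::pnorm(a, mu, sigma)
  p / z
}

# Solve for pre-truncation (mu, sigma) such that the truncated + rounded
# margin matches the target mean and SD (targets are post-truncation
# moments). Multi-start Nelder-Mead on squared standardized residuals; the
# parameter box keeps the truncation numerically well-conditioned. Some
# published (mean, SD) pairs sit at the boundary of the truncated-normal
# family (mass piling at a range limit), so a small residual is tolerated;
# it stays well inside the sampling noise of cohort-sized draws.
.solve_margin <- function(target, a, b, grain, tol = 2e-3) {
  grid <- seq(a, b, by = grain)
  len <- b - a
  obj <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    if (mu < a - 5 * len || mu > b + 5 * len || sigma > 6 * len || sigma < len / 100) {
      return(1e6)
    }
    p <- .disc_pmf(mu, sigma, grid, a, b, grain)
    if (anyNA(p)) return(1e6)
    m <- sum(p * grid)
    s <- sqrt(max(sum(p * grid^2) - m^2, 0))
    ((m - target$mean) / max(target$sd, 1e-6))^2 +
      ((s - target$sd) / max(target$sd, 1e-6))^2
  }
  best <- NULL
  for (mu0 in c(target$mean, b, (a + b) / 2, b + 2 * len)) {
    for (s0 in c(target$sd, target$sd * 3, len)) {
      fit <- stats::optim(c(mu0, log(s0)), obj,
                          control = list(maxit = 5000, reltol = 1e-15))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  }
  if (best$value > tol) {
    stop(sprintf("cannot match mean %.3f / SD %.3f on [%g, %g]: residual %.2g",
                 target$mean, target$sd, a, b, best$value))
  }
  list(mu = best$par[1], sigma = exp(best$par[2]), a = a, b = b,
       grain = grain, grid = grid)
}

# Quantile transform of a standard-normal latent value to the continuous
# margin (truncated normal; rounding applied at draw time).
.q_trunc <- function(u, mp) {
  pa <- stats::pnorm(mp$a, mp$mu, mp$sigma)
  pb <- stats::pnorm(mp$b, mp$mu, mp$sigma)
  stats::qnorm(pa + u * (pb - pa), mp$mu, mp$sigma)
}

# Density of the (unrounded) truncated normal margin.
.d_trunc <- function(x, mp) {
  z <- stats::pnorm(mp$b, mp$mu, mp$sigma) - stats::pnorm(mp$a, mp$mu, mp$sigma)
  ifelse(x < mp$a | x > mp$b, 0, stats::dnorm(x, mp$mu, mp$sigma) / z)
}

# ---- Gauss-Hermite quadrature (probabilists', weight = standard normal) ----

.gauss_hermite <- function(n = 48) {
  k <- seq_len(n - 1)
  jac <- matrix(0, n, n)
  jac[cbind(k, k + 1)] <- sqrt(k)
  jac[cbind(k + 1, k)] <- sqrt(k)
  e <- eigen(jac, symmetric = TRUE)
  list(x = e$values, w = e$vectors[1, ]^2)
}

# ---- latent correlation calibration ----------------------------------------

# Per-group margin description: a transform g(z) of a standard normal, with
# its first two moments. Binary margins with prevalence 0 or 1 are constant.
.margin_fun <- function(feature, group, cfg) {
  m <- cfg$marginals[[feature]]
  if (m$type == "binary") {
    p <- m[[group]]
    if (p <= 0 || p >= 1) {
      return(list(kind = "constant", value = round(p), mean = round(p), var = 0))
    }
    t <- stats::qnorm(1 - p)
    list(kind = "binary", t = t, mean = p, var = p * (1 - p))
  } else {
    mp <- cfg$margin_params[[group]][[feature]]
    gh <- .gh64
    g <- .q_trunc(stats::pnorm(gh$x), mp)
    list(kind = "continuous", mp = mp,
         mean = sum(gh$w * g), var = sum(gh$w * g^2) - sum(gh$w * g)^2)
  }
}

# E[g1(Z1) g2(Z2)] under latent correlation rho, by type-specific quadrature.
.cross_moment <- function(f1, f2, rho) {
  if (f1$kind == "constant" || f2$kind == "constant") {
    return(f1$mean * f2$mean)
  }
  s <- sqrt(max(1 - rho^2, 1e-12))
  gh <- .gh64
  if (f1$kind == "binary" && f2$kind == "binary") {
    # P(Z1 > t1, Z2 > t2) via 1-D integral of the conditional normal CDF
    fun <- function(z) stats::dnorm(z) * stats::pnorm((rho * z - f2$t) / s)
    stats::integrate(fun, lower = f1$t, upper = Inf, rel.tol = 1e-10)$value
  } else if (f1$kind == "binary" || f2$kind == "binary") {
    if (f1$kind != "binary") { tmp <- f1; f1 <- f2; f2 <- tmp }
    # E[g2(Z2) ; Z1 > t1]: outer adaptive over z1, inner Gauss-Hermite
    cond_mean <- function(z) {
      zz <- outer(rho * z, s * gh$x, "+")
      as.vector(.q_trunc(stats::pnorm(zz), f2$mp) %*% gh$w)
    }
    fun <- function(z) stats::dnorm(z) * cond_mean(z)
    stats::integrate(fun, lower = f1$t, upper = Inf, rel.tol = 1e-9)$value
  } else {
    g1 <- .q_trunc(stats::pnorm(gh$x), f1$mp)
    zz <- outer(rho * gh$x, s * gh$x, "+")
    cond <- as.vector(.q_trunc(stats::pnorm(zz), f2$mp) %*% gh$w)
    sum(gh$w * g1 * cond)
  }
}

#' Calibrate the latent correlation matrix of the generator
#'
#' For every feature pair, numerically inverts the map from latent-normal
#' correlation to the observed pooled within-groups correlation (phi,
#' point-biserial or attenuated Pearson under the configured margins,
#' computed by quadrature), so that generated cohorts reproduce the target
#' matrix despite dichotomization and truncation. The assembled matrix is
#' repaired to the nearest-by-eigenvalue-clipping positive semi-definite
#' correlation matrix; the maximum absolute repair adjustment is stored in
#' the returned config.
#'
#' @param cfg A [generator_config()].
#' @return The config with `latent`, `margin_params` and
#'   `repair_adjustment` filled in.
#' @export
calibrate_latent <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  feats <- names(cfg$marginals)
  cfg$margin_params <- list(benign = list(), malignant = list())
  for (f in feats) {
    m <- cfg$marginals[[f]]
    if (m$type == "continuous") {
      for (g in c("benign", "malignant")) {
        cfg$margin_params[[g]][[f]] <-
          .solve_margin(m[[g]], m[[g]]$min, m[[g]]$max, m$grain)
      }
    }
  }
  n0 <- cfg$n_benign; n1 <- cfg$n_malignant
  w <- c(benign = (n0 - 1) / (n0 + n1 - 2), malignant = (n1 - 1) / (n0 + n1 - 2))
  mf <- list(benign = lapply(feats, .margin_fun, group = "benign", cfg = cfg),
             malignant = lapply(feats, .margin_fun, group = "malignant", cfg = cfg))
  names(mf$benign) <- names(mf$malignant) <- feats

  pooled_var <- vapply(feats, function(f) {
    w["benign"] * mf$benign[[f]]$var + w["malignant"] * mf$malignant[[f]]$var
  }, 0)

  implied <- function(i, j, rho) {
    cv <- 0
    for (g in c("benign", "malignant")) {
      f1 <- mf[[g]][[feats[i]]]; f2 <- mf[[g]][[feats[j]]]
      cv <- cv + w[g] * (.cross_moment(f1, f2, rho) - f1$mean * f2$mean)
    }
    cv / sqrt(pooled_var[i] * pooled_var[j])
  }

  k <- length(feats)
  lat <- diag(k)
  dimnames(lat) <- list(feats, feats)
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    target <- cfg$corr_targets[feats[i], feats[j]]
    if (abs(target) < 1e-12) next
    lo <- implied(i, j, -0.999)
    hi <- implied(i, j, 0.999)
    if (target < lo || target > hi) {
      stop(sprintf("target correlation %.3f for pair %s-%s is unattainable under its margins (range [%.3f, %.3f])",
                   target, feats[i], feats[j], lo, hi))
    }
    lat[i, j] <- lat[j, i] <-
      stats::uniroot(function(r) implied(i, j, r) - target,
                     lower = -0.999, upper = 0.999, tol = 1e-6)$root
  }

  # PSD repair: clip eigenvalues, rescale to unit diagonal
  e <- eigen(lat, symmetric = TRUE)
  if (min(e$values) < 1e-10) {
    v <- pmax(e$values, 1e-8)
    rep_m <- e$vectors %*% (v * t(e$vectors))
    d <- sqrt(diag(rep_m))
    rep_m <- rep_m / tcrossprod(d)
    cfg$repair_adjustment <- max(abs(rep_m - lat))
    lat <- rep_m
    dimnames(lat) <- list(feats, feats)
  } else {
    cfg$repair_adjustment <- 0
  }
  cfg$latent <- lat
  cfg
}

.gh64 <- NULL  # filled at load time

.onLoad <- function(libname, pkgname) {
  assign(".gh64", .gauss_hermite(64), envir = parent.env(environment()))
}

#' Generate a synthetic lymph-node cohort
#'
#' Draws the configured numbers of benign and malignant nodes from the
#' calibrated Gaussian copula: one latent multivariate normal per node,
#' continuous margins transformed to truncated normals rounded to their
#' measurement grid and clamped to the published ranges, binary margins
#' thresholded at the prevalence quantile. Deterministic given the seed.
#'
#' @param cfg A [generator_config()]; calibrated on the fly if needed.
#' @param seed Integer seed.
#' @return A labelled cohort data frame (529 rows under the defaults).
#' @export
generate_cohort <- function(cfg = generator_config(), seed = 1) {
  stopifnot(inherits(cfg, "generator_config"))
  if (is.null(cfg$latent)) cfg <- calibrate_latent(cfg)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  feats <- names(cfg$marginals)
  ch <- chol(cfg$latent + diag(1e-10, length(feats)))
  draw_group <- function(n, group) {
    z <- matrix(stats::rnorm(n * length(feats)), n) %*% ch
    out <- matrix(0, n, length(feats), dimnames = list(NULL, feats))
    for (i in seq_along(feats)) {
      m <- cfg$marginals[[feats[i]]]
      if (m$type == "binary") {
        p <- m[[group]]
        out[, i] <- if (p <= 0) 0 else if (p >= 1) 1 else
          as.integer(z[, i] > stats::qnorm(1 - p))
      } else {
        mp <- cfg$margin_params[[group]][[feats[i]]]
        y <- .q_trunc(stats::pnorm(z[, i]), mp)
        y <- round(y / mp$grain) * mp$grain
        out[, i] <- pmin(pmax(y, mp$a), mp$b)
      }
    }
    out
  }
  ben <- draw_group(cfg$n_benign, "benign")
  mal <- draw_group(cfg$n_malignant, "malignant")
  m <- rbind(ben, mal)
  n <- nrow(m)
  cohort <- data.frame(
    node_id = sprintf("N%04d", seq_len(n)),
    patient_id = sprintf("P%03d", ceiling(seq_len(n) / 8)),
    swe_hardness_kpa = m[, "swe_hardness"],
    roundness_index = round(-m[, "neg_roundness_index"], 10),
    cortical_thickness_mm = m[, "cortical_thickness"],
    indefinite_margins = m[, "indefinite_margins"],
    hypoechogenicity = m[, "hypoechogenicity"],
    loss_fatty_hilum = m[, "loss_fatty_hilum"],
    peripheral_infiltration = m[, "peripheral_infiltration"],
    peripheral_vascularization = m[, "peripheral_vascularization"],
    malignant = rep(c(0, 1), c(cfg$n_benign, cfg$n_malignant))
  )
  validate_cohort(cohort)
  cohort
}

#' Summarize a cohort against the generator's target shapes
#'
#' Per-group observed means, SDs, medians and ranges for every feature
#' (roundness as -RI), group sizes, and the observed pooled within-groups
#' correlation matrix.
#'
#' @param cohort Labelled cohort.
#' @return List `group_sizes`, `marginals` (data frame), `pooled_corr`.
#' @export
summarize_cohort <- function(cohort) {
  validate_cohort(cohort, require_label = TRUE)
  m <- feature_matrix(cohort)
  g <- cohort$malignant
  rows <- list()
  for (f in colnames(m)) for (grp in c(0, 1)) {
    v <- m[g == grp, f]
    rows[[length(rows) + 1L]] <- data.frame(
      feature = f, malignant = grp, n = length(v),
      mean = mean(v), sd = stats::sd(v), median = stats::median(v),
      min = min(v), max = max(v))
  }
  list(group_sizes = c(benign = sum(g == 0), malignant = sum(g == 1)),
       marginals = do.call(rbind, rows),
       pooled_corr = pooled_within_groups_corr(cohort))
}

#' Density crossing of a continuous feature's group margins
#'
#' The value at which the benign and malignant truncated-normal densities of
#' the calibrated generator intersect between the two group means — the
#' large-sample limit of the Youden-optimal cut for that feature.
#'
#' @param cfg A calibrated [generator_config()].
#' @param feature One of the continuous feature names.
#' @return The crossing point (same units as the feature).
#' @export
density_crossing <- function(cfg, feature = "swe_hardness") {
  stopifnot(inherits(cfg, "generator_config"))
  if (is.null(cfg$margin_params)) cfg <- calibrate_latent(cfg)
  mp0 <- cfg$margin_params$benign[[feature]]
  mp1 <- cfg$margin_params$malignant[[feature]]
  f <- function(x) .d_trunc(x, mp1) - .d_trunc(x, mp0)
  lo <- cfg$marginals[[feature]]$benign$mean
  hi <- cfg$marginals[[feature]]$malignant$mean
  stats::uniroot(f, lower = min(lo, hi), upper = max(lo, hi), tol = 1e-8)$root
}
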