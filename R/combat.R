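#' @importFrom stats model.matrix var aov anova lm resid
NULL

# Moment estimators for the empirical-Bayes priors: normal prior on the
# per-batch additive effects, inverse-gamma prior on the multiplicative
# (variance) effects.
.aprior <- function(delta_hat) {
  m <- mean(delta_hat); s2 <- var(delta_hat)
  (2 * s2 + m^2) / s2
}
.bprior <- function(delta_hat) {
  m <- mean(delta_hat); s2 <- var(delta_hat)
  (m * s2 + m^3) / s2
}

# Iterative joint posterior solution for the shrunk location (gamma*) and
# scale (delta*) of one batch, as in the canonical parametric procedure.
.it_sol <- function(z, gamma_hat, delta_hat, gamma_bar, tau2, a, b,
                    conv = 1e-4) {
  n <- colSums(!is.na(z))
  g_old <- gamma_hat
  d_old <- delta_hat
  repeat {
    g_new <- (n * tau2 * gamma_hat + d_old * gamma_bar) / (n * tau2 + d_old)
    sum2 <- colSums(sweep(z, 2, g_new)^2, na.rm = TRUE)
    d_new <- (0.5 * sum2 + b) / (n / 2 + a - 1)
    change <- max(abs(g_new - g_old) / abs(g_old),
                  abs(d_new - d_old) / abs(d_old))
    g_old <- g_new
    d_old <- d_new
    if (is.na(change) || change < conv) break
  }
  list(gamma_star = g_new, delta_star = d_new)
}

# Build the covariate design matrix (without intercept or batch columns)
# from a feature table and a design specification.
.combat_design <- function(table, design) {
  if (is.null(design) || !length(design)) {
    return(matrix(numeric(0), nrow(table), 0))
  }
  cols <- lapply(design, function(v) {
    if (v == "disease") {
      # disorder count; healthy training rows count as 0
      g <- table$group
      g[is.na(g)] <- 0
      as.numeric(g)
    } else {
      if (!v %in% names(table)) stop("design variable not in table: ", v)
      as.numeric(table[[v]])
    }
  })
  X <- do.call(cbind, cols)
  colnames(X) <- design
  X
}

#' Fit a location-and-scale batch-harmonization model
#'
#' Implements the standard parametric empirical-Bayes harmonization of
#' multi-scanner feature data: per-feature regression on the biological
#' design plus batch indicators, standardization by the pooled residual
#' variance, then shrinkage of per-batch means toward a normal prior and of
#' per-batch variances toward an inverse-gamma prior, both estimated by
#' moments across features. Biological variance named in `design` (age,
#' sex, disease status, ...) is estimated jointly and restored on output,
#' so it is preserved by harmonization.
#'
#' @param table feature table (see [validate_feature_table()]).
#' @param batch name of the column holding scanner labels (default
#'   `"site"`), or a vector of labels of length `nrow(table)`.
#' @param design character vector of covariates to protect; `"disease"`
#'   maps to the disorder count with healthy-cohort rows coded 0.
#' @param eb logical; empirical-Bayes shrinkage (default) or direct
#'   per-batch estimates.
#' @return object of class `"combat_model"`.
#' @export
combat_fit <- function(table, batch = "site",
                       design = c("age", "sex", "disease"), eb = TRUE) {
  b <- if (length(batch) == 1L && is.character(batch)) table[[batch]] else batch
  b <- factor(b)
  if (nlevels(b) < 2L) stop("degenerate-batch error: need >= 2 batches")
  if (any(table(b) < 2L)) stop("degenerate-batch error: each batch needs >= 2 rows")
  Y <- as.matrix(table[, feature_keys(), drop = FALSE])
  n <- nrow(Y); p <- ncol(Y)
  Xb <- model.matrix(~ b - 1)            # one column per batch
  Xc <- .combat_design(table, design)
  X <- cbind(Xb, Xc)
  if (qr(X)$rank < ncol(X)) stop("design error: design matrix is rank deficient")
  # per-feature OLS of Y on [batch indicators, covariates]
  B <- solve(crossprod(X), crossprod(X, Y))     # (nbatch + q) x p
  nb <- nlevels(b)
  gamma_hat <- B[seq_len(nb), , drop = FALSE]   # per-batch means
  beta_cov <- B[-seq_len(nb), , drop = FALSE]
  prop <- as.numeric(table(b)) / n
  alpha <- drop(crossprod(prop, gamma_hat))     # grand mean per feature
  fitted_full <- X %*% B
  var_pooled <- colSums((Y - fitted_full)^2) / n
  if (any(var_pooled <= 0)) stop("degenerate feature with zero residual variance")
  stand_mean <- matrix(alpha, n, p, byrow = TRUE)
  if (ncol(Xc)) stand_mean <- stand_mean + Xc %*% beta_cov
  Z <- (Y - stand_mean) / matrix(sqrt(var_pooled), n, p, byrow = TRUE)
  gamma_hat_z <- apply(Z, 2, function(col) tapply(col, b, mean))
  delta_hat_z <- apply(Z, 2, function(col) tapply(col, b, var))
  gamma_hat_z <- matrix(gamma_hat_z, nb, p,
                        dimnames = list(levels(b), colnames(Y)))
  delta_hat_z <- matrix(delta_hat_z, nb, p,
                        dimnames = list(levels(b), colnames(Y)))
  gamma_star <- gamma_hat_z
  delta_star <- delta_hat_z
  if (eb) {
    for (i in seq_len(nb)) {
      zi <- Z[b == levels(b)[i], , drop = FALSE]
      gbar <- mean(gamma_hat_z[i, ])
      tau2 <- var(gamma_hat_z[i, ])
      a <- .aprior(delta_hat_z[i, ])
      bb <- .bprior(delta_hat_z[i, ])
      sol <- .it_sol(zi, gamma_hat_z[i, ], delta_hat_z[i, ], gbar, tau2, a, bb)
      gamma_star[i, ] <- sol$gamma_star
      delta_star[i, ] <- sol$delta_star
    }
  }
  structure(list(
    batch_levels = levels(b),
    batch_col = if (length(batch) == 1L && is.character(batch)) batch else "site",
    design = design,
    alpha = alpha,
    beta_cov = beta_cov,
    var_pooled = var_pooled,
    gamma_star = gamma_star,
    delta_star = delta_star,
    eb = eb
  ), class = "combat_model")
}

#' Apply a fitted harmonization model to a feature table
#'
#' Standardizes each feature using the model's intercept, covariate
#' coefficients and pooled variance, removes the batch location effect,
#' rescales by the batch scale effect, and restores the covariate-predicted
#' mean. Row count and covariate columns are untouched.
#'
#' @param model a [combat_fit()] result.
#' @param table feature table whose batch labels are a subset of the
#'   model's.
#' @return the table with the 28 feature columns replaced by harmonized
#'   values.
#' @export
combat_apply <- function(model, table) {
  stopifnot(inherits(model, "combat_model"))
  b <- factor(table[[model$batch_col]], levels = model$batch_levels)
  if (anyNA(b)) {
    stop("lookup error: unseen batch label(s): ",
         paste(unique(table[[model$batch_col]][is.na(b)]), collapse = ", "))
  }
  Y <- as.matrix(table[, feature_keys(), drop = FALSE])
  n <- nrow(Y); p <- ncol(Y)
  Xc <- .combat_design(table, model$design)
  stand_mean <- matrix(model$alpha, n, p, byrow = TRUE)
  if (ncol(Xc)) stand_mean <- stand_mean + Xc %*% model$beta_cov
  sdm <- matrix(sqrt(model$var_pooled), n, p, byrow = TRUE)
  Z <- (Y - stand_mean) / sdm
  idx <- as.integer(b)
  Zadj <- (Z - model$gamma_star[idx, , drop = FALSE]) /
    sqrt(model$delta_star[idx, , drop = FALSE])
  out <- table
  out[, feature_keys()] <- Zadj * sdm + stand_mean
  out
}

#' @export
print.combat_model <- function(x, ...) {
  cat("Location/scale batch-harmonization model\n")
  cat("  batches:", paste(x$batch_levels, collapse = ", "), "\n")
  cat("  protected design:", paste(x$design, collapse = ", "), "\n")
  cat("  empirical-Bayes shrinkage:", x$eb, "\n")
  cat("  additive effects (gamma*): range",
      sprintf("[%.3f, %.3f]", min(x$gamma_star), max(x$gamma_star)), "\n")
  cat("  scale effects (delta*): range",
      sprintf("[%.3f, %.3f]", min(x$delta_star), max(x$delta_star)), "\n")
  invisible(x)
}

#' Scan features for residual scanner effects
#'
#' One-way ANOVA of each feature on the batch factor after residualizing
#' age and sex, as a quality check before/after harmonization.
#'
#' @param table feature table.
#' @param batch batch column name or label vector.
#' @return data.frame with per-feature F statistics, degrees of freedom and
#'   p-values.
#' @export
site_effect_scan <- function(table, batch = "site") {
  b <- if (length(batch) == 1L && is.character(batch)) table[[batch]] else batch
  b <- factor(b)
  if (nlevels(b) < 2L) stop("need >= 2 batches")
  res <- lapply(feature_keys(), function(k) {
    f <- table[[k]]
    degenerate <- var(f) < 1e-20 * (mean(f)^2 + 1)  # identical values scan as F = 0
    y <- resid(lm(f ~ age + sex, data = table))
    m <- tapply(y, b, mean)
    nn <- tapply(y, b, length)
    ssb <- sum(nn * (m - mean(y))^2)
    ssw <- sum((y - m[as.integer(b)])^2)
    df1 <- nlevels(b) - 1L
    df2 <- length(y) - nlevels(b)
    Fst <- if (degenerate || ssb <= 0) 0 else (ssb / df1) / (ssw / df2)
    data.frame(feature = k, F = Fst, df1 = df1, df2 = df2,
               p = stats::pf(Fst, df1, df2, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
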