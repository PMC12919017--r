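#' @importFrom stats optim sd cor quantile coef lm.fit predict
#' @importFrom graphics abline plot
NULL

#' Kernel and optimizer settings for the brain-age GP
#'
#' The covariance is a sum of an isotropic squared-exponential (RBF) term,
#' a linear (dot-product) term, and white noise, on per-feature
#' standardized inputs: smooth nonlinear ageing trajectories ride on a
#' global linear trend. Hyperparameters (RBF amplitude `sf2`, length-scale
#' `ell`, linear variance `sl2`, noise variance `sn2`) are optimized by
#' multi-start maximization of the log marginal likelihood with analytic
#' gradients.
#'
#' @param optimize logical; if `FALSE`, `init` is used as-is.
#' @param n_restarts number of optimizer starts (the first is a data-driven
#'   heuristic, the rest are seeded perturbations of it).
#' @param seed RNG seed for the restarts.
#' @param init optional named numeric vector `c(sf2, ell, sl2, sn2)` of
#'   starting (or fixed) hyperparameters on the natural scale.
#' @param maxit L-BFGS-B iteration cap per start.
#' @return list of class `"gpr_config"`.
#' @export
gpr_config <- function(optimize = TRUE, n_restarts = 5L, seed = 1L,
                       init = NULL, maxit = 100L) {
  if (!is.null(init)) {
    stopifnot(all(c("sf2", "ell", "sl2", "sn2") %in% names(init)),
              all(init > 0))
  }
  structure(list(optimize = optimize, n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed), init = init,
                 maxit = as.integer(maxit)),
            class = "gpr_config")
}

.sqdist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

.kernel_cross <- function(A, B, th) {
  th["sf2"] * exp(-0.5 * .sqdist(A, B) / th["ell"]^2) +
    th["sl2"] * tcrossprod(A, B)
}

# Cholesky with escalating jitter: try the exact matrix first, then add
# 1e-8 * mean(diag) scaled up tenfold until 1e-2 before giving up.
.chol_jitter <- function(K) {
  base <- mean(diag(K))
  for (eps in c(0, base * 10^seq(-8, -2))) {
    L <- tryCatch(chol(K + diag(eps, nrow(K))), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = eps))
  }
  stop("conditioning error: kernel matrix not positive definite even with jitter")
}

# Negative log marginal likelihood and its gradient in log-parameters.
.gpr_nll <- function(lp, Xs, yc, D2, XXt, grad = FALSE) {
  th <- exp(lp)
  n <- length(yc)
  E <- th[1] * exp(-0.5 * D2 / th[2]^2)
  K <- E + th[3] * XXt + diag(th[4], n)
  cj <- tryCatch(.chol_jitter(K), error = function(e) NULL)
  if (is.null(cj)) return(if (grad) list(value = 1e10, grad = rep(0, 4)) else 1e10)
  L <- cj$L
  a <- backsolve(L, forwardsolve(t(L), yc))
  nll <- 0.5 * sum(yc * a) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
  if (!is.finite(nll)) nll <- 1e10
  if (!grad) return(nll)
  Kinv <- chol2inv(L)
  W <- tcrossprod(a) - Kinv            # d lml = 0.5 tr(W dK)
  g <- c(
    sum(W * E),
    sum(W * (E * (D2 / th[2]^2))),
    sum(W * XXt) * th[3],
    sum(diag(W)) * th[4]
  ) * 0.5
  list(value = nll, grad = -g)
}

#' Fit a Gaussian-process regression of age on morphometric features
#'
#' Fits the normative brain-age model: a GP with RBF + linear + white-noise
#' covariance mapping 28 standardized network-wise morphometric features to
#' chronological age. Features are standardized with training means/SDs
#' (stored for prediction); the target is centred at its training mean.
#' Predictions are the standard GP posterior mean
#' `m(x*) = k*' (K + sn2 I)^-1 (y - ybar) + ybar`.
#'
#' @param x numeric matrix (participants x features) or a feature table,
#'   from which the 28 canonical feature columns are taken.
#' @param y ages in years; if `x` is a feature table, defaults to its
#'   `age` column.
#' @param kernel_config a [gpr_config()].
#' @param standardize standardize columns of `x` (default TRUE).
#' @return object of class `"gpr_model"` with `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals` and `plot` methods.
#' @export
fit_gpr <- function(x, y = NULL, kernel_config = gpr_config(),
                    standardize = TRUE) {
  if (is.data.frame(x)) {
    if (is.null(y)) y <- x$age
    x <- as.matrix(x[, feature_keys(), drop = FALSE])
  }
  x <- as.matrix(x)
  stopifnot(is.numeric(y), nrow(x) == length(y))
  if (anyNA(x) || anyNA(y)) stop("missing values in features or ages")
  if (nrow(x) < 3L) stop("need at least 3 training rows")
  ctr <- if (standardize) colMeans(x) else rep(0, ncol(x))
  scl <- if (standardize) apply(x, 2, sd) else rep(1, ncol(x))
  scl[scl == 0 | is.na(scl)] <- 1
  Xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  ym <- mean(y)
  yc <- y - ym
  D2 <- .sqdist(Xs, Xs)
  XXt <- tcrossprod(Xs)
  vy <- max(var(yc), 1e-8)
  d <- ncol(Xs)
  heur <- c(sf2 = vy, ell = max(stats::median(sqrt(D2[upper.tri(D2)])), 1e-3),
            sl2 = vy / max(d, 1), sn2 = 0.1 * vy)
  init <- if (!is.null(kernel_config$init)) {
    kernel_config$init[c("sf2", "ell", "sl2", "sn2")]
  } else heur
  trace <- list()
  if (kernel_config$optimize) {
    starts <- with_seed(kernel_config$seed, {
      s <- list(log(init))
      for (i in seq_len(max(kernel_config$n_restarts - 1L, 0L))) {
        s[[i + 1L]] <- log(init) + rnorm(4, 0, 1)
      }
      s
    })
    best <- NULL
    for (i in seq_along(starts)) {
      fitres <- tryCatch(
        optim(starts[[i]],
              fn = function(lp) .gpr_nll(lp, Xs, yc, D2, XXt),
              gr = function(lp) .gpr_nll(lp, Xs, yc, D2, XXt, grad = TRUE)$grad,
              method = "L-BFGS-B", lower = rep(-15, 4), upper = rep(15, 4),
              control = list(maxit = kernel_config$maxit)),
        error = function(e) NULL)
      if (is.null(fitres)) next
      trace[[i]] <- list(start = exp(starts[[i]]), value = fitres$value,
                         convergence = fitres$convergence)
      if (is.null(best) || fitres$value < best$value) best <- fitres
    }
    if (is.null(best) || best$value >= 1e10) {
      stop("optimization error: log marginal likelihood not finite at any start")
    }
    lp <- best$par
  } else {
    lp <- log(init)
  }
  th <- exp(lp)
  names(th) <- c("sf2", "ell", "sl2", "sn2")
  K <- th["sf2"] * exp(-0.5 * D2 / th["ell"]^2) + th["sl2"] * XXt +
    diag(th["sn2"], nrow(Xs))
  cj <- .chol_jitter(K)
  alpha <- backsolve(cj$L, forwardsolve(t(cj$L), yc))
  model <- structure(list(
    theta = th, x_center = ctr, x_scale = scl, y_mean = ym,
    Xs = Xs, y = y, alpha = alpha, L = cj$L, jitter = cj$jitter,
    lml = -.gpr_nll(lp, Xs, yc, D2, XXt),
    opt_trace = trace, config = kernel_config,
    feature_names = colnames(x)
  ), class = "gpr_model")
  if (!all(is.finite(predict(model, x)))) {
    stop("non-finite predictions on training inputs")
  }
  model
}

#' Predict ages with a fitted GP model
#'
#' @param object a [fit_gpr()] model.
#' @param newdata matrix or feature table with the same feature schema as
#'   training.
#' @param ... unused.
#' @return numeric vector of predicted ages (years).
#' @export
predict.gpr_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    if (!all(object$feature_names %in% names(newdata))) {
      stop("schema error: missing feature column(s): ",
           paste(setdiff(object$feature_names, names(newdata)), collapse = ", "))
    }
    newdata <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  }
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$Xs)) {
    stop("schema error: expected ", ncol(object$Xs), " features, got ",
         ncol(newdata))
  }
  Xn <- sweep(sweep(newdata, 2, object$x_center), 2, object$x_scale, "/")
  Ks <- .kernel_cross(Xn, object$Xs, object$theta)
  drop(object$y_mean + Ks %*% object$alpha)
}

#' @export
fitted.gpr_model <- function(object, ...) {
  predict(object, sweep(sweep(object$Xs, 2, object$x_scale, "*"), 2,
                        -object$x_center))
}

#' @export
residuals.gpr_model <- function(object, ...) {
  object$y - fitted(object)
}

#' @export
coef.gpr_model <- function(object, ...) object$theta

#' @export
print.gpr_model <- function(x, ...) {
  cat("Gaussian-process brain-age model (RBF + linear + noise kernel)\n")
  cat(sprintf("  n = %d, d = %d, log marginal likelihood = %.2f\n",
              nrow(x$Xs), ncol(x$Xs), x$lml))
  cat(sprintf("  sf2 = %.4g  ell = %.4g  sl2 = %.4g  sn2 = %.4g\n",
              x$theta["sf2"], x$theta["ell"], x$theta["sl2"], x$theta["sn2"]))
  invisible(x)
}

#' @export
summary.gpr_model <- function(object, ...) {
  r <- residuals(object)
  out <- list(theta = object$theta, lml = object$lml,
              n = nrow(object$Xs), d = ncol(object$Xs),
              train_mae = mean(abs(r)),
              train_r2 = cor(fitted(object), object$y)^2,
              jitter = object$jitter)
  class(out) <- "summary.gpr_model"
  out
}

#' @export
print.summary.gpr_model <- function(x, ...) {
  cat("GP brain-age model summary\n")
  cat(sprintf("  n = %d, d = %d\n", x$n, x$d))
  cat(sprintf("  log marginal likelihood: %.2f (jitter %.3g)\n", x$lml, x$jitter))
  cat("  hyperparameters:\n")
  print(round(x$theta, 5))
  cat(sprintf("  in-sample MAE = %.2f yr, R^2 = %.3f\n", x$train_mae, x$train_r2))
  invisible(x)
}

#' @export
plot.gpr_model <- function(x, ...) {
  f <- fitted(x)
  plot(x$y, f, xlab = "chronological age (yr)",
       ylab = "fitted brain age (yr)", ...)
  abline(0, 1, lty = 2)
  invisible(x)
}
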