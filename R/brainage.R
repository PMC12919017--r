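#' @importFrom stats var median
NULL

#' Estimate the age-bias correction from out-of-fold predictions
#'
#' Brain-age predictions regress toward the training mean, so the gap
#' (predicted minus chronological) depends systematically on age. The
#' correction is the OLS fit `gap = beta0 + beta1 * age` estimated on
#' out-of-fold training predictions; corrected predictions subtract this
#' fitted trend, leaving the training-set corrected gap exactly orthogonal
#' to age.
#'
#' @param chronological ages (years), length >= 10.
#' @param predicted out-of-fold predicted ages (years).
#' @return object of class `"bias_correction"` with elements `beta0`
#'   (years) and `beta1` (dimensionless).
#' @export
fit_bias_correction <- function(chronological, predicted) {
  stopifnot(length(chronological) == length(predicted))
  if (length(chronological) < 10L) {
    stop("need >= 10 points to estimate the bias correction")
  }
  if (var(chronological) == 0) {
    stop("degenerate error: chronological age has zero variance")
  }
  gap <- predicted - chronological
  fit <- lm.fit(cbind(1, chronological), gap)
  structure(list(beta0 = unname(fit$coefficients[1]),
                 beta1 = unname(fit$coefficients[2])),
            class = "bias_correction")
}

#' @export
print.bias_correction <- function(x, ...) {
  cat(sprintf("Age-bias correction: gap = %.4f %+.4f * age\n", x$beta0, x$beta1))
  invisible(x)
}

#' Apply an age-bias correction
#'
#' @param correction a [fit_bias_correction()] object (or NULL for the
#'   identity correction).
#' @param predicted raw predicted ages.
#' @param chronological chronological ages.
#' @return corrected predicted ages.
#' @export
apply_bias_correction <- function(correction, predicted, chronological) {
  if (is.null(correction)) return(predicted)
  stopifnot(inherits(correction, "bias_correction"))
  predicted - (correction$beta0 + correction$beta1 * chronological)
}

#' Compute per-participant brain-age-gap records
#'
#' BAG is the bias-corrected predicted age minus chronological age; the
#' correction coefficients must come from the training cohort's
#' out-of-fold regression, never from the data being scored.
#'
#' @param ages chronological ages (years).
#' @param predicted raw predicted ages (years).
#' @param correction a [fit_bias_correction()] object, or NULL for no
#'   correction.
#' @param participant_id optional ids.
#' @return data.frame with columns `participant_id`, `age`,
#'   `predicted_raw`, `predicted_corrected`, `bag`.
#' @export
compute_bag <- function(ages, predicted, correction = NULL,
                        participant_id = NULL) {
  if (length(ages) != length(predicted)) {
    stop("argument error: ages and predicted must have equal length")
  }
  if (is.null(participant_id)) {
    participant_id <- if (length(ages)) sprintf("P%04d", seq_along(ages)) else character(0)
  }
  corrected <- apply_bias_correction(correction, predicted, ages)
  data.frame(participant_id = as.character(participant_id),
             age = as.numeric(ages),
             predicted_raw = as.numeric(predicted),
             predicted_corrected = as.numeric(corrected),
             bag = as.numeric(corrected - ages),
             stringsAsFactors = FALSE)
}

#' Prediction accuracy metrics
#'
#' Mean absolute error and squared Pearson correlation between
#' chronological and predicted age, optionally per group. Note that the
#' squared correlation is sign-blind: perfectly anti-correlated
#' predictions also give R^2 = 1.
#'
#' @param ages chronological ages.
#' @param predicted predicted ages.
#' @param group optional group labels for per-group metrics.
#' @return list with `mae`, `r2`, `n`, and (when `group` is given)
#'   `per_group` data.frame.
#' @export
prediction_metrics <- function(ages, predicted, group = NULL) {
  stopifnot(length(ages) == length(predicted))
  if (length(ages) < 2L) stop("degenerate error: need >= 2 observations for R^2")
  if (sd(ages) == 0 || sd(predicted) == 0) {
    stop("degenerate error: zero variance in ages or predictions")
  }
  out <- list(mae = mean(abs(predicted - ages)),
              r2 = cor(ages, predicted)^2,
              n = length(ages))
  if (!is.null(group)) {
    g <- factor(group)
    per <- do.call(rbind, lapply(levels(g), function(l) {
      i <- g == l
      r2 <- if (sum(i) >= 2 && sd(ages[i]) > 0 && sd(predicted[i]) > 0) {
        cor(ages[i], predicted[i])^2
      } else NA_real_
      data.frame(group = l, n = sum(i),
                 mae = mean(abs(predicted[i] - ages[i])), r2 = r2,
                 stringsAsFactors = FALSE)
    }))
    out$per_group <- per
  }
  out
}

# Stratified-by-age-quantile fold assignment: rows are binned by age
# quantile, shuffled within bin, and dealt round-robin so every fold spans
# the age range.
.age_stratified_folds <- function(age, folds, seed) {
  with_seed(seed, {
    n <- length(age)
    n_bins <- max(min(folds, floor(n / folds)), 1L)
    br <- unique(quantile(age, probs = seq(0, 1, length.out = n_bins + 1)))
    bin <- cut(age, breaks = br, include.lowest = TRUE, labels = FALSE)
    fold <- integer(n)
    offset <- 0L
    for (bb in sort(unique(bin))) {
      idx <- sample(which(bin == bb))
      fold[idx] <- ((seq_along(idx) - 1L + offset) %% folds) + 1L
      offset <- offset + length(idx)
    }
    fold
  })
}

#' Cross-validate the brain-age model on a training table
#'
#' Age-quantile-stratified k-fold cross-validation: each row is predicted
#' exactly once by a model fitted without it, the age-bias correction is
#' estimated from the pooled out-of-fold predictions, and accuracy metrics
#' are reported before and after correction.
#'
#' @param table feature table with an `age` column.
#' @param folds number of folds (default 5).
#' @param seed seed for fold assignment.
#' @param kernel_config [gpr_config()] passed to each fold's fit.
#' @return object of class `"brainage_cv"`: fold assignment, out-of-fold
#'   records, per-fold MAE, pooled metrics raw/corrected, and the fitted
#'   [fit_bias_correction()].
#' @export
cross_validate <- function(table, folds = 5L, seed = 1L,
                           kernel_config = gpr_config()) {
  stopifnot(is.data.frame(table), "age" %in% names(table))
  n <- nrow(table)
  if (folds < 2L) stop("argument error: folds must be >= 2")
  if (n < folds) stop("argument error: fewer rows than folds")
  fold <- .age_stratified_folds(table$age, folds, seed)
  pred <- rep(NA_real_, n)
  for (f in seq_len(folds)) {
    test <- fold == f
    m <- fit_gpr(table[!test, , drop = FALSE], kernel_config = kernel_config)
    pred[test] <- predict(m, table[test, , drop = FALSE])
  }
  bias <- fit_bias_correction(table$age, pred)
  corrected <- apply_bias_correction(bias, pred, table$age)
  per_fold_mae <- vapply(seq_len(folds), function(f) {
    mean(abs(corrected[fold == f] - table$age[fold == f]))
  }, numeric(1))
  structure(list(
    fold = fold,
    oof = compute_bag(table$age, pred, bias,
                      participant_id = table$participant_id),
    bias = bias,
    per_fold_mae = per_fold_mae,
    metrics_raw = prediction_metrics(table$age, pred),
    metrics_corrected = prediction_metrics(table$age, corrected)
  ), class = "brainage_cv")
}

#' @export
print.brainage_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validated brain-age model (n = %d)\n",
              length(x$per_fold_mae), nrow(x$oof)))
  cat(sprintf("  pooled MAE: raw %.2f yr, corrected %.2f +/- %.2f yr (per-fold SD)\n",
              x$metrics_raw$mae, x$metrics_corrected$mae, sd(x$per_fold_mae)))
  cat(sprintf("  pooled R^2: raw %.3f, corrected %.3f\n",
              x$metrics_raw$r2, x$metrics_corrected$r2))
  print(x$bias)
  invisible(x)
}
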