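#' @importFrom stats aggregate ave
NULL

# Evaluate a model (gpr_model or plain function) on a feature matrix.
.eval_model <- function(model, X) {
  if (is.function(model)) {
    as.numeric(model(X))
  } else {
    as.numeric(predict(model, X))
  }
}

#' Select an age-matched reference set from the training cohort
#'
#' Picks the `k` training participants closest in age to the target; the
#' mean model prediction over these rows is the attribution baseline.
#' Age ties are broken by ascending participant id, so selection is
#' deterministic.
#'
#' @param target_age target participant's age (years).
#' @param training_table training feature table.
#' @param k reference-set size (default 10).
#' @return list of class `"reference_set"` with `indices` (rows of
#'   `training_table`), `rows` (their feature sub-table), `ages`, `k` and
#'   `target_age`.
#' @export
select_reference_set <- function(target_age, training_table, k = 10L) {
  stopifnot(is.data.frame(training_table), "age" %in% names(training_table))
  n <- nrow(training_table)
  if (k > n) stop("argument error: k exceeds training size")
  dist <- abs(training_table$age - target_age)
  id <- if ("participant_id" %in% names(training_table)) {
    as.character(training_table$participant_id)
  } else sprintf("%09d", seq_len(n))
  ord <- order(dist, id)
  idx <- ord[seq_len(k)]
  structure(list(indices = idx,
                 rows = training_table[idx, , drop = FALSE],
                 ages = training_table$age[idx],
                 k = as.integer(k),
                 target_age = target_age),
            class = "reference_set")
}

# k x d reference feature matrix from a reference set (or bare matrix).
.ref_matrix <- function(ref) {
  if (inherits(ref, "reference_set")) {
    as.matrix(ref$rows[, feature_keys(), drop = FALSE])
  } else {
    as.matrix(ref)
  }
}

#' Sampled Shapley attribution of one prediction
#'
#' Attributes the model's prediction for one participant to the individual
#' features with an interventional value function: the value of a feature
#' coalition S is the mean model prediction over the reference rows with
#' the features in S replaced by the participant's values. Shapley values
#' are estimated by antithetic permutation sampling (each sampled feature
#' order is paired with its reverse); along each permutation the marginal
#' contributions telescope, so the estimate satisfies the efficiency
#' identity sum(phi) = f(x) - baseline by construction.
#'
#' @param model a [fit_gpr()] model or a function mapping a feature matrix
#'   to predictions.
#' @param x a single feature row (numeric vector, 1-row matrix, or 1-row
#'   feature table).
#' @param ref a [select_reference_set()] object or a reference feature
#'   matrix.
#' @param n_permutations number of sampled permutations (>= 1; rounded up
#'   to an even count for antithetic pairing).
#' @param seed RNG seed.
#' @return list of class `"shap_values"`: `phi` (named, in model output
#'   units, i.e. years), `se` (Monte-Carlo standard errors), `baseline`,
#'   `prediction`, `n_permutations`, `seed`.
#' @export
shapley_attribution <- function(model, x, ref, n_permutations = 512L,
                                seed = 1L) {
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  R <- .ref_matrix(ref)
  if (is.data.frame(x)) x <- as.matrix(x[, colnames(R), drop = FALSE])
  x <- as.numeric(x)
  d <- ncol(R)
  if (length(x) != d) stop("schema error: x has ", length(x),
                           " features, reference has ", d)
  k <- nrow(R)
  n_pairs <- ceiling(n_permutations / 2)
  fx <- mean(.eval_model(model, matrix(x, k, d, byrow = TRUE,
                                       dimnames = list(NULL, colnames(R)))))
  v0 <- mean(.eval_model(model, R))
  perm_phi <- matrix(0, 2L * n_pairs, d)
  perms <- with_seed(seed, {
    lapply(seq_len(n_pairs), function(i) sample.int(d))
  })
  for (pidx in seq_len(n_pairs)) {
    for (anti in 1:2) {
      pi_ <- if (anti == 1) perms[[pidx]] else rev(perms[[pidx]])
      # walk the permutation; hybrid rows for all prefixes in one batch
      H <- matrix(NA_real_, (d + 1L) * k, d)
      Z <- R
      H[seq_len(k), ] <- Z
      for (j in seq_len(d)) {
        Z[, pi_[j]] <- x[pi_[j]]
        H[j * k + seq_len(k), ] <- Z
      }
      colnames(H) <- colnames(R)
      vals <- .eval_model(model, H)
      vmeans <- rowMeans(matrix(vals, nrow = d + 1L, byrow = TRUE))
      contrib <- diff(vmeans)
      perm_phi[(pidx - 1L) * 2L + anti, pi_] <- contrib
    }
  }
  phi <- colMeans(perm_phi)
  # MC uncertainty from the spread of antithetic-pair averages
  pair_means <- (perm_phi[seq(1, 2 * n_pairs, 2), , drop = FALSE] +
                   perm_phi[seq(2, 2 * n_pairs, 2), , drop = FALSE]) / 2
  se <- if (n_pairs > 1) {
    apply(pair_means, 2, sd) / sqrt(n_pairs)
  } else rep(NA_real_, d)
  names(phi) <- names(se) <- colnames(R)
  structure(list(phi = phi, se = se, baseline = v0, prediction = fx,
                 n_permutations = 2L * n_pairs, seed = seed),
            class = "shap_values")
}

#' @export
print.shap_values <- function(x, ...) {
  cat(sprintf("Shapley attribution: f(x) = %.3f, baseline = %.3f, sum(phi) = %.3f\n",
              x$prediction, x$baseline, sum(x$phi)))
  cat(sprintf("  %d permutations, max MC SE = %.4f\n", x$n_permutations,
              suppressWarnings(max(x$se))))
  top <- sort(abs(x$phi), decreasing = TRUE)[seq_len(min(5, length(x$phi)))]
  cat("  largest |phi|:\n")
  print(round(x$phi[names(top)], 4))
  invisible(x)
}

#' Exact Shapley values by coalition enumeration
#'
#' Enumerates all 2^d feature coalitions under the same interventional
#' value function as [shapley_attribution()]; feasible for d <= 15.
#' Serves as the exact oracle against which the sampler is checked.
#'
#' @inheritParams shapley_attribution
#' @return named numeric vector of exact Shapley values.
#' @export
exact_shapley_oracle <- function(model, x, ref) {
  R <- .ref_matrix(ref)
  if (is.data.frame(x)) x <- as.matrix(x[, colnames(R), drop = FALSE])
  x <- as.numeric(x)
  d <- ncol(R)
  if (d > 15L) stop("size error: exact enumeration limited to d <= 15")
  k <- nrow(R)
  n_sets <- 2^d
  # hybrid rows for every coalition in one batch
  H <- matrix(NA_real_, n_sets * k, d)
  for (s in 0:(n_sets - 1L)) {
    inS <- as.logical(bitwAnd(s, 2^(0:(d - 1L))))
    Z <- R
    Z[, inS] <- matrix(x[inS], k, sum(inS), byrow = TRUE)
    H[s * k + seq_len(k), ] <- Z
  }
  colnames(H) <- colnames(R)
  vals <- rowMeans(matrix(.eval_model(model, H), nrow = n_sets, byrow = TRUE))
  sizes <- vapply(0:(n_sets - 1L), function(s) sum(bitwAnd(s, 2^(0:(d - 1L))) > 0), 1L)
  # weight |S|!(d-|S|-1)!/d! applies to coalitions S not containing j,
  # so the full set's (undefined) weight is never used
  w <- numeric(n_sets)
  proper <- sizes < d
  w[proper] <- factorial(sizes[proper]) * factorial(d - sizes[proper] - 1L) /
    factorial(d)
  phi <- numeric(d)
  for (j in seq_len(d)) {
    bit <- 2^(j - 1L)
    noj <- which(bitwAnd(0:(n_sets - 1L), bit) == 0)
    phi[j] <- sum(w[noj] * (vals[noj + bit] - vals[noj]))
  }
  names(phi) <- colnames(R)
  phi
}

#' Global feature importance from a Shapley matrix
#'
#' Mean absolute Shapley value per feature across participants, with
#' per-network aggregation and ranking within each morphometric measure.
#'
#' @param shap participants x features matrix (or data.frame) of signed
#'   Shapley values with feature-key column names.
#' @return list of class `"importance_summary"`: `per_feature` and
#'   `per_cell` data.frames (the latter ranked within measure).
#' @export
global_importance <- function(shap) {
  M <- as.matrix(shap)
  if (nrow(M) < 1L) stop("need >= 1 participant")
  imp <- colMeans(abs(M))
  info <- parse_feature_key(colnames(M))
  per_feature <- data.frame(info, importance = unname(imp),
                            stringsAsFactors = FALSE)
  per_cell <- per_feature
  per_cell$rank_in_measure <- ave(-per_cell$importance, per_cell$measure,
                                  FUN = rank)
  structure(list(per_feature = per_feature, per_cell = per_cell),
            class = "importance_summary")
}

#' @export
print.importance_summary <- function(x, ...) {
  cat("Global feature importance (mean |phi| across participants)\n")
  for (m in unique(x$per_cell$measure)) {
    sub <- x$per_cell[x$per_cell$measure == m, ]
    sub <- sub[order(sub$rank_in_measure), ]
    cat(sprintf("  %-13s %s\n", m,
                paste(sprintf("%s=%.3f", sub$network, sub$importance),
                      collapse = " ")))
  }
  invisible(x)
}

#' Reshape signed Shapley values to long network-by-measure format
#'
#' One row per participant, network and measure (28 rows per participant),
#' carrying the participant's group and covariates for mixed-effects
#' modelling. Signed values pass through unchanged; each cell holds the
#' single feature of that network-measure pair.
#'
#' @param shap participants x features matrix of signed Shapley values;
#'   rownames (or the `participant_id` argument) identify participants.
#' @param table clinical feature table supplying group and covariates.
#' @param participant_id optional ids aligned with `shap` rows.
#' @return long data.frame with columns `participant_id`, `network`,
#'   `measure`, `phi`, group labels, and covariates.
#' @export
aggregate_signed_shap <- function(shap, table, participant_id = NULL) {
  M <- as.matrix(shap)
  ids <- participant_id
  if (is.null(ids)) ids <- rownames(M)
  if (is.null(ids)) stop("integrity error: no participant ids on shap matrix")
  if (!all(ids %in% table$participant_id)) {
    stop("integrity error: shap ids missing from table: ",
         paste(setdiff(ids, table$participant_id), collapse = ", "))
  }
  info <- parse_feature_key(colnames(M))
  long <- data.frame(
    participant_id = rep(ids, each = ncol(M)),
    network = rep(info$network, times = nrow(M)),
    measure = rep(info$measure, times = nrow(M)),
    phi = as.vector(t(M)),
    stringsAsFactors = FALSE)
  meta_cols <- intersect(c("group", "hiv", "cu", "nci", .covariate_cols()),
                         names(table))
  meta <- table[match(long$participant_id, table$participant_id),
                meta_cols, drop = FALSE]
  rownames(meta) <- NULL
  cbind(long, meta)
}
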