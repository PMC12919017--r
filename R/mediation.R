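#' @importFrom stats quantile
NULL

# Point estimates of all path quantities on one (re)sample. X matrices are
# passed pre-built; idx selects the bootstrap rows.
.mediation_paths <- function(idx, d1, d2, bag, y, Z) {
  Xm <- cbind(1, d1 = d1[idx], d2 = d2[idx], Z[idx, , drop = FALSE])
  Xo <- cbind(1, bag = bag[idx], d1 = d1[idx], d2 = d2[idx],
              Z[idx, , drop = FALSE])
  fm <- lm.fit(Xm, bag[idx])
  fo <- lm.fit(Xo, y[idx])
  a1 <- unname(fm$coefficients[2]); a2 <- unname(fm$coefficients[3])
  b <- unname(fo$coefficients[2])
  c1p <- unname(fo$coefficients[3]); c2p <- unname(fo$coefficients[4])
  ind1 <- a1 * b; ind2 <- a2 * b
  sy <- sd(y[idx]); s1 <- sd(d1[idx]); s2 <- sd(d2[idx])
  c(a1 = a1, a2 = a2, b = b,
    direct1 = c1p, direct2 = c2p,
    indirect1 = ind1, indirect2 = ind2,
    total1 = c1p + ind1, total2 = c2p + ind2,
    indirect_diff = ind2 - ind1,
    indirect1_std = ind1 * s1 / sy, indirect2_std = ind2 * s2 / sy,
    total1_std = (c1p + ind1) * s1 / sy, total2_std = (c2p + ind2) * s2 / sy,
    direct1_std = c1p * s1 / sy, direct2_std = c2p * s2 / sy)
}

#' Bootstrap path-model mediation of impairment by the brain-age gap
#'
#' Two-equation path model with BAG as mediator between disorder burden
#' and impairment: (i) a linear model of BAG on the two burden dummies
#' (1 vs 0 and 2 vs 0 disorders) and covariates gives paths `a1`, `a2`;
#' (ii) a linear-probability model of the NCI flag on BAG, the dummies and
#' covariates gives the mediator path `b` and direct effects. Indirect
#' effects are `a * b`; with both equations linear over the same rows and
#' covariates, total = direct + indirect holds exactly on every draw.
#' Standardized coefficients scale each effect by sd(exposure)/sd(outcome).
#' Inference is by seeded percentile bootstrap over participants, including
#' the between-contrast difference in indirect effects.
#'
#' @param group disorder count (0/1/2); both non-zero levels must be
#'   present.
#' @param bag brain-age gaps (years), the mediator.
#' @param nci binary impairment flags, the outcome.
#' @param covariates data.frame of adjustment covariates.
#' @param n_boot bootstrap draws (>= 200).
#' @param seed RNG seed.
#' @param conf CI level (default 0.95).
#' @return object of class `"mediation_result"`: `estimates` data.frame
#'   (estimate, bootstrap SE, percentile CI, bootstrap p per quantity),
#'   the bootstrap draws, and the maximum absolute total-decomposition
#'   error across draws.
#' @export
mediation_model <- function(group, bag, nci, covariates = NULL,
                            n_boot = 2000L, seed = 1L, conf = 0.95) {
  if (n_boot < 200L) stop("n_boot must be >= 200")
  g <- as.integer(as.character(factor(group)))
  if (!all(c(1L, 2L) %in% g)) stop("both burden dummies must be present")
  if (sd(bag) == 0) stop("degenerate mediator variance")
  d1 <- as.numeric(g == 1L); d2 <- as.numeric(g == 2L)
  y <- as.numeric(nci)
  n <- length(y)
  Z <- as.matrix(.as_cov_df(covariates, n))
  if (ncol(Z)) storage.mode(Z) <- "double"
  est <- .mediation_paths(seq_len(n), d1, d2, bag, y, Z)
  # exact decomposition check against the direct total-effect regression
  Xt <- cbind(1, d1 = d1, d2 = d2, Z)
  ft <- lm.fit(Xt, y)
  decomp_err <- max(abs(c(ft$coefficients[2] - est["total1"],
                          ft$coefficients[3] - est["total2"])))
  draws <- with_seed(seed, {
    t(replicate(n_boot, .mediation_paths(sample.int(n, replace = TRUE),
                                         d1, d2, bag, y, Z)))
  })
  alpha <- (1 - conf) / 2
  boot_p <- function(v) {
    v <- v[is.finite(v)]
    min(1, 2 * min(mean(v <= 0), mean(v >= 0)))
  }
  qs <- apply(draws, 2, quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE)
  estimates <- data.frame(
    quantity = names(est),
    estimate = unname(est),
    boot_se = apply(draws, 2, sd, na.rm = TRUE),
    ci_lo = qs[1, ], ci_hi = qs[2, ],
    p = apply(draws, 2, boot_p),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(estimates = estimates, draws = draws,
                 n = n, n_boot = n_boot, seed = seed, conf = conf,
                 decomposition_max_abs_err = decomp_err),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Bootstrap path-model mediation (n = %d, %d draws)\n",
              x$n, x$n_boot))
  show <- c("a1", "a2", "b", "indirect1", "indirect2",
            "direct1", "direct2", "total1", "total2", "indirect_diff")
  print(x$estimates[x$estimates$quantity %in% show, ],
        digits = 3, row.names = FALSE)
  cat(sprintf("max |total - (direct + indirect)| = %.2e\n",
              x$decomposition_max_abs_err))
  invisible(x)
}
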