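#' @importFrom stats lm glm binomial gaussian anova vcov pt pf pchisq
#'   p.adjust qnorm model.matrix as.formula terms update rbinom fitted
#' @importFrom utils combn
NULL

.as_cov_df <- function(covariates, n) {
  if (is.null(covariates)) return(data.frame(row.names = seq_len(n)))
  cov <- as.data.frame(covariates)
  stopifnot(nrow(cov) == n)
  cov
}

#' Classify neurocognitive impairment from domain T-scores
#'
#' A participant is flagged as impaired when at least `min_domains`
#' cognitive domains have fully adjusted T-scores at or below
#' `mean - threshold_sd * sd` (boundary inclusive: a score exactly 1 SD
#' below the mean counts as impaired).
#'
#' @param domain_tscores data.frame or matrix, one column per domain.
#' @param mean,sd normative mean and SD of the T-scores (50 and 10).
#' @param threshold_sd impairment cut in SD units (default 1.0).
#' @param min_domains minimum number of impaired domains (default 2).
#' @return logical flags (NA for rejected rows); rows with missing domain
#'   values are rejected and reported via the `"report"` attribute.
#' @export
classify_nci <- function(domain_tscores, mean = 50, sd = 10,
                         threshold_sd = 1.0, min_domains = 2L) {
  M <- as.matrix(domain_tscores)
  if (ncol(M) < 2L) stop("need >= 2 cognitive domains")
  cut <- mean - threshold_sd * sd
  bad <- which(apply(M, 1, anyNA))
  flags <- rowSums(M <= cut) >= min_domains
  flags[bad] <- NA
  attr(flags, "report") <- data.frame(
    row = bad,
    problem = rep("missing domain value", length(bad)),
    stringsAsFactors = FALSE)
  flags
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return q-values (step-up with monotonicity enforcement).
#' @export
fdr_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("argument error: p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

# Shared machinery: OLS of an outcome on a 3-level disorder-count factor
# plus covariates, Type III F tests (sum-to-zero contrasts), and the three
# pairwise group contrasts with BH adjustment.
.group_model <- function(outcome, group, covariates, outcome_name = "outcome") {
  g <- factor(group)
  if (nlevels(g) < 2L) stop("need >= 2 non-empty groups")
  dat <- data.frame(.y = outcome, group = g,
                    .as_cov_df(covariates, length(outcome)))
  form <- as.formula(paste(".y ~", paste(setdiff(names(dat), ".y"),
                                         collapse = " + ")))
  fit_sum <- do.call(lm, list(formula = form, data = dat,
                              contrasts = list(group = "contr.sum")))
  if (any(is.na(coef(fit_sum)))) stop("design error: rank-deficient design")
  a3 <- car::Anova(fit_sum, type = 3)
  fit_trt <- lm(form, data = dat)   # treatment coding for contrasts
  cf <- coef(fit_trt); V <- vcov(fit_trt)
  lev <- levels(g)
  pairs <- combn(seq_along(lev), 2)
  contrasts <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    lo <- pairs[1, i]; hi <- pairs[2, i]
    cvec <- rep(0, length(cf)); names(cvec) <- names(cf)
    if (hi > 1) cvec[paste0("group", lev[hi])] <- 1
    if (lo > 1) cvec[paste0("group", lev[lo])] <- -1
    est <- sum(cvec * cf)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    tval <- est / se
    data.frame(contrast = paste(lev[hi], "-", lev[lo]),
               estimate = est, se = se, t = tval,
               df = fit_trt$df.residual,
               p = 2 * pt(abs(tval), fit_trt$df.residual, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  contrasts$q <- fdr_adjust(contrasts$p)
  structure(list(outcome = outcome_name,
                 anova = a3,
                 F_group = a3["group", "F value"],
                 df_group = c(a3["group", "Df"], a3["Residuals", "Df"]),
                 p_group = a3["group", "Pr(>F)"],
                 contrasts = contrasts,
                 coefficients = cf,
                 fit = fit_trt),
            class = "group_model_result")
}

#' Dose-dependent group model for the brain-age gap
#'
#' OLS of BAG on the disorder-count factor and covariates with a Type III
#' F test for the group term (sum-to-zero contrasts) and all pairwise
#' group contrasts, BH-adjusted.
#'
#' @param bag brain-age gaps (years).
#' @param group disorder count (0/1/2) or any factor.
#' @param covariates data.frame of adjustment covariates (age, sex,
#'   education, zung, euler, motion).
#' @return object of class `"group_model_result"`.
#' @export
bag_group_model <- function(bag, group, covariates = NULL) {
  .group_model(bag, group, covariates, "bag")
}

#' Comorbidity model for a single morphometric feature
#'
#' Identical machinery to [bag_group_model()] applied to one
#' network-by-measure feature, used to check whether attribution-identified
#' comorbidity effects correspond to measurable structural differences.
#'
#' @param feature numeric feature vector.
#' @inheritParams bag_group_model
#' @return object of class `"group_model_result"`.
#' @export
morphometric_validation_model <- function(feature, group, covariates = NULL) {
  .group_model(feature, group, covariates, "feature")
}

#' @export
print.group_model_result <- function(x, ...) {
  cat(sprintf("Group model for %s: Type III F(%d, %d) = %.2f, p = %.3g\n",
              x$outcome, x$df_group[1], x$df_group[2], x$F_group, x$p_group))
  cat("Pairwise contrasts (BH-adjusted):\n")
  print(x$contrasts, digits = 4, row.names = FALSE)
  invisible(x)
}

# Logistic regression with LR test for a focal term, odds ratios, and
# marginally standardized outcome probabilities with bootstrap CIs.
.logistic_focal <- function(outcome, focal, covariates, focal_name,
                            n_boot = 500L, seed = 1L, conf = 0.95) {
  y <- as.integer(outcome)
  if (length(unique(y[!is.na(y)])) < 2L) stop("outcome must have both classes")
  dat <- data.frame(.y = y, .as_cov_df(covariates, length(y)))
  dat[[focal_name]] <- focal
  rhs <- setdiff(names(dat), ".y")
  form <- as.formula(paste(".y ~", paste(rhs, collapse = " + ")))
  form0 <- as.formula(paste(".y ~", paste(setdiff(rhs, focal_name),
                                          collapse = " + "), "+ 1"))
  fit <- glm(form, data = dat, family = binomial())
  if (any(is.na(coef(fit)))) stop("design error: rank-deficient design")
  separation <- any(abs(coef(fit)) > 15) ||
    any(fitted(fit) > 1 - 1e-8) || any(fitted(fit) < 1e-8)
  if (separation) {
    warning("possible (quasi-)separation: coefficients may be unstable")
  }
  fit0 <- glm(form0, data = dat, family = binomial())
  lr <- anova(fit0, fit, test = "Chisq")
  z <- qnorm(1 - (1 - conf) / 2)
  cf <- coef(fit); se <- sqrt(diag(vcov(fit)))
  focal_idx <- grep(paste0("^", focal_name), names(cf))
  or <- data.frame(term = names(cf)[focal_idx],
                   log_or = cf[focal_idx],
                   or = exp(cf[focal_idx]),
                   ci_lo = exp(cf[focal_idx] - z * se[focal_idx]),
                   ci_hi = exp(cf[focal_idx] + z * se[focal_idx]),
                   p = 2 * stats::pnorm(abs(cf[focal_idx] / se[focal_idx]),
                                        lower.tail = FALSE),
                   stringsAsFactors = FALSE, row.names = NULL)
  # marginal standardization (G-computation)
  adj <- NULL
  if (is.factor(focal)) {
    std_one <- function(d) {
      vapply(levels(focal), function(l) {
        d2 <- d; d2[[focal_name]] <- factor(l, levels = levels(focal))
        mean(predict(glm(form, data = d, family = binomial()),
                     newdata = d2, type = "response"))
      }, numeric(1))
    }
    pt_est <- vapply(levels(focal), function(l) {
      d2 <- dat; d2[[focal_name]] <- factor(l, levels = levels(focal))
      mean(predict(fit, newdata = d2, type = "response"))
    }, numeric(1))
    boots <- with_seed(seed, {
      replicate(n_boot, {
        idx <- sample.int(nrow(dat), replace = TRUE)
        tryCatch(suppressWarnings(std_one(dat[idx, , drop = FALSE])),
                 error = function(e) rep(NA_real_, nlevels(focal)))
      })
    })
    ci <- apply(boots, 1, quantile,
                probs = c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
    adj <- data.frame(level = levels(focal), prob = pt_est,
                      ci_lo = ci[1, ], ci_hi = ci[2, ],
                      stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(list(focal = focal_name,
                 coefficients = cf,
                 lr_chisq = lr$Deviance[2], lr_df = lr$Df[2],
                 lr_p = lr$`Pr(>Chi)`[2],
                 odds_ratios = or,
                 adjusted_probabilities = adj,
                 separation = separation,
                 fit = fit),
            class = "logistic_result")
}

#' Logistic model of impairment on disorder burden
#'
#' Maximum-likelihood logistic regression of the NCI flag on the
#' disorder-count factor and covariates, with a likelihood-ratio chi-square
#' for the burden term, odds ratios versus the 0-disorder group (Wald 95%
#' CIs), and model-adjusted impairment probabilities per group by marginal
#' standardization (every participant's burden set counterfactually to
#' each level, predicted probabilities averaged) with percentile-bootstrap
#' CIs.
#'
#' @param nci binary impairment flags.
#' @param group disorder count (0/1/2).
#' @param covariates data.frame of adjustment covariates.
#' @param n_boot bootstrap draws for the adjusted-probability CIs.
#' @param seed RNG seed for the bootstrap.
#' @return object of class `"logistic_result"`.
#' @export
nci_burden_logistic <- function(nci, group, covariates = NULL,
                                n_boot = 500L, seed = 1L) {
  .logistic_focal(nci, factor(group), covariates, "group",
                  n_boot = n_boot, seed = seed)
}

#' Logistic model of impairment on the brain-age gap
#'
#' As [nci_burden_logistic()] with a continuous BAG predictor; the odds
#' ratio is per year of BAG.
#'
#' @param nci binary impairment flags.
#' @param bag brain-age gaps (years).
#' @inheritParams nci_burden_logistic
#' @return object of class `"logistic_result"`.
#' @export
nci_bag_logistic <- function(nci, bag, covariates = NULL,
                             n_boot = 500L, seed = 1L) {
  if (sd(bag) == 0) stop("degenerate-predictor error: bag is constant")
  .logistic_focal(nci, as.numeric(bag), covariates, "bag",
                  n_boot = n_boot, seed = seed)
}

#' @export
print.logistic_result <- function(x, ...) {
  cat(sprintf("Logistic model, focal term '%s': LR chi^2(%d) = %.2f, p = %.3g\n",
              x$focal, x$lr_df, x$lr_chisq, x$lr_p))
  cat("Odds ratios:\n")
  print(x$odds_ratios, digits = 3, row.names = FALSE)
  if (!is.null(x$adjusted_probabilities)) {
    cat("Model-adjusted probabilities:\n")
    print(x$adjusted_probabilities, digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' Factorial HIV-by-cocaine-use model
#'
#' Fits `outcome ~ hiv * cu + covariates` with a linear (gaussian) or
#' logistic link and reports a Wald chi-square per term (Type III).
#'
#' @param outcome numeric or binary outcome.
#' @param hiv,cu binary indicators.
#' @param covariates data.frame of adjustment covariates.
#' @param family `"linear"` or `"logistic"`.
#' @return object of class `"factorial_result"` with the per-term
#'   chi-square table and the fitted model.
#' @export
factorial_hiv_cu <- function(outcome, hiv, cu, covariates = NULL,
                             family = c("linear", "logistic")) {
  family <- match.arg(family)
  if (all(hiv == cu) || all(hiv == 1 - cu)) {
    stop("rank-deficiency error: hiv and cu are collinear")
  }
  cells <- table(factor(hiv, levels = 0:1), factor(cu, levels = 0:1))
  interaction_ok <- all(cells > 0)
  if (!interaction_ok) {
    warning("empty hiv x cu cell: the interaction is not estimable and is ",
            "dropped; main effects reported from the additive model")
  }
  dat <- data.frame(.y = outcome, hiv = hiv, cu = cu,
                    .as_cov_df(covariates, length(outcome)))
  main <- if (interaction_ok) "hiv * cu" else "hiv + cu"
  rhs <- c(main, setdiff(names(dat), c(".y", "hiv", "cu")))
  form <- as.formula(paste(".y ~", paste(rhs, collapse = " + ")))
  fam <- if (family == "linear") gaussian() else binomial()
  fit <- glm(form, data = dat, family = fam)
  if (any(is.na(coef(fit)))) stop("rank-deficiency error: design is singular")
  aw <- car::Anova(fit, type = 3, test.statistic = "Wald")
  chisq <- setNames(aw$Chisq, rownames(aw))
  p <- setNames(aw$`Pr(>Chisq)`, rownames(aw))
  if (!interaction_ok) {
    chisq["hiv:cu"] <- NA_real_
    p["hiv:cu"] <- NA_real_
  }
  structure(list(family = family, anova = aw, fit = fit,
                 interaction_estimable = interaction_ok,
                 chisq = chisq, p = p),
            class = "factorial_result")
}

#' @export
print.factorial_result <- function(x, ...) {
  cat(sprintf("HIV x CU factorial model (%s link), Wald chi-square per term:\n",
              x$family))
  print(x$anova)
  invisible(x)
}

#' Exact Fisher test for a 2 x C contingency table
#'
#' Exact conditional test: the p-value is the total probability of all
#' tables with the observed margins whose hypergeometric probability does
#' not exceed that of the observed table (probability-ordering two-sided
#' definition). Tables with two rows and total count <= 500 are evaluated
#' by full enumeration of the margin-constrained tables; larger or
#' higher-dimensional tables fall back to the network algorithm of
#' [stats::fisher.test()].
#'
#' @param counts matrix of non-negative integer counts.
#' @return the exact p-value.
#' @export
fisher_exact_rxc <- function(counts) {
  M <- as.matrix(counts)
  if (any(M < 0) || any(M != round(M))) {
    stop("argument error: counts must be non-negative integers")
  }
  if (any(rowSums(M) == 0) || any(colSums(M) == 0)) {
    # a zero margin admits a single table: p = 1
    if (sum(M) == 0) return(1)
    M <- M[rowSums(M) > 0, colSums(M) > 0, drop = FALSE]
    if (!is.matrix(M) || nrow(M) < 2L || ncol(M) < 2L) return(1)
  }
  if (nrow(M) != 2L && ncol(M) == 2L) M <- t(M)
  if (nrow(M) != 2L || sum(M) > 500) {
    return(stats::fisher.test(M, workspace = 2e7)$p.value)
  }
  cs <- colSums(M); N <- sum(M)
  r1 <- sum(M[1, ])
  obs_lp <- sum(lchoose(cs, M[1, ]))  # unnormalized; candidates compared on the same scale
  C <- length(cs)
  tail_cap <- rev(cumsum(rev(cs)))  # max mass available from column j on
  acc <- new.env()
  acc$p <- 0
  recurse <- function(j, rem, lp) {
    if (j == C) {
      if (rem <= cs[C]) {
        tot <- lp + lchoose(cs[C], rem)
        # probability ordering with fisher.test's relative tolerance
        if (tot <= obs_lp + log1p(1e-7)) acc$p <- acc$p + exp(tot - lchoose(N, r1))
      }
      return(invisible(NULL))
    }
    lo <- max(0L, rem - tail_cap[j + 1L])
    hi <- min(cs[j], rem)
    if (lo > hi) return(invisible(NULL))
    for (x in lo:hi) {
      recurse(j + 1L, rem - x, lp + lchoose(cs[j], x))
    }
  }
  recurse(1L, r1, 0)
  min(acc$p, 1)
}
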