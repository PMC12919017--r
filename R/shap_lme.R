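#' @importFrom lme4 lmer VarCorr
#' @importFrom stats logLik formula drop1
NULL

.lme_lrt <- function(full_ml, drop_term, data) {
  red <- update(full_ml, as.formula(paste(". ~ . -", drop_term)))
  ll_f <- logLik(full_ml); ll_r <- logLik(red)
  stat <- as.numeric(2 * (ll_f - ll_r))
  df <- attr(ll_f, "df") - attr(ll_r, "df")
  data.frame(term = drop_term, chisq = stat, df = df,
             p = pchisq(stat, df, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Mixed-effects tests of signed Shapley values
#'
#' Random-intercept linear mixed model of signed Shapley values from
#' [aggregate_signed_shap()]: fixed effects for comorbidity burden,
#' network, morphometric measure and all their interactions, plus
#' adjustment covariates; a random intercept per participant absorbs
#' within-participant correlation across the 28 network-by-measure cells.
#' Coefficients and variance components are estimated by REML; fixed-term
#' tests are likelihood-ratio tests between maximum-likelihood fits of
#' nested models (degrees-of-freedom approximations for mixed-model F
#' tests are deliberately avoided). Follow-ups test the burden-by-network
#' interaction within each measure and, within each network of a measure,
#' the burden effect (participant-level OLS, since each cell holds one row
#' per participant) with BH-adjusted pairwise burden comparisons.
#'
#' @param long_table long data.frame from [aggregate_signed_shap()] with
#'   columns `phi`, `group`, `network`, `measure`, `participant_id` and
#'   covariates.
#' @param covariates character vector of covariate column names to adjust
#'   for (defaults to the six standard covariates present in the table).
#' @param followup `TRUE` (per-measure interaction tests plus per-cell
#'   burden tests), `FALSE` (none), or `"cells"` (per-cell tests only).
#' @param lrt_terms which fixed terms to test by likelihood ratio:
#'   `"all"` (default) walks the full hierarchy; a character vector (e.g.
#'   `"burden:network:measure"`) tests only those terms against the full
#'   model, which is much cheaper in simulation studies.
#' @return object of class `"shap_lme_result"`: REML fixed effects,
#'   variance components, the likelihood-ratio test table, and follow-up
#'   tables.
#' @export
signed_shap_lme <- function(long_table,
                            covariates = intersect(.covariate_cols(),
                                                   names(long_table)),
                            followup = TRUE, lrt_terms = "all") {
  d <- long_table
  need <- c("phi", "group", "network", "measure", "participant_id")
  stopifnot(all(need %in% names(d)))
  d$burden <- factor(d$group)
  d$network <- factor(d$network, levels = morph_networks())
  d$measure <- factor(d$measure, levels = morph_measures())
  d$participant_id <- factor(d$participant_id)
  if (min(table(d$participant_id)) < 2L) {
    stop("need >= 2 rows per participant for a random intercept")
  }
  d$burden <- droplevels(d$burden)
  if (nlevels(d$burden) < 2L) stop("need >= 2 burden levels")
  cov_part <- if (length(covariates)) paste(c("", covariates), collapse = " + ") else ""
  form <- as.formula(paste("phi ~ burden * network * measure", cov_part,
                           "+ (1 | participant_id)"))
  fit_reml <- lmer(form, data = d, REML = TRUE)
  fit_ml <- lmer(form, data = d, REML = FALSE)
  vc <- as.data.frame(VarCorr(fit_reml))
  varcomp <- c(participant = vc$vcov[vc$grp == "participant_id"],
               residual = vc$vcov[vc$grp == "Residual"])
  if (identical(lrt_terms, "all")) {
    lrt <- .lme_lrt(fit_ml, "burden:network:measure", d)
    # two-way terms tested against the model without the three-way term
    fit2 <- update(fit_ml, . ~ . - burden:network:measure)
    for (tm in c("burden:network", "burden:measure", "network:measure")) {
      lrt <- rbind(lrt, .lme_lrt(fit2, tm, d))
    }
    # main effects tested in the additive model
    fit1 <- update(fit2, . ~ . - burden:network - burden:measure - network:measure)
    for (tm in c("burden", "network", "measure")) {
      lrt <- rbind(lrt, .lme_lrt(fit1, tm, d))
    }
  } else {
    lrt <- do.call(rbind, lapply(lrt_terms, .lme_lrt, full_ml = fit_ml,
                                 data = d))
  }
  followups <- NULL
  do_cells <- isTRUE(followup) || identical(followup, "cells")
  if (do_cells) {
    per_measure <- if (isTRUE(followup)) {
      do.call(rbind, lapply(levels(d$measure), function(m) {
        dm <- d[d$measure == m, , drop = FALSE]
        fm <- as.formula(paste("phi ~ burden * network", cov_part,
                               "+ (1 | participant_id)"))
        full <- lmer(fm, data = dm, REML = FALSE)
        cbind(measure = m, .lme_lrt(full, "burden:network", dm))
      }))
    } else NULL
    per_network <- do.call(rbind, lapply(levels(d$measure), function(m) {
      do.call(rbind, lapply(levels(d$network), function(nw) {
        dc <- d[d$measure == m & d$network == nw, , drop = FALSE]
        fo <- as.formula(paste("phi ~ burden", cov_part))
        f1 <- lm(fo, data = dc)
        f0 <- update(f1, . ~ . - burden)
        av <- anova(f0, f1)
        lev <- levels(droplevels(dc$burden))
        pw <- if (nlevels(droplevels(dc$burden)) >= 2) {
          cf <- coef(f1); V <- vcov(f1)
          prs <- combn(seq_along(lev), 2)
          do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
            lo <- prs[1, i]; hi <- prs[2, i]
            cv <- rep(0, length(cf)); names(cv) <- names(cf)
            if (hi > 1) cv[paste0("burden", lev[hi])] <- 1
            if (lo > 1) cv[paste0("burden", lev[lo])] <- -1
            est <- sum(cv * cf); se <- sqrt(drop(t(cv) %*% V %*% cv))
            data.frame(measure = m, network = nw,
                       contrast = paste(lev[hi], "-", lev[lo]),
                       estimate = est,
                       p = 2 * pt(abs(est / se), f1$df.residual,
                                  lower.tail = FALSE),
                       stringsAsFactors = FALSE)
          }))
        } else NULL
        list(main = data.frame(measure = m, network = nw,
                               F = av$F[2], df1 = av$Df[2],
                               df2 = f1$df.residual, p = av$`Pr(>F)`[2],
                               stringsAsFactors = FALSE),
             pairwise = pw)
      }))
    }))
    main_tab <- do.call(rbind, per_network[, "main"])
    pw_tab <- do.call(rbind, per_network[, "pairwise"])
    # FDR within each measure across networks; pairwise FDR within network
    main_tab$q <- unsplit(lapply(split(main_tab$p, main_tab$measure),
                                 fdr_adjust), main_tab$measure)
    if (!is.null(pw_tab)) {
      key <- paste(pw_tab$measure, pw_tab$network)
      pw_tab$q <- unsplit(lapply(split(pw_tab$p, key), fdr_adjust), key)
    }
    followups <- list(burden_network_by_measure = per_measure,
                      burden_by_cell = main_tab,
                      pairwise_by_cell = pw_tab)
  }
  structure(list(fixed = lme4::fixef(fit_reml),
                 varcomp = varcomp,
                 lrt = lrt,
                 followups = followups,
                 fit = fit_reml),
            class = "shap_lme_result")
}

#' @export
print.shap_lme_result <- function(x, ...) {
  cat("Mixed-effects model of signed Shapley values (random participant intercept)\n")
  cat(sprintf("  variance components: participant %.4f, residual %.4f\n",
              x$varcomp["participant"], x$varcomp["residual"]))
  cat("  likelihood-ratio tests (ML nested fits):\n")
  print(x$lrt, digits = 4, row.names = FALSE)
  invisible(x)
}
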