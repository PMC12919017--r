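test_that("impairment rule counts domains at or below the 1-SD cut", {
  all50 <- data.frame(d1 = rep(50, 3), d2 = 50, d3 = 50)
  expect_equal(as.logical(classify_nci(all50)), rep(FALSE, 3))
  # boundary inclusive: exactly two domains at T = 40 is impaired
  expect_true(classify_nci(data.frame(d1 = 40, d2 = 40, d3 = 55))[1])
  # a single deeply impaired domain is not enough
  expect_false(classify_nci(data.frame(d1 = 20, d2 = 55, d3 = 55))[1])
  withmiss <- data.frame(d1 = c(30, NA), d2 = c(30, 50))
  flags <- classify_nci(withmiss)
  expect_true(flags[1])
  expect_true(is.na(flags[2]))
  expect_equal(attr(flags, "report")$row, 2L)
  expect_error(classify_nci(data.frame(d1 = 1:3)), ">= 2")
})

test_that("BH adjustment matches hand computation and edge cases", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(1, 4)), rep(1, 4))
  expect_error(fdr_adjust(c(0.5, 1.2)), "argument error")
})

test_that("exact Fisher p-values match hand enumeration and the network algorithm", {
  # hand-enumerated hypergeometric tail
  expect_equal(fisher_exact_rxc(rbind(c(3, 1), c(1, 3))),
               2 * (choose(4, 3) * choose(4, 1) + 1) / choose(8, 4),
               tolerance = 1e-12)
  # degenerate margin admits a single table
  expect_equal(fisher_exact_rxc(rbind(c(34, 0), c(34, 0))), 1)
  expect_error(fisher_exact_rxc(rbind(c(1.5, 2), c(3, 4))), "argument error")
  # exhaustive agreement with an independent brute-force oracle, total <= 60
  set.seed(17)
  for (i in 1:25) {
    C <- sample(2:4, 1)
    M <- matrix(rpois(2 * C, 5), 2, C)
    if (any(colSums(M) == 0) || any(rowSums(M) == 0)) next
    expect_equal(fisher_exact_rxc(M), fisher_brute(M), tolerance = 1e-12)
    expect_equal(fisher_exact_rxc(M), fisher.test(M)$p.value,
                 tolerance = 1e-9)
  }
  # r > 2 rows fall back to the network algorithm
  M3 <- rbind(c(4, 2, 3), c(1, 5, 2), c(3, 3, 1))
  expect_equal(fisher_exact_rxc(M3), fisher.test(M3)$p.value, tolerance = 1e-12)
})

test_that("group model recovers planted dose effects with FDR-significant contrasts", {
  cfg <- sim_config(n_per_group = c(200L, 200L, 200L), clinical_bag_sd = 4)
  cl <- simulate_clinical_cohort(cfg, seed = 51)
  res <- bag_group_model(cl$truth$participants$true_bag, cl$table$group,
                         cov_cols(cl$table))
  expect_s3_class(res, "group_model_result")
  expect_lt(res$p_group, 1e-6)
  expect_true(all(res$contrasts$q < 0.05))
  expect_true(all(res$contrasts$q >= res$contrasts$p))
  planted <- c("1 - 0" = 3.5, "2 - 0" = 6.3, "2 - 1" = 2.8)
  for (ct in names(planted)) {
    row <- res$contrasts[res$contrasts$contrast == ct, ]
    expect_lt(abs(row$estimate - planted[[ct]]), 3 * row$se)
  }
  expect_output(print(res), "Type III")
})

test_that("covariate-free balanced design reduces to textbook one-way ANOVA", {
  set.seed(23)
  y <- rnorm(90) + rep(c(0, 1, 2), each = 30)
  g <- rep(0:2, each = 30)
  ours <- bag_group_model(y, g, covariates = NULL)
  oracle <- anova(aov(y ~ factor(g)))
  expect_equal(ours$F_group, oracle$`F value`[1], tolerance = 1e-10)
  expect_equal(ours$p_group, oracle$`Pr(>F)`[1], tolerance = 1e-10)
  # shared machinery: the morphometric validation model is the same fit
  expect_equal(morphometric_validation_model(y, g, NULL)$contrasts,
               ours$contrasts)
})

test_that("logistic burden model reduces to the cross-product odds ratio on a 2x2 table", {
  y <- c(rep(1, 30), rep(0, 10), rep(1, 20), rep(0, 40))
  g <- c(rep(1, 40), rep(0, 60))
  res <- nci_burden_logistic(y, g, n_boot = 50, seed = 1)
  expect_equal(res$odds_ratios$or[1], (30 * 40) / (10 * 20), tolerance = 1e-8)
  # marginal standardization collapses to raw group rates without covariates
  expect_equal(res$adjusted_probabilities$prob,
               as.vector(tapply(y, g, mean)), tolerance = 1e-10)
  expect_error(nci_burden_logistic(rep(1, 20), rep(0:1, 10)), "both classes")
})

test_that("continuous-BAG logistic model behaves under reparameterization and recovery", {
  set.seed(29)
  n <- 2000
  bag <- rnorm(n, 3, 5)
  p <- plogis(-1.5 + 0.08 * bag)
  nci <- rbinom(n, 1, p)
  res <- nci_bag_logistic(nci, bag, n_boot = 50, seed = 2)
  expect_gt(res$odds_ratios$or[1], 1.05)
  expect_lt(res$odds_ratios$or[1], 1.11)
  res10 <- nci_bag_logistic(nci, bag * 10, n_boot = 50, seed = 2)
  expect_equal(res10$odds_ratios$log_or[1], res$odds_ratios$log_or[1] / 10,
               tolerance = 1e-6)
  expect_error(nci_bag_logistic(nci, rep(2, n)), "degenerate-predictor")
})

test_that("factorial model detects a planted interaction and rejects collinearity", {
  set.seed(31)
  n <- 900
  hiv <- rbinom(n, 1, 0.5); cu <- rbinom(n, 1, 0.5)
  y <- 2 * hiv + 2 * cu + 2 * hiv * cu + rnorm(n, 0, 4)
  res <- factorial_hiv_cu(y, hiv, cu, family = "linear")
  expect_lt(res$p[["hiv:cu"]], 0.05)
  expect_lt(res$p[["hiv"]], 0.05)
  expect_error(factorial_hiv_cu(y, hiv, hiv, family = "linear"),
               "collinear")
  hiv2 <- hiv; hiv2[cu == 0] <- 1   # empty (0,0) cell
  expect_warning(factorial_hiv_cu(y, hiv2, cu, family = "linear"),
                 "empty")
})
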