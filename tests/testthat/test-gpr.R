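test_that("posterior mean matches the dense-matrix oracle with fixed hyperparameters", {
  set.seed(42)
  th <- c(sf2 = 1.3, ell = 1.7, sl2 = 0.4, sn2 = 0.05)
  # 3-point case from first principles
  X <- matrix(c(0, 1, 2), 3, 1)
  y <- c(1, 3, 2)
  m <- fit_gpr(X, y, gpr_config(optimize = FALSE, init = th),
               standardize = FALSE)
  Xs <- matrix(c(0.5, 1.5, 3), 3, 1)
  expect_equal(predict(m, Xs), gp_dense_oracle(X, y, Xs, th, m$jitter),
               tolerance = 1e-10)
  # larger random instance
  X2 <- matrix(rnorm(40 * 6), 40, 6)
  y2 <- rowSums(sin(X2)) + rnorm(40, 0, 0.2)
  m2 <- fit_gpr(X2, y2, gpr_config(optimize = FALSE, init = th),
                standardize = FALSE)
  X2s <- matrix(rnorm(8 * 6), 8, 6)
  expect_equal(predict(m2, X2s), gp_dense_oracle(X2, y2, X2s, th, m2$jitter),
               tolerance = 1e-8)
})

test_that("analytic marginal-likelihood gradient matches finite differences", {
  set.seed(7)
  X <- matrix(rnorm(25 * 3), 25, 3)
  y <- rowSums(X) + rnorm(25, 0, 0.3)
  yc <- y - mean(y)
  D2 <- morphage:::.sqdist(X, X); XXt <- tcrossprod(X)
  lp <- log(c(1.2, 1.5, 0.4, 0.2))
  g_an <- morphage:::.gpr_nll(lp, X, yc, D2, XXt, grad = TRUE)$grad
  g_num <- vapply(1:4, function(i) {
    e <- rep(0, 4); e[i] <- 1e-6
    (morphage:::.gpr_nll(lp + e, X, yc, D2, XXt) -
       morphage:::.gpr_nll(lp - e, X, yc, D2, XXt)) / 2e-6
  }, numeric(1))
  expect_equal(g_an, g_num, tolerance = 1e-6)
})

test_that("noise-free limit interpolates and constant targets are reproduced", {
  X <- matrix(c(0, 1, 2, 3.5, 5), 5, 1)
  y <- c(0.2, 0.9, 0.1, -0.5, 0.7)
  m <- fit_gpr(X, y, gpr_config(optimize = FALSE,
                                init = c(sf2 = 1, ell = 1, sl2 = 1e-12,
                                         sn2 = 1e-8)),
               standardize = FALSE)
  expect_lt(max(abs(predict(m, X) - y)), 1e-6)
  # constant targets: optimized model predicts the constant everywhere
  set.seed(1)
  Xc <- matrix(rnorm(25 * 4), 25, 4)
  mc <- fit_gpr(Xc, rep(7.5, 25), gpr_config(n_restarts = 2, maxit = 30))
  expect_lt(max(abs(predict(mc, matrix(rnorm(10 * 4), 10, 4)) - 7.5)), 1e-6)
})

test_that("predictions are row-equivariant and deterministic", {
  set.seed(3)
  X <- matrix(rnorm(30 * 5), 30, 5)
  y <- X[, 1] * 2 + rnorm(30, 0, 0.1)
  m <- fit_gpr(X, y, gpr_config(n_restarts = 2, maxit = 40))
  Xt <- matrix(rnorm(6 * 5), 6, 5)
  p <- predict(m, Xt)
  expect_identical(predict(m, Xt), p)
  perm <- c(4, 1, 6, 2, 5, 3)
  expect_equal(predict(m, Xt[perm, ]), p[perm])
  expect_equal(predict(m, Xt[c(1, 1), ]), p[c(1, 1)])
  expect_error(predict(m, Xt[, 1:3]), "schema")
})

test_that("model object exposes the standard fitted-model surface", {
  tr <- simulate_training_cohort(quick_cfg(), seed = 9)$table
  m <- fit_gpr(tr, kernel_config = gpr_config(n_restarts = 2, maxit = 40))
  expect_s3_class(m, "gpr_model")
  expect_named(coef(m), c("sf2", "ell", "sl2", "sn2"))
  expect_true(all(coef(m) > 0))
  expect_equal(residuals(m), tr$age - fitted(m))
  expect_output(print(m), "Gaussian-process")
  expect_output(print(summary(m)), "hyperparameters")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(m))
  expect_error(fit_gpr(tr[1:2, ]), "at least 3")
})

test_that("cross-validation partitions rows and nails a noiseless smooth map", {
  # age is a deterministic smooth function of one feature
  tab <- simulate_training_cohort(noiseless_cfg(n_training = 60L), seed = 5)$table
  cv <- cross_validate(tab, folds = 5, seed = 2,
                       kernel_config = gpr_config(n_restarts = 2, maxit = 60))
  expect_lt(cv$metrics_corrected$mae, 0.5)
  expect_true(all(tabulate(cv$fold, 5) >= 10))
  # leave-one-out on 10 rows: singleton test sets covering all rows
  cv10 <- cross_validate(tab[1:10, ], folds = 10, seed = 1,
                         kernel_config = gpr_config(optimize = FALSE))
  expect_equal(sort(unique(cv10$fold)), 1:10)
  expect_equal(tabulate(cv10$fold, 10), rep(1L, 10))
  # fold assignment is reproducible
  expect_identical(cv$fold,
                   morphage:::.age_stratified_folds(tab$age, 5, seed = 2))
  expect_error(cross_validate(tab[1:3, ], folds = 5), "fewer rows")
})
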