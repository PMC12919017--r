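# Configurations with no latent BAG so residual variance equals the planted
# noise and site offsets are exactly interpretable in residual-SD units.
combat_cfg <- function(shift, scale = c(1, 1), n = 400L) {
  sim_config(n_training = n, n_sites = 2L, site_shift = shift,
             site_scale = scale, training_bag_sd = 0)
}

test_that("planted additive site offsets are recovered by the shrunk batch means", {
  tr <- simulate_training_cohort(combat_cfg(c(-0.3, 0.3)), seed = 7)
  cm <- combat_fit(tr$table, design = c("age", "sex"))
  # planted offsets in units of the model's pooled residual SD
  planted <- outer(c(-0.3, 0.3), tr$truth$config$noise_sd_map) /
    matrix(sqrt(cm$var_pooled), 2, 28, byrow = TRUE)
  expect_lt(mean(abs(cm$gamma_star - planted)), 0.05)
  expect_true(all(cm$delta_star > 0))
})

test_that("identically distributed batches give near-null batch effects", {
  tr <- simulate_training_cohort(combat_cfg(c(0, 0)), seed = 9)
  cm <- combat_fit(tr$table, design = c("age", "sex"))
  expect_lt(max(abs(cm$gamma_star)), 3 / sqrt(200))
  expect_lt(max(abs(cm$delta_star - 1)), 0.3)
  # and applying the model barely changes the data
  h <- combat_apply(cm, tr$table)
  delta <- as.matrix(h[, feature_keys()]) - as.matrix(tr$table[, feature_keys()])
  rms_sd <- sqrt(colMeans(delta^2)) / apply(as.matrix(tr$table[, feature_keys()]), 2, sd)
  expect_lt(max(rms_sd), 0.05)
})

test_that("fitted covariate coefficients match the per-feature OLS oracle", {
  tr <- simulate_training_cohort(combat_cfg(c(-0.5, 0.5)), seed = 13)
  cm <- combat_fit(tr$table, design = c("age", "sex"))
  for (k in c("thickness__VIS", "surface_area__LIM")) {
    oracle <- coef(lm(tr$table[[k]] ~ site + age + sex, data = tr$table))
    expect_equal(unname(cm$beta_cov["age", k]), unname(oracle["age"]),
                 tolerance = 1e-8)
    expect_equal(unname(cm$beta_cov["sex", k]), unname(oracle["sex"]),
                 tolerance = 1e-8)
  }
})

test_that("harmonization removes batch effects while preserving age slopes", {
  tr <- simulate_training_cohort(combat_cfg(c(-0.5, 0.5), scale = c(1, 2)),
                                 seed = 15)
  tab <- tr$table
  pre <- site_effect_scan(tab)
  expect_gt(sum(pre$p < 0.05), 20)   # offsets are visible before
  cm <- combat_fit(tab, design = c("age", "sex"))
  h <- combat_apply(cm, tab)
  post <- site_effect_scan(h)
  crit <- qf(0.95, post$df1[1], post$df2[1])
  expect_gte(sum(post$F < crit), 27)
  # planted age slopes survive within 5% relative error
  for (k in c("thickness__VAN", "volume__FPN")) {
    sl_pre <- coef(lm(tab[[k]] ~ age + sex, data = tab))["age"]
    sl_post <- coef(lm(h[[k]] ~ age + sex, data = h))["age"]
    expect_lt(abs(sl_post - sl_pre) / abs(sl_pre), 0.05)
  }
  # row count and covariates untouched
  expect_equal(nrow(h), nrow(tab))
  expect_identical(h[, c("participant_id", "age", "sex", "zung")],
                   tab[, c("participant_id", "age", "sex", "zung")])
})

test_that("harmonization is approximately idempotent", {
  tr <- simulate_training_cohort(combat_cfg(c(-0.5, 0.5), scale = c(1, 1.8)),
                                 seed = 17)
  h1 <- combat_apply(combat_fit(tr$table, design = c("age", "sex")), tr$table)
  h2 <- combat_apply(combat_fit(h1, design = c("age", "sex")), h1)
  delta <- as.matrix(h2[, feature_keys()]) - as.matrix(h1[, feature_keys()])
  rms_sd <- sqrt(colMeans(delta^2)) / apply(as.matrix(h1[, feature_keys()]), 2, sd)
  expect_lt(max(rms_sd), 0.02)
})

test_that("disease-aware harmonization preserves planted burden offsets", {
  cfg <- sim_config(n_training = 300L, n_per_group = c(100L, 100L, 100L),
                    training_bag_sd = 0, clinical_bag_sd = 0,
                    mediation_a = c(0, 0, 0),
                    burden_effect_map = c(thickness__VIS = -0.05))
  tr <- simulate_training_cohort(cfg, seed = 19)
  cl <- simulate_clinical_cohort(cfg, seed = 20)
  both <- rbind(tr$table, cl$table)
  h <- combat_apply(combat_fit(both, design = c("age", "sex", "disease")), both)
  hc <- h[h$cohort == "clinical", ]
  slope_pre <- coef(lm(thickness__VIS ~ group + age + sex,
                       data = cl$table))["group"]
  slope_post <- coef(lm(thickness__VIS ~ group + age + sex, data = hc))["group"]
  expect_lt(abs(slope_post - slope_pre) / abs(slope_pre), 0.10)
})

test_that("joint fit agrees with the reference empirical-Bayes implementation", {
  tr <- simulate_training_cohort(combat_cfg(c(-0.4, 0.4), scale = c(1, 1.5),
                                            n = 200L), seed = 23)
  tab <- tr$table
  ours <- combat_apply(combat_fit(tab, design = c("age", "sex")), tab)
  mod <- stats::model.matrix(~ age + sex, data = tab)
  ref <- t(sva::ComBat(dat = t(as.matrix(tab[, feature_keys()])),
                       batch = tab$site, mod = mod))
  expect_lt(max(abs(as.matrix(ours[, feature_keys()]) - ref)), 1e-6)
})

test_that("degenerate batch structure and rank problems are rejected", {
  tr <- simulate_training_cohort(quick_cfg(n_sites = 1L, site_shift = 0,
                                           site_scale = 1), seed = 2)
  expect_error(combat_fit(tr$table), "degenerate-batch")
  tr2 <- simulate_training_cohort(quick_cfg(), seed = 2)
  tab2 <- tr2$table
  tab2$dup_age <- tab2$age
  expect_error(combat_fit(tab2, design = c("age", "dup_age")),
               "rank deficient")
  cm <- combat_fit(tr2$table, design = c("age", "sex"))
  tab3 <- tr2$table; tab3$site <- "S9"
  expect_error(combat_apply(cm, tab3), "unseen batch")
})

test_that("site scan is calibrated under the null and flags planted offsets", {
  # planted 1-SD offset: overwhelming evidence in affected features
  tr <- simulate_training_cohort(combat_cfg(c(-0.5, 0.5), n = 200L), seed = 29)
  scan <- site_effect_scan(tr$table)
  expect_true(all(scan$p < 1e-6))
  # null: about 5% of features significant across replicates
  hits <- 0L
  for (r in 1:30) {
    trn <- simulate_training_cohort(combat_cfg(c(0, 0), n = 80L),
                                    seed = 100 + r)
    hits <- hits + sum(site_effect_scan(trn$table)$p < 0.05)
  }
  rate <- hits / (30 * 28)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
  # identical batches of identical values scan as F = 0
  tab <- simulate_training_cohort(noiseless_cfg(n_training = 40L), seed = 3)$table
  tab$site <- rep(c("S1", "S2"), 20)
  tab$age <- 50; tab[, feature_keys()] <- 1   # constant feature, equal batches
  expect_equal(site_effect_scan(tab)$F, rep(0, 28))
})
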