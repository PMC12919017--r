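test_that("reference sets pick the k nearest-in-age training rows deterministically", {
  tt <- data.frame(participant_id = c("a", "b", "c"), age = c(40, 50, 60))
  expect_equal(select_reference_set(49, tt, k = 1)$indices, 2L)
  expect_equal(select_reference_set(60, tt, k = 1)$indices, 3L)
  tt4 <- data.frame(participant_id = c("a", "b", "c", "d"),
                    age = c(40, 41, 59, 60))
  rs <- select_reference_set(50, tt4, k = 2)
  expect_setequal(rs$ages, c(41, 59))
  expect_error(select_reference_set(50, tt4, k = 5), "exceeds")
  # age ties break by ascending participant id
  ties <- data.frame(participant_id = c("z9", "a1", "m5"), age = c(50, 50, 50))
  expect_equal(select_reference_set(50, ties, k = 2)$rows$participant_id,
               c("a1", "m5"))
  # selected distances never exceed excluded distances
  set.seed(8)
  for (i in 1:20) {
    tr <- data.frame(participant_id = sprintf("p%02d", 1:15),
                     age = sample(40:60, 15, replace = TRUE))
    rs <- select_reference_set(runif(1, 35, 65), tr, k = 6)
    d <- abs(tr$age - rs$target_age)
    expect_lte(max(d[rs$indices]), min(d[-rs$indices]))
  }
})

test_that("linear models yield the closed-form attribution for any sample size", {
  set.seed(5)
  w <- rnorm(7); x <- rnorm(7); b <- rnorm(7)
  fmod <- function(M) M %*% w
  for (np in c(2, 16)) {
    sv <- shapley_attribution(fmod, x, matrix(b, 1), n_permutations = np,
                              seed = 1)
    expect_equal(unname(sv$phi), w * (x - b), tolerance = 1e-12)
  }
  expect_equal(unname(exact_shapley_oracle(fmod, x, matrix(b, 1))),
               w * (x - b), tolerance = 1e-12)
})

test_that("a participant identical to its reference row gets zero attribution", {
  fmod <- function(M) sin(M[, 1]) + M[, 2]^2
  x <- c(0.3, -1.2)
  sv <- shapley_attribution(fmod, x, matrix(x, 1), n_permutations = 2, seed = 1)
  expect_equal(unname(sv$phi), c(0, 0))
})

test_that("the exact oracle satisfies the dummy, symmetry and efficiency axioms", {
  set.seed(11)
  # dummy: an ignored feature gets exactly zero
  fmod <- function(M) M[, 1]^2 + 3 * M[, 3]
  x <- rnorm(3); R <- matrix(rnorm(2 * 3), 2, 3)
  phi <- exact_shapley_oracle(fmod, x, R)
  expect_identical(unname(phi[2]), 0)
  # symmetry: exchangeable duplicated features share credit equally
  fsym <- function(M) (M[, 1] + M[, 2])^2
  xs <- c(1.3, 1.3, -2)
  Rs <- matrix(c(0.2, 0.2, 1), 1, 3)
  ps <- exact_shapley_oracle(fsym, xs, Rs)
  expect_equal(ps[1], ps[2], tolerance = 1e-12, ignore_attr = TRUE)
  # efficiency on random instances
  for (i in 1:5) {
    d <- sample(3:8, 1)
    f <- local({ W <- rnorm(d); function(M) cos(M %*% W) })
    xi <- rnorm(d); Ri <- matrix(rnorm(3 * d), 3, d)
    phi_i <- exact_shapley_oracle(f, xi, Ri)
    fx <- mean(f(matrix(xi, 3, d, byrow = TRUE)))
    v0 <- mean(f(Ri))
    expect_lt(abs(sum(phi_i) - (fx - v0)), 1e-10)
  }
  expect_error(exact_shapley_oracle(fmod, rnorm(16), matrix(rnorm(16), 1)),
               "size error")
})

test_that("sampled attributions agree with exact enumeration within MC error", {
  set.seed(13)
  th <- c(sf2 = 1, ell = 1.5, sl2 = 0.2, sn2 = 0.1)
  X <- matrix(rnorm(25 * 4), 25, 4)
  y <- sin(X[, 1]) + X[, 2] + rnorm(25, 0.1)
  m <- fit_gpr(X, y, gpr_config(optimize = FALSE, init = th),
               standardize = FALSE)
  x <- rnorm(4); R <- X[1:3, ]
  ex <- exact_shapley_oracle(m, x, R)
  sv <- shapley_attribution(m, x, R, n_permutations = 1024, seed = 2)
  expect_true(all(abs(sv$phi - ex) <= 3 * sv$se))
  # efficiency holds to numerical precision
  expect_lt(abs(sum(sv$phi) - (sv$prediction - sv$baseline)), 1e-8)
})

test_that("global importance aggregates mean absolute attributions", {
  phi1 <- matrix(0, 1, 28, dimnames = list("p1", feature_keys()))
  phi1[1, 1] <- 2; phi1[1, 2] <- -2
  imp <- global_importance(phi1)
  expect_equal(imp$per_feature$importance[1:3], c(2, 2, 0))
  zero <- global_importance(matrix(0, 2, 28,
                                   dimnames = list(NULL, feature_keys())))
  expect_true(all(zero$per_feature$importance == 0))
  expect_true(all(imp$per_cell$rank_in_measure >= 1))
})

test_that("long-format reshape preserves signed values and column sums", {
  cl <- simulate_clinical_cohort(quick_cfg(), seed = 3)$table
  phi <- matrix(rnorm(2 * 28), 2, 28,
                dimnames = list(cl$participant_id[1:2], feature_keys()))
  long <- aggregate_signed_shap(phi, cl)
  expect_equal(nrow(long), 56L)
  expect_equal(long$phi[long$participant_id == cl$participant_id[1]],
               unname(phi[1, ]))
  sums_long <- tapply(long$phi, paste(long$measure, long$network, sep = "__"),
                      sum)
  expect_equal(as.numeric(sums_long[feature_keys()]),
               as.numeric(colSums(phi)))
  expect_true(all(c("group", "age", "zung") %in% names(long)))
  bad <- phi; rownames(bad) <- c("nope", "alsono")
  expect_error(aggregate_signed_shap(bad, cl), "integrity")
})

test_that("a lone informative feature dominates the importance ranking", {
  hits <- 0L
  for (r in 1:10) {
    cfg <- sim_config(n_training = 80L, n_per_group = c(4L, 4L, 4L),
                      slope_map = c(thickness__VIS = -0.02),
                      curvature_map = 0,
                      burden_effect_map = c(thickness__VIS = -0.03),
                      training_bag_sd = 0,
                      site_shift = c(0, 0), site_scale = c(1, 1),
                      clinical_site_shift = 0, clinical_site_scale = 1)
    # zero out every other slope so only thickness__VIS carries age signal
    cfg$slope_map[setdiff(feature_keys(), "thickness__VIS")] <- 0
    tr <- simulate_training_cohort(cfg, seed = 400 + r)
    cl <- simulate_clinical_cohort(cfg, seed = 500 + r)
    m <- fit_gpr(tr$table, kernel_config = gpr_config(n_restarts = 2,
                                                      maxit = 40))
    phi <- t(vapply(seq_len(nrow(cl$table)), function(i) {
      ref <- select_reference_set(cl$table$age[i], tr$table, k = 5)
      shapley_attribution(m, cl$table[i, ], ref, n_permutations = 16,
                          seed = i)$phi
    }, numeric(28)))
    colnames(phi) <- feature_keys()
    imp <- global_importance(phi)
    th <- imp$per_cell[imp$per_cell$measure == "thickness", ]
    if (th$rank_in_measure[th$network == "VIS"] <= 2) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})
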