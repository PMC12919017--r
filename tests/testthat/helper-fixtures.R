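# Shared fixtures, built in code at test time.

# Small, fast simulation configuration for pipeline-level tests.
quick_cfg <- function(...) {
  sim_config(n_training = 120L, n_per_group = c(20L, 20L, 20L), ...)
}

# A noiseless configuration: features lie exactly on their planted
# trajectories in chronological age.
noiseless_cfg <- function(...) {
  sim_config(noise_sd_map = 0, site_shift = c(0, 0), site_scale = c(1, 1),
             clinical_site_shift = 0, clinical_site_scale = 1,
             curvature_map = 0, training_bag_sd = 0, clinical_bag_sd = 0,
             ...)
}

# Six standard covariate columns from a feature table.
cov_cols <- function(tab) {
  tab[, c("age", "sex", "education", "zung", "euler", "motion")]
}

# Independent dense-matrix GP posterior-mean oracle (naive loops, no
# shared code with the package's kernel algebra beyond arithmetic).
gp_dense_oracle <- function(X, y, Xstar, th, jitter = 0) {
  n <- nrow(X); m <- nrow(Xstar)
  kfun <- function(a, b) {
    th[["sf2"]] * exp(-0.5 * sum((a - b)^2) / th[["ell"]]^2) +
      th[["sl2"]] * sum(a * b)
  }
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) K[i, j] <- kfun(X[i, ], X[j, ])
  Ks <- matrix(0, m, n)
  for (i in seq_len(m)) for (j in seq_len(n)) Ks[i, j] <- kfun(Xstar[i, ], X[j, ])
  drop(mean(y) + Ks %*% solve(K + diag(th[["sn2"]] + jitter, n), y - mean(y)))
}

# Brute-force Fisher enumeration for 2xC tables via expand.grid (kept
# independent of the package's recursive implementation).
fisher_brute <- function(tab) {
  cs <- colSums(tab); r1 <- sum(tab[1, ]); N <- sum(tab)
  G <- expand.grid(lapply(cs, function(m) 0:m))
  G <- G[rowSums(G) == r1, , drop = FALSE]
  lp <- apply(G, 1, function(x) sum(lchoose(cs, x)))
  obs <- sum(lchoose(cs, tab[1, ]))
  sum(exp(lp[lp <= obs + log1p(1e-7)] - lchoose(N, r1)))
}
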