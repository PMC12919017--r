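#' @importFrom stats rnorm runif rbinom plogis setNames
NULL

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv))
  })
  set.seed(seed)
  force(expr)
}

# Expand a per-measure default into a full 28-key named vector, then apply
# user overrides given as a (partially) named vector.
.expand_map <- function(per_measure, network_weight = NULL, override = NULL) {
  keys <- feature_keys()
  info <- parse_feature_key(keys)
  out <- per_measure[info$measure]
  names(out) <- keys
  if (!is.null(network_weight)) {
    out <- out * if (is.matrix(network_weight)) {
      network_weight[cbind(info$measure, info$network)]
    } else {
      network_weight[info$network]
    }
  }
  if (!is.null(override)) {
    if (is.null(names(override)) && length(override) == 1L) {
      out[] <- override
    } else {
      bad <- setdiff(names(override), keys)
      if (length(bad)) stop("unknown feature key(s) in map: ",
                            paste(bad, collapse = ", "))
      out[names(override)] <- override
    }
  }
  out
}

#' Simulation configuration for synthetic cohorts
#'
#' Bundles every generative choice behind the synthetic training and
#' clinical cohorts: sample sizes, age ranges, smooth age trajectories per
#' feature, scanner (site) effects, disorder-burden offsets on specific
#' network-by-measure features, and the latent brain-age-gap (BAG) pathway
#' to the neurocognitive-impairment (NCI) outcome.
#'
#' Defaults mirror the study conditions of the cohorts the generator
#' emulates: a training cohort of 725 healthy adults aged 36-100, and a
#' clinical cohort of 34/72/80 participants carrying 0/1/2 disorders, with
#' group BAG offsets of 0/3.5/6.3 years, an NCI log-odds slope of 0.08 per
#' year of BAG, and burden offsets that lower cortical thickness in the
#' visual, ventral-attention, and frontoparietal networks and deepen sulci
#' in the somatomotor network. Feature baselines/scales are conventions at
#' plausible magnitudes (thickness ~2.5 mm, sulcal depth ~10 mm, areas and
#' volumes ~1e4) so harmonization and standardization are exercised across
#' heterogeneous units. The methods vignette documents the remaining
#' free choices.
#'
#' @param n_training training-cohort size.
#' @param n_per_group clinical-group sizes for disorder counts 0/1/2.
#' @param age_range training age range (years), sampled uniformly.
#' @param clinical_age_range clinical age range (years).
#' @param n_sites number of training scanners.
#' @param site_shift per-site additive offsets, in units of each feature's
#'   residual SD.
#' @param site_scale per-site multiplicative residual-variance factors.
#' @param clinical_site_shift,clinical_site_scale same, for the single
#'   clinical scanner (site label `"CLIN"`).
#' @param baseline_map,slope_map,curvature_map,noise_sd_map,burden_effect_map
#'   optional named overrides (names from [feature_keys()]; an unnamed
#'   scalar sets every key) of the per-feature baselines, linear and
#'   quadratic age coefficients (feature units per year, per year squared),
#'   residual SDs, and per-disorder offsets.
#' @param training_bag_sd SD (years) of the latent brain-age deviation of
#'   healthy training participants.
#' @param clinical_bag_sd SD (years) of the residual latent BAG in the
#'   clinical cohort around its group offset.
#' @param mediation_a length-3 vector: mean true BAG (years) for disorder
#'   counts 0/1/2.
#' @param mediation_b log-odds of NCI per year of true BAG.
#' @param direct_c log-odds of NCI per disorder, not through BAG.
#' @param nci_intercept intercept of the NCI linear predictor.
#' @param nci_zung_beta,nci_education_beta covariate terms of the NCI
#'   linear predictor (zung is centred at 41).
#' @param seed integer RNG seed.
#' @return object of class `"sim_config"` (a validated list).
#' @export
sim_config <- function(n_training = 725L,
                       n_per_group = c(34L, 72L, 80L),
                       age_range = c(36, 100),
                       clinical_age_range = c(35, 77),
                       n_sites = 2L,
                       site_shift = c(-0.3, 0.3),
                       site_scale = c(1, 1.5),
                       clinical_site_shift = 0.5,
                       clinical_site_scale = 1.5,
                       baseline_map = NULL,
                       slope_map = NULL,
                       curvature_map = NULL,
                       noise_sd_map = NULL,
                       burden_effect_map = NULL,
                       training_bag_sd = 3,
                       clinical_bag_sd = 2,
                       mediation_a = c(0, 3.5, 6.3),
                       mediation_b = 0.08,
                       direct_c = 0.55,
                       nci_intercept = -1.54,
                       nci_zung_beta = 0.02,
                       nci_education_beta = 0.3,
                       seed = 1L) {
  base_default  <- c(thickness = 2.5,   sulcal_depth = 10,    surface_area = 12000, volume = 11000)
  slope_default <- c(thickness = -5e-3, sulcal_depth = 1.2e-2, surface_area = -18,  volume = -28)
  curv_default  <- c(thickness = -2e-5, sulcal_depth = 0,     surface_area = 0,     volume = 0)
  noise_default <- c(thickness = 0.03,  sulcal_depth = 0.12,  surface_area = 180,   volume = 280)
  # measure-specific network modulation of the age slopes, mirroring the
  # qualitative importance patterns of network-wise cortical ageing:
  # thickness ageing strongest in attention/default-mode cortex, sulcal
  # deepening dominated by somatomotor cortex, surface-area loss by limbic
  # cortex, volume loss by association cortex
  netw <- rbind(
    thickness    = c(VIS = 1.05, SMN = 0.85, DAN = 0.90, VAN = 1.30,
                     LIM = 0.80, FPN = 1.10, DMN = 1.25),
    sulcal_depth = c(VIS = 0.80, SMN = 1.50, DAN = 1.10, VAN = 0.90,
                     LIM = 0.70, FPN = 0.85, DMN = 0.75),
    surface_area = c(VIS = 0.95, SMN = 0.85, DAN = 0.90, VAN = 1.00,
                     LIM = 1.40, FPN = 0.95, DMN = 1.00),
    volume       = c(VIS = 0.90, SMN = 0.85, DAN = 0.95, VAN = 1.30,
                     LIM = 0.85, FPN = 1.15, DMN = 1.25))
  burden_default <- setNames(numeric(28), feature_keys())
  burden_default[c("thickness__VIS", "thickness__VAN", "thickness__FPN")] <- -0.003
  burden_default["sulcal_depth__SMN"] <- 0.012
  cfg <- list(
    n_training = as.integer(n_training),
    n_per_group = as.integer(n_per_group),
    age_range = age_range,
    clinical_age_range = clinical_age_range,
    n_sites = as.integer(n_sites),
    site_shift = rep_len(site_shift, n_sites),
    site_scale = rep_len(site_scale, n_sites),
    clinical_site_shift = clinical_site_shift,
    clinical_site_scale = clinical_site_scale,
    baseline_map = .expand_map(base_default, NULL, baseline_map),
    slope_map = .expand_map(slope_default, netw, slope_map),
    curvature_map = .expand_map(curv_default, NULL, curvature_map),
    noise_sd_map = .expand_map(noise_default, NULL, noise_sd_map),
    burden_effect_map = {
      b <- burden_default
      if (!is.null(burden_effect_map)) {
        # an explicit map fully replaces the default pattern
        b[] <- 0
        if (is.null(names(burden_effect_map)) && length(burden_effect_map) == 1L) {
          b[] <- burden_effect_map
        } else {
          bad <- setdiff(names(burden_effect_map), feature_keys())
          if (length(bad)) stop("unknown feature key(s) in burden map: ",
                                paste(bad, collapse = ", "))
          b[names(burden_effect_map)] <- burden_effect_map
        }
      }
      b
    },
    training_bag_sd = training_bag_sd,
    clinical_bag_sd = clinical_bag_sd,
    mediation_a = mediation_a,
    mediation_b = mediation_b,
    direct_c = direct_c,
    nci_intercept = nci_intercept,
    nci_zung_beta = nci_zung_beta,
    nci_education_beta = nci_education_beta,
    seed = as.integer(seed)
  )
  if (any(cfg$noise_sd_map < 0)) stop("config error: noise SDs must be >= 0")
  if (diff(cfg$age_range) <= 0 || diff(cfg$clinical_age_range) <= 0) {
    stop("config error: age_range lo must be < hi")
  }
  if (length(cfg$n_per_group) != 3L || any(cfg$n_per_group < 0L)) {
    stop("config error: n_per_group must give sizes for groups 0/1/2")
  }
  if (length(cfg$mediation_a) != 3L) {
    stop("config error: mediation_a must have one entry per group 0/1/2")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Feature matrix given effective brain age (chronological + latent BAG),
# group (disorder count), site index into shift/scale vectors.
.gen_features <- function(cfg, eff_age, group, shift, scale_var) {
  n <- length(eff_age)
  keys <- feature_keys()
  agec <- eff_age - mean(cfg$age_range)
  X <- matrix(NA_real_, n, length(keys), dimnames = list(NULL, keys))
  for (j in seq_along(keys)) {
    k <- keys[j]
    sd_j <- cfg$noise_sd_map[k]
    X[, j] <- cfg$baseline_map[k] +
      cfg$slope_map[k] * agec +
      cfg$curvature_map[k] * agec^2 +
      cfg$burden_effect_map[k] * group +
      shift * sd_j +
      rnorm(n, 0, sd_j * sqrt(scale_var))
  }
  X
}

.assemble_table <- function(id, site, cohort, group, hiv, cu, nci, covs, X) {
  tab <- data.frame(participant_id = id,
                    covs,
                    site = site, cohort = cohort,
                    group = group, hiv = hiv, cu = cu, nci = nci,
                    stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(X))
  tab[, feature_table_columns()]
}

#' Simulate the healthy training cohort
#'
#' Ages are uniform on `age_range`; each participant carries a latent
#' brain-age deviation (SD `training_bag_sd`) and every feature follows its
#' planted quadratic trajectory in effective brain age, plus site offset and
#' site-scaled Gaussian noise. Reproducible under a fixed seed.
#'
#' @param config [sim_config()] object.
#' @param seed optional seed overriding `config$seed`.
#' @return list with `table` (feature table) and `truth` (ground-truth
#'   bookkeeping: per-participant latent BAG, planted site and burden
#'   offsets).
#' @export
simulate_training_cohort <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- config$seed
  with_seed(seed, {
    n <- config$n_training
    age <- runif(n, config$age_range[1], config$age_range[2])
    d <- rnorm(n, 0, config$training_bag_sd)
    site_idx <- sample.int(config$n_sites, n, replace = TRUE)
    covs <- data.frame(
      age = age,
      sex = rbinom(n, 1, 0.5),
      education = rbinom(n, 1, 0.15),
      zung = rnorm(n, 38, 7),
      euler = as.integer(round(rnorm(n, -40, 20))),
      motion = pmax(0.01, rnorm(n, 0.12, 0.05)))
    X <- .gen_features(config, age + d, group = 0,
                       shift = config$site_shift[site_idx],
                       scale_var = config$site_scale[site_idx])
    id <- sprintf("T%04d", seq_len(n))
    tab <- .assemble_table(id, paste0("S", site_idx), "training",
                           NA_integer_, NA_integer_, NA_integer_, NA_integer_,
                           covs, X)
    truth <- list(
      participants = data.frame(participant_id = id, true_bag = d,
                                stringsAsFactors = FALSE),
      site_offsets = outer(config$site_shift, config$noise_sd_map),
      burden_offsets = config$burden_effect_map,
      config = config)
    list(table = tab, truth = truth)
  })
}

#' Simulate the clinical comorbidity cohort
#'
#' Groups sized by `n_per_group` carry 0, 1 or 2 disorders; the 1-disorder
#' group is split as evenly as possible between HIV-only and cocaine-only.
#' Each participant's true latent BAG is `mediation_a[group] +
#' Normal(0, clinical_bag_sd)`; features follow the training generative
#' model evaluated at effective brain age (chronological + true BAG) with
#' the per-disorder burden offsets added, on a dedicated clinical scanner.
#' NCI is Bernoulli with log-odds
#' `nci_intercept + mediation_b * trueBAG + direct_c * group +
#' nci_zung_beta * (zung - 41) + nci_education_beta * education`,
#' so the BAG-mediated pathway is planted directly and is recoverable
#' independently of any fitted age model.
#'
#' @inheritParams simulate_training_cohort
#' @return list with `table` and `truth`; `truth$participants` carries the
#'   true BAG and the NCI linear predictor.
#' @export
simulate_clinical_cohort <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- config$seed + 1L
  with_seed(seed, {
    npg <- config$n_per_group
    n <- sum(npg)
    group <- rep(0:2, npg)
    hiv <- integer(n); cu <- integer(n)
    i1 <- which(group == 1)
    if (length(i1)) {
      half <- ceiling(length(i1) / 2)
      hiv[i1[seq_len(half)]] <- 1L
      cu[i1[-seq_len(half)]] <- 1L
    }
    hiv[group == 2] <- 1L
    cu[group == 2] <- 1L
    age <- runif(n, config$clinical_age_range[1], config$clinical_age_range[2])
    true_bag <- config$mediation_a[group + 1L] + rnorm(n, 0, config$clinical_bag_sd)
    covs <- data.frame(
      age = age,
      sex = rbinom(n, 1, 0.45),
      education = rbinom(n, 1, 0.2),
      zung = rnorm(n, 41, 8.5),
      euler = as.integer(round(rnorm(n, -45, 25))),
      motion = pmax(0.01, rnorm(n, 0.15, 0.07)))
    X <- .gen_features(config, age + true_bag, group = group,
                       shift = config$clinical_site_shift,
                       scale_var = config$clinical_site_scale)
    lp <- config$nci_intercept + config$mediation_b * true_bag +
      config$direct_c * group +
      config$nci_zung_beta * (covs$zung - 41) +
      config$nci_education_beta * covs$education
    nci <- rbinom(n, 1, plogis(lp))
    id <- sprintf("C%04d", seq_len(n))
    tab <- .assemble_table(id, "CLIN", "clinical", group, hiv, cu, nci,
                           covs, X)
    truth <- list(
      participants = data.frame(participant_id = id, group = group,
                                true_bag = true_bag, nci_lp = lp,
                                stringsAsFactors = FALSE),
      site_offsets = matrix(config$clinical_site_shift * config$noise_sd_map,
                            1, 28, dimnames = list("CLIN", feature_keys())),
      burden_offsets = config$burden_effect_map,
      config = config)
    list(table = tab, truth = truth)
  })
}

#' Simulate cognitive-domain T-scores
#'
#' Emulates a battery of `n_domains` fully adjusted T-scores: unimpaired
#' participants draw every domain from Normal(50, 10); a designated
#' impaired subset has at least two domains drawn from Normal(34, 3), two
#' SD below the T = 40 impairment cut, so planted impairment is reliably
#' below threshold in those domains.
#'
#' @param n participants.
#' @param n_domains number of cognitive domains (>= 2).
#' @param impaired_fraction proportion of participants planted as impaired.
#' @param seed RNG seed.
#' @return list with `tscores` (n x n_domains data.frame) and `impaired`
#'   (logical truth flags).
#' @export
simulate_domain_tscores <- function(n, n_domains = 7L, impaired_fraction = 0.3,
                                    seed = 1L) {
  if (n_domains < 2L) stop("config error: n_domains must be >= 2")
  if (impaired_fraction < 0 || impaired_fraction > 1) {
    stop("config error: impaired_fraction must lie in [0, 1]")
  }
  with_seed(seed, {
    ts <- matrix(rnorm(n * n_domains, 50, 10), n, n_domains,
                 dimnames = list(NULL, paste0("domain_", seq_len(n_domains))))
    n_imp <- round(impaired_fraction * n)
    impaired <- rep(FALSE, n)
    if (n_imp > 0) {
      idx <- sample.int(n, n_imp)
      impaired[idx] <- TRUE
      for (i in idx) {
        nd <- sample(2:n_domains, 1L)
        dom <- sample.int(n_domains, nd)
        ts[i, dom] <- rnorm(nd, 34, 3)
      }
    }
    list(tscores = as.data.frame(ts), impaired = impaired)
  })
}
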