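test_that("trial simulation is deterministic given the seed", {
  cfg <- trial_sim_config(n_metabolites = 20, seed = 42)
  expect_identical(simulate_trial(cfg), simulate_trial(cfg))
  d3 <- simulate_trial(trial_sim_config(n_metabolites = 20, seed = 43))
  expect_false(identical(simulate_trial(cfg)$followup, d3$followup))
})

test_that("trial layout matches the 3x3 factorial design", {
  d <- simulate_trial(trial_sim_config(n_per_cell = 5, n_metabolites = 8,
                                       seed = 1))
  tab <- table(d$lycopene_arm, d$greentea_arm)
  expect_true(all(tab == 5))
  expect_length(d$id, 45)
  expect_equal(dim(d$followup), c(45, 8))
  thin <- simulate_trial(trial_sim_config(n_per_cell = 5, n_metabolites = 8,
                                          thinning = 4L, seed = 1))
  expect_length(thin$id, 41)
})

test_that("arm_effects validation rejects out-of-range trait indices", {
  expect_error(trial_sim_config(n_metabolites = 5,
                                arm_effects = data.frame(factor = "lycopene",
                                                         arm = "supplement",
                                                         trait = 9,
                                                         effect = 1)),
               "metabolite index")
})

test_that("null trial shows no systematic arm effects", {
  diffs <- vapply(1:60, function(i) {
    d <- simulate_trial(trial_sim_config(n_metabolites = 4,
                                         skewed_fraction = 0,
                                         missing_baseline_rate = 0,
                                         seed = 100 + i))
    z <- zscore_traits(d$followup)$z[, 1]
    mean(z[d$lycopene_arm == "supplement"]) - mean(z[d$lycopene_arm == "placebo"])
  }, numeric(1))
  mc_se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * mc_se)
})

test_that("planted supplement effect is recovered by the ITT estimate", {
  ae <- data.frame(factor = "lycopene", arm = "supplement", trait = 1,
                   effect = -0.62)
  est <- vapply(1:80, function(i) {
    d <- simulate_trial(trial_sim_config(arm_effects = ae,
                                         n_metabolites = 6,
                                         skewed_fraction = 0,
                                         seed = 300 + i))
    zs <- suppressWarnings(zscore_traits(d$followup))
    f <- fit_itt(d, "lycopene", "trait001")
    truth <- attr(d, "sim_truth")
    # back to original units, then to the latent SD scale of the plant
    f$beta[f$arm == "supplement"] * zs$trait_sds["trait001"] / truth$sig[1]
  }, numeric(1))
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - (-0.62)), 3 * mc_se)
})

test_that("missingness rates apply independently per matrix", {
  d <- simulate_trial(trial_sim_config(n_metabolites = 40,
                                       missing_baseline_rate = 0.2,
                                       missing_followup_rate = 0.05,
                                       seed = 9))
  expect_gt(mean(is.na(d$baseline)), 0.15)
  expect_lt(mean(is.na(d$baseline)), 0.25)
  expect_gt(mean(is.na(d$followup)), 0.02)
  expect_lt(mean(is.na(d$followup)), 0.09)
})

test_that("gwas pair simulation is deterministic and respects bounds", {
  cfg <- gwas_sim_config(n_snps = 300, eaf_range = c(0.1, 0.6), seed = 5)
  gw <- simulate_gwas_pair(cfg)
  expect_identical(gw, simulate_gwas_pair(cfg))
  for (tab in gw) {
    expect_true(all(tab$eaf > 0.1 & tab$eaf < 0.6))
    expect_true(all(tab$se > 0))
  }
  expect_identical(gw$exposure$rsid, gw$outcome$rsid)
  pal <- is_pal <- gw$exposure$other_allele ==
    chartr("ACGT", "TGCA", gw$exposure$effect_allele)
  expect_gt(mean(pal), 0.1); expect_lt(mean(pal), 0.35)
})

test_that("simulated outcome SEs follow the case-control formula", {
  cfg <- gwas_sim_config(n_snps = 50, n_cases = 1000, n_controls = 2000,
                         seed = 2)
  gw <- simulate_gwas_pair(cfg)
  expect_equal(gw$outcome$se,
               sqrt((1 / 1000 + 1 / 2000) /
                      (2 * gw$outcome$eaf * (1 - gw$outcome$eaf))),
               tolerance = 1e-12)
})

test_that("null gwas pair gives an IVW estimate near zero", {
  gw <- simulate_gwas_pair(gwas_sim_config(n_snps = 5000, theta = 0,
                                           palindromic_fraction = 0,
                                           seed = 77))
  h <- harmonize(gw$exposure, gw$outcome)
  r <- mr_ivw(h)
  expect_lt(abs(r$beta), 3 * r$se)
})

test_that("mediation plants a dose-proportional effect recoverable by 2SLS", {
  # noise-free dose determined by arm; trait responds only through dose
  ae <- data.frame(factor = "lycopene", arm = "supplement", trait = 1,
                   effect = 0.8)
  dm <- list(lycopene = list(baseline_mean = 0, baseline_sd = 0,
                             increment = c(placebo = 0, supplement = 1,
                                           diet = 0.5),
                             noise_sd = 0),
             greentea = list(baseline_mean = 0, baseline_sd = 0,
                             increment = c(placebo = 0, supplement = 1,
                                           diet = 0.5),
                             noise_sd = 0))
  est <- vapply(1:40, function(i) {
    d <- simulate_trial(trial_sim_config(n_metabolites = 3, mediation = TRUE,
                                         arm_effects = ae, dose_model = dm,
                                         skewed_fraction = 0,
                                         trait_locations = 0, trait_scales = 1,
                                         missing_baseline_rate = 0,
                                         seed = 600 + i))
    tsls(d, "lycopene", "trait001", adjusted = FALSE,
         standardize = FALSE)$beta
  }, numeric(1))
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.8), 3 * mc_se)
})
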