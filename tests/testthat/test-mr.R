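# The MR engine: instrument arithmetic, harmonisation, and the four
# estimators, checked against closed forms and brute-force oracles.

tab2 <- read_summary_tsv(system.file("extdata", "metabolite_instruments.tsv",
                                     package = "trialmr"))

test_that("per-variant r2 reproduces the published instrument cells", {
  expect_equal(round(snp_r2(0.41, 0.086), 4), 0.0036)   # valine rs10211524
  expect_equal(round(snp_r2(0.76, -0.083), 4), 0.0025)  # DHA rs11604424
  expect_equal(round(snp_r2(0.64, -0.081), 4), 0.0030)  # pyruvate rs1260326
  expect_equal(snp_r2(0.3, 0), 0)
  expect_error(snp_r2(1.2, 0.1), "eaf")
})

test_that("combined F uses the minimum-N convention and matches print", {
  ace <- tab2[tab2$phenotype == "acetate", ]
  expect_equal(round(instrument_f(snp_r2(ace$eaf, ace$beta), ace$n)$f_stat, 1),
               44.3)
  pyr <- tab2[tab2$phenotype == "pyruvate", ]
  fp <- instrument_f(snp_r2(pyr$eaf, pyr$beta), pyr$n)
  expect_equal(fp$n_used, 22529)
  expect_equal(round(fp$f_stat, 1), 59.4)
  val <- tab2[tab2$phenotype == "valine", ]
  expect_equal(round(instrument_f(snp_r2(val$eaf, val$beta), val$n)$f_stat, 1),
               79.0)
  expect_equal(instrument_f(0, 1000)$f_stat, 0)
})

test_that("instrument selection filters strictly below the threshold", {
  expect_equal(nrow(select_instruments(tab2[tab2$phenotype == "pyruvate", ])),
               2)
  expect_equal(nrow(suppressMessages(select_instruments(tab2, 0))), 0)
  mixed <- make_stats(c("rs1", "rs2"), c("A", "C"), c("G", "T"),
                      c(0.3, 0.4), c(0.1, 0.1), c(0.01, 0.01),
                      pval = c(1e-7, 1e-9))
  kept <- select_instruments(mixed)
  expect_identical(kept$rsid, "rs2")
})

test_that("the published instrument fixture parses to 17 records, 5 exposures", {
  expect_equal(nrow(tab2), 17)
  expect_length(unique(tab2$phenotype), 5)
  expect_equal(tab2$pval[tab2$rsid == "rs10211524"], 5.24e-20)
  expect_true(all(tab2$se > 0))
})

test_that("harmonisation keeps, flips and drops correctly", {
  ex <- make_stats(c("rs1", "rs2", "rs3", "rs4", "rs5"),
                   c("A", "C", "A", "A", "C"),
                   c("G", "T", "T", "G", "G"),
                   c(0.2, 0.3, 0.2, 0.25, 0.5),
                   c(0.1, -0.2, 0.15, 0.1, 0.1),
                   rep(0.02, 5))
  ou <- make_stats(c("rs1", "rs2", "rs3", "rs4", "rs5"),
                   c("A", "T", "T", "C", "C"),
                   c("G", "C", "A", "G", "G"),
                   c(0.2, 0.7, 0.8, 0.5, 0.5),
                   c(0.05, 0.08, -0.04, 0.02, 0.02),
                   rep(0.03, 5))
  h <- harmonize(ex, ou)
  aud <- attr(h, "audit")
  # rs1 identical coding: kept untouched
  expect_equal(h$by[h$rsid == "rs1"], 0.05)
  # rs2 swapped coding: sign-flip and eaf complement
  expect_equal(h$by[h$rsid == "rs2"], -0.08)
  expect_equal(h$eaf_y[h$rsid == "rs2"], 0.3)
  # rs3 palindromic, MAFs 0.2/0.2, frequencies agree after orientation
  expect_true(h$palindromic[h$rsid == "rs3"])
  expect_equal(h$by[h$rsid == "rs3"], 0.04)
  # rs4 alleles irreconcilable
  expect_identical(aud$reason[aud$rsid == "rs4"], "allele_mismatch")
  # rs5 palindromic with MAF 0.5: ambiguous
  expect_identical(aud$reason[aud$rsid == "rs5"], "palindromic_ambiguous")
  expect_false("rs5" %in% h$rsid)
})

test_that("harmonisation resolves opposite-strand records", {
  ex <- make_stats("rs9", "A", "G", 0.3, 0.12, 0.02)
  ou_same <- make_stats("rs9", "T", "C", 0.3, 0.07, 0.03)   # complement
  ou_swap <- make_stats("rs9", "C", "T", 0.7, 0.07, 0.03)   # complement, swapped
  expect_equal(harmonize(ex, ou_same)$by, 0.07)
  h2 <- harmonize(ex, ou_swap)
  expect_equal(h2$by, -0.07)
  expect_equal(h2$eaf_y, 0.3)
})

test_that("duplicate rsids are rejected", {
  ex <- make_stats(c("rs1", "rs1"), c("A", "A"), c("G", "G"),
                   c(0.2, 0.2), c(0.1, 0.1), c(0.02, 0.02))
  expect_error(harmonize(ex, make_stats("rs1", "A", "G", 0.2, 0.1, 0.02)),
               "duplicate")
})

test_that("allele recoding of the exposure leaves MR estimates unchanged", {
  set.seed(64)
  gw <- simulate_gwas_pair(gwas_sim_config(n_snps = 30, theta = 0.2,
                                           palindromic_fraction = 0,
                                           seed = 19))
  ex <- gw$exposure
  h0 <- harmonize(ex, gw$outcome)
  # recode a handful of exposure records to the opposite allele
  ex2 <- ex
  for (i in c(2, 7, 20)) {
    ex2$effect_allele[i] <- ex$other_allele[i]
    ex2$other_allele[i] <- ex$effect_allele[i]
    ex2$beta[i] <- -ex$beta[i]
    ex2$eaf[i] <- 1 - ex$eaf[i]
  }
  h1 <- harmonize(ex2, gw$outcome)
  expect_equal(mr_ivw(h1)$beta, mr_ivw(h0)$beta, tolerance = 1e-13)
  expect_equal(mr_ivw(h1)$se, mr_ivw(h0)$se, tolerance = 1e-13)
  expect_equal(mr_egger(h1)$beta, mr_egger(h0)$beta, tolerance = 1e-13)
  expect_equal(mr_egger(h1)$egger_intercept, mr_egger(h0)$egger_intercept,
               tolerance = 1e-13)
  w0 <- mr_weighted_median(h0, n_boot = 50, seed = 1)
  w1 <- mr_weighted_median(h1, n_boot = 50, seed = 1)
  expect_equal(w1$beta, w0$beta, tolerance = 1e-13)
})

test_that("Wald ratio matches hand computation and symmetry", {
  expect_equal(wald_ratio(0.5, 0.1, 0.1, 0.05),
               list(beta = 0.2, se = 0.1))
  same <- wald_ratio(0.3, 0.02, 0.3, 0.02)
  expect_equal(same$beta, 1)
  flip <- wald_ratio(-0.5, 0.1, -0.1, 0.05)
  expect_equal(flip$beta, 0.2)
  expect_equal(flip$se, 0.1)
  expect_error(wald_ratio(0, 0.1, 0.1, 0.05), "bx")
  # second-order form is never smaller
  expect_gte(wald_ratio(0.5, 0.1, 0.1, 0.05, second_order = TRUE)$se, 0.1)
})

test_that("IVW reduces to the Wald ratio and pools closed-form", {
  h1 <- make_h(0.5, 0.1, 0.05)
  r1 <- mr_ivw(h1)
  w <- wald_ratio(0.5, 0.01, 0.1, 0.05)
  expect_equal(r1$beta, w$beta, tolerance = 1e-14)
  expect_equal(r1$se, w$se, tolerance = 1e-14)
  # two identical variants: same estimate, se shrinks by sqrt(2)
  h2 <- make_h(c(0.5, 0.5), c(0.1, 0.1), c(0.05, 0.05))
  r2 <- mr_ivw(h2)
  expect_equal(r2$beta, 0.2, tolerance = 1e-14)
  expect_equal(r2$se, r1$se / sqrt(2), tolerance = 1e-14)
  expect_error(mr_ivw(make_h(c(0.5, 0), c(0.1, 0.1), c(0.05, 0.05))), "bx")
})

test_that("IVW equals the origin-constrained WLS oracle", {
  set.seed(11)
  h <- make_h(runif(40, 0.02, 0.3), rnorm(40, 0.05, 0.02),
              runif(40, 0.01, 0.08))
  fit <- lm(by ~ 0 + bx, data = h, weights = 1 / h$se_y^2)
  expect_equal(mr_ivw(h)$beta, unname(coef(fit)), tolerance = 1e-12)
})

test_that("Egger with zero intercept reproduces IVW, and handles exact fit", {
  set.seed(13)
  h <- make_h(runif(20, 0.05, 0.3), rnorm(20, 0.04, 0.03),
              runif(20, 0.01, 0.08))
  ivw <- mr_ivw(h)
  # constrain the intercept via the same WLS normal equations
  constrained <- sum(h$by * h$bx / h$se_y^2) / sum(h$bx^2 / h$se_y^2)
  expect_equal(ivw$beta, constrained, tolerance = 1e-13)
  # exactly collinear points: perfect fit, dispersion floored at 1
  hc <- make_h(c(0.1, 0.2, 0.3), 0.05 + 0.25 * c(0.1, 0.2, 0.3),
               c(0.02, 0.03, 0.04))
  eg <- mr_egger(hc)
  expect_equal(eg$beta, 0.25, tolerance = 1e-10)
  expect_equal(eg$egger_intercept, 0.05, tolerance = 1e-10)
  expect_true(is.finite(eg$se) && eg$se > 0)
  expect_error(mr_egger(make_h(c(0.1, 0.1, 0.1), c(1, 1, 1), c(1, 1, 1))),
               "spread")
  expect_error(mr_egger(make_h(c(0.1, 0.2), c(1, 1), c(1, 1))), "at least 3")
})

test_that("weighted median matches plain median and the brute-force scan", {
  # equal weights, odd k: plain median
  h <- make_h(c(1, 1, 1), c(1, 2, 9), c(1, 1, 1))
  expect_equal(mr_weighted_median(h, n_boot = 10, seed = 1)$beta, 2)
  # equal weights, even k: midpoint
  h4 <- make_h(rep(1, 4), c(1, 2, 5, 9), rep(1, 4))
  expect_equal(mr_weighted_median(h4, n_boot = 10, seed = 1)$beta, 3.5)
  # dominant weight takes its own ratio
  hd <- make_h(c(2, 0.5, 0.5), c(2 * 1.4, 0.5 * 3, 0.5 * 5), c(1, 1, 1))
  expect_equal(mr_weighted_median(hd, n_boot = 10, seed = 1)$beta, 1.4)
  # random cases vs the independent weighted-CDF scan
  set.seed(17)
  for (rep in 1:20) {
    k <- sample(3:12, 1)
    bx <- runif(k, 0.05, 0.4)
    by <- rnorm(k, 0.1, 0.1)
    se_y <- runif(k, 0.01, 0.1)
    hh <- make_h(bx, by, se_y)
    expect_equal(mr_weighted_median(hh, n_boot = 2, seed = 1)$beta,
                 bf_weighted_median(by / bx, bx^2 / se_y^2),
                 tolerance = 1e-12)
  }
})

test_that("weighted median bootstrap SE is seeded and reproducible", {
  set.seed(23)
  h <- make_h(runif(10, 0.1, 0.3), rnorm(10, 0.05, 0.05),
              runif(10, 0.02, 0.06), se_x = runif(10, 0.005, 0.02))
  a <- mr_weighted_median(h, n_boot = 200, seed = 42)
  b <- mr_weighted_median(h, n_boot = 200, seed = 42)
  expect_identical(a, b)
  c_ <- mr_weighted_median(h, n_boot = 200, seed = 43)
  expect_false(identical(a$se, c_$se))
})

test_that("weighted median resists a pleiotropic minority", {
  set.seed(29)
  est <- vapply(1:60, function(i) {
    k_valid <- 12; k_bad <- 6
    bx <- runif(k_valid + k_bad, 0.15, 0.3)
    se_y <- rep(0.005, k_valid + k_bad)
    by <- 0.25 * bx + rnorm(k_valid + k_bad, sd = se_y)
    by[(k_valid + 1):(k_valid + k_bad)] <-
      by[(k_valid + 1):(k_valid + k_bad)] + 0.08
    h <- make_h(bx, by, se_y)
    c(mr_weighted_median(h, n_boot = 2, seed = i)$beta, mr_ivw(h)$beta)
  }, numeric(2))
  wm_err <- abs(mean(est[1, ]) - 0.25)
  ivw_err <- abs(mean(est[2, ]) - 0.25)
  expect_lt(wm_err, 0.03)
  expect_gt(ivw_err, 0.05)          # IVW pulled by the pleiotropic minority
  expect_lt(wm_err, ivw_err / 3)
})

test_that("odds-ratio reporting inverts the published pyruvate interval", {
  r <- trialmr:::mr_result("ivw", beta = 0.2546, se = 0.1152, n_snps = 2)
  out <- report_or(r, bonferroni_m = 4)
  expect_equal(round(out$or_, 2), 1.29)
  expect_equal(round(out$ci_low_or, 2), 1.03)
  expect_equal(round(out$ci_high_or, 2), 1.62)
  expect_equal(out$bonferroni_threshold, 0.0125)
  null <- report_or(trialmr:::mr_result("ivw", beta = 0, se = 0.1,
                                        n_snps = 1), 1)
  expect_equal(null$or_, 1)
  expect_equal(null$ci_low_or * null$ci_high_or, 1, tolerance = 1e-12)
})

test_that("IVW type-I error is near nominal under the null", {
  rej <- vapply(1:400, function(i) {
    gw <- simulate_gwas_pair(gwas_sim_config(n_snps = 60, theta = 0,
                                             palindromic_fraction = 0,
                                             seed = 30000 + i))
    h <- harmonize(gw$exposure, gw$outcome)
    mr_ivw(h)$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})
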