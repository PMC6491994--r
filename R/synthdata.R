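# Synthetic factorial-trial and GWAS summary-statistic generators.
# Every downstream stage (ITT screen, 2SLS, two-sample MR) has a known
# ground truth here, so estimator recovery can be tested without any
# external download.

#' Configuration for the factorial-trial simulator
#'
#' Describes a 3x3 factorial dietary trial (lycopene x green tea, arms
#' placebo / supplement / diet) over a panel of correlated metabolic traits
#' measured at baseline and six-month follow-up, together with serum
#' biomarker doses (lycopene in umol/L, EGCG in nM).
#'
#' Trait covariance follows a latent factor model with block-sparse
#' loadings: each trait loads primarily on one of `n_factors` factors
#' (loading `loading_scale`) plus weak dense cross-loadings
#' (`cross_loading * loading_scale`), emulating the block correlation of
#' NMR panels, where groups of traits (amino acids, glycolysis
#' intermediates, and particularly the 14 lipoprotein subclasses) move
#' near-jointly. Within a block the trait correlation is roughly
#' `1 / (1 + q c^2 + 1/s^2)` for `q = n_factors`, `s = loading_scale`,
#' `c = cross_loading`. Under the defaults (`n_factors = 14`,
#' `loading_scale = 30`, `cross_loading = 0.005`) a sample of ~128
#' participants yields about 14 principal components for 95% of the
#' panel variance — the regime in which an effective-number-of-tests
#' multiplicity correction is well calibrated.
#'
#' @param n_per_cell Participants per factorial cell (9 cells). Default
#'   `ceiling(128/9)` = 15, emulating a ~128-participant trial.
#' @param n_metabolites Number of metabolic traits (default 159).
#' @param n_factors Latent factors generating the trait covariance; each
#'   trait is assigned one primary factor, round-robin.
#' @param loading_scale Primary loading per trait (unitless).
#' @param cross_loading Relative scale of the dense secondary loadings
#'   (fraction of `loading_scale`).
#' @param baseline_carryover Correlation `rho` in [0,1] between the
#'   baseline and follow-up latent trait values (default 0.5).
#' @param arm_effects `data.frame` with columns `factor`
#'   (`"lycopene"`/`"greentea"`), `arm` (`"supplement"`/`"diet"`), `trait`
#'   (index) and `effect`. With `mediation = FALSE`, `effect` is the planted
#'   follow-up shift in SD units versus placebo. With `mediation = TRUE`,
#'   `effect` is the slope gamma: the trait responds only through the
#'   realised biomarker dose, as `gamma * dose` (SD units per dose unit),
#'   and the `arm` column is ignored (all arms respond through their dose).
#' @param dose_model Named list per factor with elements `baseline_mean`,
#'   `baseline_sd`, `increment` (named vector: placebo/supplement/diet mean
#'   dose increment, in umol/L or nM) and `noise_sd`.
#' @param mediation Logical; see `arm_effects`.
#' @param confounding_strength SD of a shared participant-level component
#'   added to both the biomarker doses and the follow-up traits
#'   (confounds dose-outcome regressions; randomised arms stay clean).
#' @param missing_baseline_rate,missing_followup_rate Independent
#'   per-entry missingness probabilities for the two trait matrices.
#' @param skewed_fraction Fraction of traits given a log-normal
#'   (right-skewed) margin by exponentiating the standardized value.
#' @param trait_locations,trait_scales Optional fixed concentration
#'   location/scale applied to every trait (length 1 or `n_metabolites`).
#'   `NULL` (default) draws them as U(1,10) and U(0.5,2) per trait, giving
#'   heterogeneous units as in a real panel; fixing them to 0 and 1 leaves
#'   traits on the latent SD scale.
#' @param thinning Number of participants to drop at random after cell
#'   assignment (default 0), to emulate slightly unequal arm sizes.
#' @param seed Integer seed; one seed drives the whole simulation and the
#'   output is deterministic given it.
#' @return An object of class `trial_sim_config`.
#' @seealso [simulate_trial()]
#' @export
trial_sim_config <- function(n_per_cell = ceiling(128 / 9),
                             n_metabolites = 159,
                             n_factors = 14,
                             loading_scale = 30,
                             cross_loading = 0.005,
                             baseline_carryover = 0.5,
                             arm_effects = NULL,
                             dose_model = NULL,
                             mediation = FALSE,
                             confounding_strength = 0,
                             missing_baseline_rate = 0.07,
                             missing_followup_rate = 0,
                             skewed_fraction = 0.2,
                             trait_locations = NULL,
                             trait_scales = NULL,
                             thinning = 0L,
                             seed = 1L) {
  stopifnot(n_per_cell >= 2, n_metabolites >= 1, n_factors >= 1,
            baseline_carryover >= 0, baseline_carryover <= 1,
            missing_baseline_rate >= 0, missing_baseline_rate <= 1,
            missing_followup_rate >= 0, missing_followup_rate <= 1,
            skewed_fraction >= 0, skewed_fraction <= 1,
            confounding_strength >= 0)
  if (is.null(dose_model)) {
    dose_model <- list(
      lycopene = list(baseline_mean = 0.6, baseline_sd = 0.2,
                      increment = c(placebo = 0, supplement = 1.0, diet = 0.6),
                      noise_sd = 0.25),
      greentea = list(baseline_mean = 10, baseline_sd = 5,
                      increment = c(placebo = 0, supplement = 150, diet = 100),
                      noise_sd = 40)
    )
  }
  if (!is.null(arm_effects)) {
    stopifnot(is.data.frame(arm_effects),
              all(c("factor", "arm", "trait", "effect") %in% names(arm_effects)))
    if (any(arm_effects$trait < 1 | arm_effects$trait > n_metabolites))
      stop("arm_effects refers to a metabolite index outside 1..n_metabolites")
  }
  structure(list(n_per_cell = as.integer(n_per_cell),
                 n_metabolites = as.integer(n_metabolites),
                 n_factors = as.integer(n_factors),
                 loading_scale = loading_scale,
                 cross_loading = cross_loading,
                 baseline_carryover = baseline_carryover,
                 arm_effects = arm_effects,
                 dose_model = dose_model,
                 mediation = isTRUE(mediation),
                 confounding_strength = confounding_strength,
                 missing_baseline_rate = missing_baseline_rate,
                 missing_followup_rate = missing_followup_rate,
                 skewed_fraction = skewed_fraction,
                 trait_locations = trait_locations,
                 trait_scales = trait_scales,
                 thinning = as.integer(thinning),
                 seed = as.integer(seed)),
            class = "trial_sim_config")
}

arm_levels <- c("placebo", "supplement", "diet")

# stable sub-seed per named stream, derived from the global seed
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.integer(seed) * 1009L + as.integer(h %% 1000003L)) %% 2147483587L
}

#' Simulate a 3x3 factorial dietary trial
#'
#' Generates participant arm assignments, baseline/follow-up metabolite
#' matrices from a latent-factor covariance, and biomarker doses, with
#' optional planted arm effects, dose mediation, confounding, skewed
#' margins and missingness. Deterministic given `cfg$seed`.
#'
#' Follow-up latent values are
#' `rho * baseline + sqrt(1 - rho^2) * fresh + planted effect + confounding`,
#' so that under the null baseline and follow-up have equal unit variance
#' and correlation `rho`. Planted effects are in SD units of this latent
#' scale, which downstream z-scoring recovers.
#'
#' @param cfg A [trial_sim_config()].
#' @return A `trial_dataset`: list with `id`, `lycopene_arm`,
#'   `greentea_arm` (factors with levels placebo/supplement/diet),
#'   `lycopene_umol_l`, `egcg_nm` (follow-up serum doses),
#'   `baseline`, `followup` (participants x traits concentration matrices),
#'   and `trait_names`.
#' @examples
#' d <- simulate_trial(trial_sim_config(n_metabolites = 10, seed = 42))
#' table(d$lycopene_arm, d$greentea_arm)
#' @export
simulate_trial <- function(cfg) {
  stopifnot(inherits(cfg, "trial_sim_config"))
  p <- cfg$n_metabolites
  q <- cfg$n_factors
  rho <- cfg$baseline_carryover

  set.seed(substream_seed(cfg$seed, "structure"))
  cells <- expand.grid(lycopene = arm_levels, greentea = arm_levels,
                       stringsAsFactors = FALSE)
  lyc <- rep(cells$lycopene, each = cfg$n_per_cell)
  gt <- rep(cells$greentea, each = cfg$n_per_cell)
  n <- length(lyc)
  if (cfg$thinning > 0) {
    keep <- sort(sample.int(n, n - cfg$thinning))
    lyc <- lyc[keep]; gt <- gt[keep]; n <- length(keep)
  }
  block <- rep_len(seq_len(q), p)              # primary factor per trait
  lambda <- matrix(stats::rnorm(p * q, sd = cfg$cross_loading *
                                  cfg$loading_scale), p, q)
  lambda[cbind(seq_len(p), block)] <-
    lambda[cbind(seq_len(p), block)] + cfg$loading_scale
  trait_scale <- sqrt(rowSums(lambda^2) + 1)   # latent SD per trait
  mu <- if (is.null(cfg$trait_locations)) stats::runif(p, 1, 10)
        else rep_len(cfg$trait_locations, p)
  sig <- if (is.null(cfg$trait_scales)) stats::runif(p, 0.5, 2)
         else rep_len(cfg$trait_scales, p)
  n_skew <- round(cfg$skewed_fraction * p)
  skewed <- if (n_skew > 0) sample.int(p, n_skew) else integer(0)

  draw_std <- function(stream) {
    set.seed(substream_seed(cfg$seed, stream))
    f <- matrix(stats::rnorm(n * q), n, q)
    e <- matrix(stats::rnorm(n * p), n, p)
    sweep(f %*% t(lambda) + e, 2, trait_scale, "/")  # unit-variance latents
  }
  base_std <- draw_std("baseline")
  fu_std <- rho * base_std + sqrt(1 - rho^2) * draw_std("followup")

  # shared participant-level confounder: enters doses and follow-up traits
  set.seed(substream_seed(cfg$seed, "confound"))
  u <- stats::rnorm(n)
  if (cfg$confounding_strength > 0)
    fu_std <- fu_std + cfg$confounding_strength * u

  # biomarker doses at follow-up
  set.seed(substream_seed(cfg$seed, "dose"))
  dose_of <- function(fac, arms) {
    dm <- cfg$dose_model[[fac]]
    dm$baseline_mean + stats::rnorm(n, sd = dm$baseline_sd) +
      unname(dm$increment[arms]) +
      stats::rnorm(n, sd = dm$noise_sd) +
      cfg$confounding_strength * u * dm$noise_sd
  }
  lyc_dose <- dose_of("lycopene", lyc)
  gt_dose <- dose_of("greentea", gt)

  # planted intervention effects
  if (!is.null(cfg$arm_effects)) {
    ae <- cfg$arm_effects
    for (i in seq_len(nrow(ae))) {
      arms <- if (ae$factor[i] == "lycopene") lyc else gt
      dose <- if (ae$factor[i] == "lycopene") lyc_dose else gt_dose
      j <- ae$trait[i]
      if (cfg$mediation) {
        fu_std[, j] <- fu_std[, j] + ae$effect[i] * dose
      } else {
        fu_std[arms == ae$arm[i], j] <-
          fu_std[arms == ae$arm[i], j] + ae$effect[i]
      }
    }
  }

  to_conc <- function(m) {
    if (length(skewed)) m[, skewed] <- exp(m[, skewed])
    sweep(sweep(m, 2, sig, "*"), 2, mu, "+")
  }
  baseline <- to_conc(base_std)
  followup <- to_conc(fu_std)

  set.seed(substream_seed(cfg$seed, "missing"))
  punch <- function(m, rate) {
    if (rate > 0) m[matrix(stats::runif(length(m)) < rate, nrow(m))] <- NA
    m
  }
  baseline <- punch(baseline, cfg$missing_baseline_rate)
  followup <- punch(followup, cfg$missing_followup_rate)

  trait_names <- sprintf("trait%03d", seq_len(p))
  colnames(baseline) <- colnames(followup) <- trait_names
  out <- structure(list(id = sprintf("P%04d", seq_len(n)),
                 lycopene_arm = factor(lyc, levels = arm_levels),
                 greentea_arm = factor(gt, levels = arm_levels),
                 lycopene_umol_l = lyc_dose,
                 egcg_nm = gt_dose,
                 baseline = baseline,
                 followup = followup,
                 trait_names = trait_names),
            class = "trial_dataset")
  # ground truth of the draw, for recovery tests (not serialised to CSV)
  attr(out, "sim_truth") <- list(mu = mu, sig = sig, skewed = skewed)
  out
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat("trial_dataset:", length(x$id), "participants,",
      length(x$trait_names), "metabolic traits\n")
  print(table(lycopene = x$lycopene_arm, greentea = x$greentea_arm))
  invisible(x)
}

#' Configuration for the paired GWAS summary-statistics simulator
#'
#' Emulates the two-sample Mendelian randomisation design: one set of
#' per-SNP associations with a standardized metabolite (exposure, linear
#' scale, SD per allele) and one with a binary disease (outcome, log-odds
#' per allele), sharing instruments and a known causal effect.
#'
#' @param n_snps Number of variants.
#' @param eaf_range Interval inside (0,1) for effect-allele frequencies.
#' @param exposure_beta_scale SD of the per-allele exposure effects
#'   (SD units of the metabolite per allele).
#' @param n_exposure Exposure GWAS sample size (default 24,000, the scale
#'   of published metabolite GWAS).
#' @param n_cases,n_controls Outcome GWAS case/control counts (defaults
#'   44,825 / 27,904, the scale of large prostate-cancer consortia).
#' @param theta True causal effect, log-odds of disease per SD of exposure.
#' @param pleiotropy_mean,pleiotropy_sd Directional/balanced horizontal
#'   pleiotropy added to outcome effects (log-odds scale).
#' @param palindromic_fraction Fraction of SNPs given strand-ambiguous
#'   (A/T or C/G) allele pairs.
#' @param seed Integer seed.
#' @return An object of class `gwas_sim_config`.
#' @export
gwas_sim_config <- function(n_snps = 200L,
                            eaf_range = c(0.05, 0.95),
                            exposure_beta_scale = 0.1,
                            n_exposure = 24000L,
                            n_cases = 44825L,
                            n_controls = 27904L,
                            theta = 0,
                            pleiotropy_mean = 0,
                            pleiotropy_sd = 0,
                            palindromic_fraction = 0.2,
                            seed = 1L) {
  stopifnot(n_snps >= 1, length(eaf_range) == 2,
            eaf_range[1] > 0, eaf_range[2] < 1, eaf_range[1] < eaf_range[2],
            n_exposure > 0, n_cases > 0, n_controls > 0,
            pleiotropy_sd >= 0,
            palindromic_fraction >= 0, palindromic_fraction <= 1)
  structure(list(n_snps = as.integer(n_snps), eaf_range = eaf_range,
                 exposure_beta_scale = exposure_beta_scale,
                 n_exposure = n_exposure, n_cases = n_cases,
                 n_controls = n_controls, theta = theta,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 palindromic_fraction = palindromic_fraction,
                 seed = as.integer(seed)),
            class = "gwas_sim_config")
}

#' Simulate a paired exposure/outcome summary-statistics set
#'
#' Per SNP j: EAF `p_j ~ U(eaf_range)`; exposure effect
#' `bx_j ~ N(0, exposure_beta_scale^2)` with
#' `SE(bx)_j = 1/sqrt(2 p_j (1-p_j) n_exposure)` (the exposure effects are
#' treated as estimated without error, the usual NOME simplification);
#' outcome effect `by_j = theta * bx_j + sign(bx_j) * alpha_j + eps_j`
#' with `alpha_j ~ N(pleiotropy_mean, pleiotropy_sd^2)` — the pleiotropy
#' term rides on the exposure-increasing allele, the orientation in
#' which the MR-Egger intercept is defined —,
#' `eps_j ~ N(0, SE(by)_j^2)` and
#' `SE(by)_j = sqrt((1/n_cases + 1/n_controls) / (2 p_j (1-p_j)))`.
#' A configurable fraction of SNPs get palindromic (A/T, C/G) allele pairs.
#'
#' @param cfg A [gwas_sim_config()].
#' @return List with elements `exposure` and `outcome`, each a
#'   `data.frame` with columns rsid, chr, pos, effect_allele, other_allele,
#'   eaf, beta, se, pval, n (the summary-statistics dialect used
#'   throughout the package).
#' @examples
#' gw <- simulate_gwas_pair(gwas_sim_config(n_snps = 50, theta = 0.25, seed = 3))
#' head(gw$exposure)
#' @export
simulate_gwas_pair <- function(cfg) {
  stopifnot(inherits(cfg, "gwas_sim_config"))
  set.seed(substream_seed(cfg$seed, "gwas"))
  m <- cfg$n_snps
  eaf <- stats::runif(m, cfg$eaf_range[1], cfg$eaf_range[2])
  bx <- stats::rnorm(m, sd = cfg$exposure_beta_scale)
  se_x <- 1 / sqrt(2 * eaf * (1 - eaf) * cfg$n_exposure)
  se_y <- sqrt((1 / cfg$n_cases + 1 / cfg$n_controls) / (2 * eaf * (1 - eaf)))
  alpha <- if (cfg$pleiotropy_sd > 0 || cfg$pleiotropy_mean != 0)
    stats::rnorm(m, cfg$pleiotropy_mean, cfg$pleiotropy_sd) else numeric(m)
  # directional pleiotropy attaches to the exposure-increasing allele
  # (the orientation in which the Egger intercept is defined)
  by <- cfg$theta * bx + sign(bx) * alpha + stats::rnorm(m, sd = se_y)

  pal <- stats::runif(m) < cfg$palindromic_fraction
  pairs_std <- matrix(c("A", "G", "C", "T", "G", "A", "T", "C"), ncol = 2,
                      byrow = TRUE)
  pairs_pal <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"), ncol = 2,
                      byrow = TRUE)
  pick <- function(is_pal) {
    tab <- if (is_pal) pairs_pal else pairs_std
    tab[sample.int(nrow(tab), 1), ]
  }
  al <- t(vapply(pal, pick, character(2)))

  mk <- function(beta, se, n) {
    data.frame(rsid = sprintf("rs%06d", seq_len(m)),
               chr = sample(1:22, m, replace = TRUE),
               pos = sample.int(1e8, m),
               effect_allele = al[, 1], other_allele = al[, 2],
               eaf = eaf, beta = beta, se = se,
               pval = 2 * stats::pnorm(-abs(beta / se)),
               n = n, stringsAsFactors = FALSE)
  }
  list(exposure = mk(bx, se_x, cfg$n_exposure),
       outcome = mk(by, se_y, cfg$n_cases + cfg$n_controls))
}
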