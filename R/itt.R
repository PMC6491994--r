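# Intention-to-treat screening of follow-up metabolites across factorial
# arms: z-scoring, robust per-trait contrasts vs placebo, a PCA-based
# multiplicity threshold, and diet-vs-supplement concordance.

#' Convert a concentration matrix to standard-deviation (z) scores
#'
#' Each trait (column) is centred and scaled to sample SD 1 (n-1
#' denominator) over its non-missing entries; missing entries are
#' preserved. The original per-trait SDs are returned so effect estimates
#' can be back-transformed to concentration units. Traits with fewer than
#' two non-missing values or zero variance cannot be standardized: they
#' are excluded from the returned matrix and reported, with a warning.
#'
#' @param mat Numeric matrix, participants x traits, with column names.
#' @return List with `z` (standardized matrix, excluded traits removed),
#'   `trait_sds` and `trait_means` (named, original units, analysed traits
#'   only) and `excluded` (character vector of excluded trait names).
#' @examples
#' zscore_traits(cbind(a = c(1, 2, 3)))$z
#' @export
zscore_traits <- function(mat) {
  stopifnot(is.matrix(mat), !is.null(colnames(mat)))
  n_ok <- colSums(!is.na(mat))
  sds <- apply(mat, 2, stats::sd, na.rm = TRUE)
  bad <- n_ok < 2 | is.na(sds) | sds == 0
  if (any(bad))
    warning("excluding ", sum(bad), " constant/degenerate trait(s): ",
            paste(colnames(mat)[bad], collapse = ", "))
  keep <- which(!bad)
  mns <- colMeans(mat[, keep, drop = FALSE], na.rm = TRUE)
  z <- sweep(sweep(mat[, keep, drop = FALSE], 2, mns, "-"), 2, sds[keep], "/")
  list(z = z, trait_sds = sds[keep], trait_means = mns,
       excluded = colnames(mat)[bad])
}

# OLS with sandwich covariance; CI/p reference is t(resid df) by
# default, as in robust trial regressions; "normal" gives 1.96-style
# intervals.
contrast_rows <- function(fit, terms, labels, trait, fac, adjusted,
                          hc_type, df_ref) {
  vc <- sandwich::vcovHC(fit, type = hc_type)
  b <- stats::coef(fit)[terms]
  se <- sqrt(diag(vc)[terms])
  crit <- if (identical(df_ref, "normal")) stats::qnorm(0.975)
          else stats::qt(0.975, df = fit$df.residual)
  pfun <- if (identical(df_ref, "normal"))
    function(t) 2 * stats::pnorm(-abs(t))
  else
    function(t) 2 * stats::pt(-abs(t), df = fit$df.residual)
  data.frame(trait = trait, factor = fac, arm = labels,
             beta = unname(b), se = unname(se),
             ci_low = unname(b - crit * se), ci_high = unname(b + crit * se),
             p = unname(pfun(b / se)),
             n_used = stats::nobs(fit), adjusted = adjusted,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Intention-to-treat contrast of one trait across one factor's arms
#'
#' Ordinary least squares of the standardized follow-up trait on two arm
#' indicators (supplement, diet) with placebo as reference; the other
#' factor is ignored (marginal analysis of the factorial design).
#' Standard errors are heteroskedasticity-consistent (HC1 by default,
#' matching the robust option of common trial software; HC0-HC3
#' available). The adjusted variant adds the standardized baseline trait
#' as a covariate and restricts to complete baseline + follow-up cases.
#'
#' @param dataset A `trial_dataset` (from [simulate_trial()] or
#'   [read_trial_csv()]).
#' @param factor_name `"lycopene"` or `"greentea"`.
#' @param trait Trait name (column of the follow-up matrix).
#' @param adjusted Add the baseline z-score as covariate (default FALSE).
#' @param hc_type Sandwich flavour passed to [sandwich::vcovHC()]
#'   (default `"HC1"`).
#' @param df_ref Reference distribution for CIs and p-values: `"t"`
#'   (default, residual degrees of freedom, matching standard
#'   robust-regression output) or `"normal"` (1.96-style intervals).
#' @param standardize z-score the matrices before fitting (default TRUE);
#'   set FALSE when the input is already on the analysis scale.
#' @param zscores Optional precomputed [zscore_traits()] results (list
#'   with `followup` and `baseline`) to avoid re-standardizing in loops;
#'   computed on the fly when NULL.
#' @return `data.frame` with one row per arm (supplement, diet): trait,
#'   factor, arm, beta (SD units vs placebo), se, ci_low, ci_high, p,
#'   n_used, adjusted.
#' @export
fit_itt <- function(dataset, factor_name = c("lycopene", "greentea"),
                    trait, adjusted = FALSE, hc_type = "HC1",
                    df_ref = c("t", "normal"), standardize = TRUE,
                    zscores = NULL) {
  factor_name <- match.arg(factor_name)
  df_ref <- match.arg(df_ref)
  stopifnot(inherits(dataset, "trial_dataset"),
            trait %in% dataset$trait_names)
  if (is.null(zscores)) {
    zscores <- if (standardize)
      list(followup = zscore_traits(dataset$followup),
           baseline = zscore_traits(dataset$baseline))
    else
      list(followup = list(z = dataset$followup),
           baseline = list(z = dataset$baseline))
  }
  if (!trait %in% colnames(zscores$followup$z))
    stop("trait '", trait, "' was excluded during standardization")
  arm <- dataset[[paste0(factor_name, "_arm")]]
  y <- zscores$followup$z[, trait]
  dat <- data.frame(y = y, arm = arm)
  fml <- y ~ arm
  if (adjusted) {
    if (!trait %in% colnames(zscores$baseline$z))
      stop("no usable baseline values for trait '", trait, "'")
    dat$base <- zscores$baseline$z[, trait]
    fml <- y ~ arm + base
  }
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (any(table(dat$arm) < 2))
    stop("factor '", factor_name, "' needs >= 2 participants per arm")
  fit <- stats::lm(fml, data = dat)
  contrast_rows(fit, c("armsupplement", "armdiet"),
                c("supplement", "diet"), trait, factor_name, adjusted,
                hc_type, df_ref)
}

#' Screen every trait of a trial against one factor's arms
#'
#' Standardizes the follow-up (and, if `adjusted`, baseline) matrix once
#' and applies [fit_itt()] to each analysable trait.
#'
#' @inheritParams fit_itt
#' @param traits Traits to analyse (default: all).
#' @return Stacked `data.frame` of [fit_itt()] rows.
#' @export
itt_screen <- function(dataset, factor_name = c("lycopene", "greentea"),
                       traits = dataset$trait_names, adjusted = FALSE,
                       hc_type = "HC1", df_ref = c("t", "normal")) {
  factor_name <- match.arg(factor_name)
  df_ref <- match.arg(df_ref)
  zs <- suppressWarnings(
    list(followup = zscore_traits(dataset$followup),
         baseline = zscore_traits(dataset$baseline)))
  traits <- intersect(traits, colnames(zs$followup$z))
  out <- lapply(traits, function(tr)
    fit_itt(dataset, factor_name, tr, adjusted = adjusted,
            hc_type = hc_type, df_ref = df_ref, zscores = zs))
  do.call(rbind, out)
}

#' Multiplicity threshold from the effective number of tests
#'
#' Principal component analysis on the correlation scale (traits
#' standardized) of the complete-case submatrix; `k` is the smallest
#' number of components whose cumulative variance fraction reaches
#' `var_target`, and the per-test significance threshold is `alpha / k`.
#' With highly correlated metabolic panels this gives a much less severe
#' correction than Bonferroni over all traits, while holding the
#' familywise error near `alpha`.
#'
#' @param mat Numeric matrix, participants x traits (any scale; PCA is
#'   performed on standardized traits, so the result is invariant to
#'   per-trait rescaling).
#' @param var_target Cumulative variance fraction to reach (default 0.95).
#' @param alpha Nominal familywise level (default 0.05).
#' @return List of class `pca_threshold`: `k_components`,
#'   `variance_explained` (achieved fraction at k), `alpha`, `threshold`
#'   (= alpha/k at full precision).
#' @examples
#' m <- matrix(rnorm(300), 30)          # 10 near-independent traits
#' colnames(m) <- paste0("t", 1:10)
#' pca_threshold(m)$k_components
#' @export
pca_threshold <- function(mat, var_target = 0.95, alpha = 0.05) {
  stopifnot(is.matrix(mat), var_target > 0, var_target <= 1)
  cc <- mat[stats::complete.cases(mat), , drop = FALSE]
  if (nrow(cc) < 2) stop("fewer than 2 complete rows for PCA")
  sds <- apply(cc, 2, stats::sd)
  cc <- cc[, sds > 0, drop = FALSE]
  if (ncol(cc) < 2) stop("fewer than 2 non-constant traits for PCA")
  pc <- stats::prcomp(cc, center = TRUE, scale. = TRUE)
  cumfrac <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- which(cumfrac >= var_target - 1e-12)[1]
  structure(list(k_components = as.integer(k),
                 variance_explained = cumfrac[k],
                 alpha = alpha,
                 threshold = alpha / k),
            class = "pca_threshold")
}

#' @export
print.pca_threshold <- function(x, ...) {
  cat(sprintf("effective number of tests: %d components (%.1f%% variance)\n",
              x$k_components, 100 * x$variance_explained))
  cat(sprintf("threshold: %g/%d = %s\n", x$alpha, x$k_components,
              signif(x$threshold, 2)))
  invisible(x)
}

#' Diet-vs-supplement concordance of effect profiles
#'
#' Unweighted least-squares line of supplement-arm effect estimates on
#' diet-arm estimates across traits. A slope of 1 with intercept 0 and
#' R-squared 1 would indicate identical metabolic signatures of the two
#' modes of intervention.
#'
#' @param diet_betas,supplement_betas Equal-length numeric vectors of
#'   per-trait effect estimates (SD units vs placebo), length >= 3.
#' @return List of class `concordance_fit`: `slope`, `slope_se`,
#'   `intercept`, `r_squared`, `n_traits`.
#' @export
concordance <- function(diet_betas, supplement_betas) {
  stopifnot(length(diet_betas) == length(supplement_betas),
            length(diet_betas) >= 3)
  if (stats::sd(diet_betas) == 0)
    stop("zero variance in diet-arm estimates; slope undefined")
  fit <- stats::lm(supplement_betas ~ diet_betas)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 slope_se = unname(sm$coefficients[2, 2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 n_traits = length(diet_betas)),
            class = "concordance_fit")
}

#' @export
print.concordance_fit <- function(x, ...) {
  cat(sprintf("slope = %.2f +/- %.2f; intercept = %.2f; R^2 = %.2f (%d traits)\n",
              x$slope, x$slope_se, x$intercept, x$r_squared, x$n_traits))
  invisible(x)
}

#' Re-express standardized effect estimates in concentration units
#'
#' Multiplies beta, SE and CI bounds by the trait's original-unit SD
#' (p-values unchanged), turning "SD difference vs placebo" into e.g.
#' "mmol/L difference vs placebo".
#'
#' @param estimates `data.frame` as returned by [fit_itt()]/[itt_screen()].
#' @param trait_sds Named numeric vector of per-trait SDs in original
#'   units (e.g. `zscore_traits(...)$trait_sds`).
#' @param unit Optional unit label recorded in a `unit` column.
#' @return The estimates with beta/se/ci columns rescaled and a
#'   `beta_sd` column preserving the standardized effect.
#' @export
to_concentration_units <- function(estimates, trait_sds, unit = NA_character_) {
  stopifnot(is.data.frame(estimates), all(estimates$trait %in% names(trait_sds)))
  s <- unname(trait_sds[estimates$trait])
  if (any(is.na(s) | s <= 0)) stop("missing or non-positive trait SD")
  out <- estimates
  out$beta_sd <- estimates$beta
  for (col in c("beta", "se", "ci_low", "ci_high")) out[[col]] <- out[[col]] * s
  out$unit <- unit
  out
}
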