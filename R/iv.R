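# Instrumental-variable estimation within the trial: randomisation arms
# instrument the serum biomarker dose, and two-stage least squares
# estimates the dose effect on each follow-up metabolite. Written
# directly on the normal equations so the projection algebra is explicit.

exposure_column <- function(factor_name) {
  switch(factor_name, lycopene = "lycopene_umol_l", greentea = "egcg_nm")
}

# design pieces shared by tsls() and first_stage_diagnostics()
iv_design <- function(dataset, factor_name, trait, adjusted, standardize) {
  stopifnot(inherits(dataset, "trial_dataset"),
            trait %in% dataset$trait_names)
  arm <- dataset[[paste0(factor_name, "_arm")]]
  expo <- dataset[[exposure_column(factor_name)]]
  if (standardize) {
    zs <- suppressWarnings(zscore_traits(dataset$followup))
    if (!trait %in% colnames(zs$z))
      stop("trait '", trait, "' was excluded during standardization")
    y <- zs$z[, trait]
    base <- if (adjusted)
      suppressWarnings(zscore_traits(dataset$baseline))$z[, trait]
  } else {
    y <- dataset$followup[, trait]
    base <- if (adjusted) dataset$baseline[, trait]
  }
  dat <- data.frame(y = y, expo = expo, arm = arm)
  if (adjusted) dat$base <- base
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  dat$arm <- droplevels(dat$arm)
  if (nlevels(dat$arm) < 2) stop("need at least two arm levels as instruments")
  inst <- stats::model.matrix(~arm, dat)[, -1, drop = FALSE]  # arm indicators
  covar <- if (adjusted) cbind(base = dat$base) else NULL
  list(y = dat$y, expo = dat$expo, inst = inst, covar = covar, arm = dat$arm)
}

first_stage <- function(d) {
  n <- length(d$expo)
  z_full <- cbind(`(Intercept)` = rep(1, n), d$inst, d$covar)
  z_red <- cbind(`(Intercept)` = rep(1, n), d$covar)
  rss <- function(Z) {
    sum(stats::lsfit(Z, d$expo, intercept = FALSE)$residuals^2)
  }
  rss1 <- rss(z_full)
  rss0 <- rss(z_red)
  k_inst <- ncol(d$inst)
  df2 <- n - ncol(z_full)
  f <- ((rss0 - rss1) / k_inst) / (rss1 / df2)
  tss <- sum((d$expo - mean(d$expo))^2)
  r2 <- (rss0 - rss1) / tss
  list(f = f, r2 = r2, k_inst = k_inst, df2 = df2,
       arm_means = tapply(d$expo, d$arm, mean))
}

#' Two-stage least squares: biomarker dose effect on a metabolite
#'
#' Uses the randomisation arm indicators (supplement, diet vs placebo) as
#' instruments for the follow-up serum biomarker (lycopene umol/L or EGCG
#' nM) and estimates the dose effect on the standardized follow-up trait.
#' Stage 1 regresses the exposure on the instruments (plus the baseline
#' trait z-score when `adjusted`); stage 2 regresses the trait on the
#' fitted exposure (plus the same covariate). The coefficient is in
#' 1-SD-of-metabolite per one exposure unit. Standard errors use the
#' classical 2SLS variance with residuals taken against the observed (not
#' fitted) exposure; `hc_type = "HC1"` switches to a sandwich form.
#'
#' Randomisation guarantees the instruments are independent of
#' confounders of the dose-metabolite relation, so under the exclusion
#' restriction (arms act on the metabolite only through the biomarker)
#' the estimate is causal even when naive OLS is confounded.
#'
#' @inheritParams fit_itt
#' @param adjusted Include the baseline trait as covariate in both stages
#'   (default TRUE, matching baseline-adjusted trial practice).
#' @param covariate_stage Where the baseline covariate enters:
#'   `"both"` (default), `"first"`, or `"second"`.
#' @param standardize Analyse the z-scored trait (default TRUE); FALSE
#'   uses raw concentration units.
#' @param hc_type `"classical"` (default) or an HC flavour (`"HC0"`,
#'   `"HC1"`, ...) for the second-stage covariance.
#' @param weak_f_warn Warn (and flag) when the first-stage F falls below
#'   this threshold (default 10).
#' @return One-row `data.frame`: trait, exposure, beta, se, ci_low,
#'   ci_high, p, first_stage_f, first_stage_r2, n_used, weak_flag, and a
#'   `sargan_p` column (over-identification diagnostic, NA when
#'   just-identified).
#' @export
tsls <- function(dataset, factor_name = c("lycopene", "greentea"), trait,
                 adjusted = TRUE, covariate_stage = c("both", "first", "second"),
                 standardize = TRUE, hc_type = "classical",
                 weak_f_warn = 10) {
  factor_name <- match.arg(factor_name)
  covariate_stage <- match.arg(covariate_stage)
  d <- iv_design(dataset, factor_name, trait, adjusted, standardize)
  n <- length(d$y)
  cov1 <- if (adjusted && covariate_stage %in% c("both", "first")) d$covar
  cov2 <- if (adjusted && covariate_stage %in% c("both", "second")) d$covar
  z <- cbind(`(Intercept)` = 1, d$inst, cov1)
  x <- cbind(`(Intercept)` = 1, expo = d$expo, cov2)
  if (qr(z)$rank < ncol(z)) stop("rank-deficient first-stage design")
  # P_Z X via least squares; beta = (X'PzX)^{-1} X'Pz y
  xhat <- z %*% solve(crossprod(z), crossprod(z, x))
  xpx <- crossprod(xhat, x)
  beta <- solve(xpx, crossprod(xhat, d$y))
  resid <- d$y - x %*% beta            # observed-exposure residuals
  k <- ncol(x)
  if (hc_type == "classical") {
    sigma2 <- sum(resid^2) / (n - k)
    vc <- sigma2 * solve(crossprod(xhat))
  } else {
    omega <- resid^2
    if (hc_type == "HC1") omega <- omega * n / (n - k)
    else if (hc_type != "HC0") stop("hc_type must be classical, HC0 or HC1")
    bread <- solve(xpx)
    meat <- crossprod(xhat * sqrt(omega))
    vc <- bread %*% meat %*% t(bread)
  }
  fs <- first_stage(list(y = d$y, expo = d$expo, inst = d$inst,
                         covar = cov1, arm = d$arm))
  # Sargan over-identification statistic (logged, never used to filter)
  sargan_p <- NA_real_
  if (fs$k_inst > 1) {
    u <- as.vector(resid)
    fitu <- stats::lsfit(z, u, intercept = FALSE)
    r2u <- 1 - sum(fitu$residuals^2) / sum((u - mean(u))^2)
    sargan_p <- stats::pchisq(n * r2u, df = fs$k_inst - 1, lower.tail = FALSE)
  }
  b <- beta["expo", 1]
  se <- sqrt(vc[which(colnames(x) == "expo"), which(colnames(x) == "expo")])
  weak <- fs$f < weak_f_warn
  if (weak)
    warning(sprintf("weak instruments: first-stage F = %.2f < %g", fs$f,
                    weak_f_warn))
  data.frame(trait = trait, exposure = exposure_column(factor_name),
             beta = b, se = se,
             ci_low = b - 1.96 * se, ci_high = b + 1.96 * se,
             p = 2 * stats::pnorm(-abs(b / se)),
             first_stage_f = fs$f, first_stage_r2 = fs$r2,
             n_used = n, weak_flag = weak, sargan_p = sargan_p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' First-stage instrument diagnostics
#'
#' Joint F-statistic of the arm indicators for the biomarker dose, their
#' incremental R-squared, and arm-wise mean doses — the checks that the
#' randomised instrument is sufficiently associated with the exposure.
#'
#' @inheritParams tsls
#' @param trait Trait whose complete-case pattern defines the analysis
#'   sample (default: first trait).
#' @return List: `f`, `r2`, `arm_dose_means`, `n_used`.
#' @export
first_stage_diagnostics <- function(dataset,
                                    factor_name = c("lycopene", "greentea"),
                                    trait = dataset$trait_names[1],
                                    adjusted = FALSE) {
  factor_name <- match.arg(factor_name)
  d <- iv_design(dataset, factor_name, trait, adjusted, standardize = TRUE)
  fs <- first_stage(d)
  list(f = fs$f, r2 = fs$r2,
       arm_dose_means = fs$arm_means, n_used = length(d$y))
}

#' IV screen over all traits
#'
#' Applies [tsls()] to each trait of the panel for one factor.
#'
#' @inheritParams tsls
#' @param traits Traits to analyse (default: all).
#' @return Stacked [tsls()] rows.
#' @export
iv_screen <- function(dataset, factor_name = c("lycopene", "greentea"),
                      traits = dataset$trait_names, adjusted = TRUE,
                      hc_type = "classical") {
  factor_name <- match.arg(factor_name)
  rows <- lapply(traits, function(tr)
    tryCatch(suppressWarnings(
      tsls(dataset, factor_name, tr, adjusted = adjusted, hc_type = hc_type)),
      error = function(e) NULL))
  do.call(rbind, rows)
}
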