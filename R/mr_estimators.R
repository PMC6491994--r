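# Two-sample MR estimators: Wald ratio, inverse-variance-weighted,
# MR-Egger and weighted median, with odds-ratio reporting. All operate on
# a harmonized set (or any data.frame with bx, se_x, by, se_y).

mr_result <- function(method, beta, se, n_snps,
                      egger_intercept = NA_real_,
                      egger_intercept_se = NA_real_) {
  data.frame(method = method, n_snps = as.integer(n_snps),
             beta = beta, se = se,
             p = 2 * stats::pnorm(-abs(beta / se)),
             or_ = exp(beta),
             ci_low_or = exp(beta - 1.96 * se),
             ci_high_or = exp(beta + 1.96 * se),
             egger_intercept = egger_intercept,
             egger_intercept_se = egger_intercept_se,
             egger_intercept_p =
               2 * stats::pnorm(-abs(egger_intercept / egger_intercept_se)),
             row.names = NULL, stringsAsFactors = FALSE)
}

check_harmonized <- function(h, min_snps, method) {
  stopifnot(all(c("bx", "se_x", "by", "se_y") %in% names(h)))
  if (nrow(h) < min_snps)
    stop(method, " needs at least ", min_snps, " variants, got ", nrow(h))
  if (any(h$se_y <= 0) || any(h$se_x < 0)) stop("non-positive standard error")
  invisible(h)
}

#' Wald ratio: single-instrument causal estimate
#'
#' `beta = by / bx`, with the first-order delta-method standard error
#' `se = se_y / |bx|` (the exposure association's uncertainty is ignored,
#' appropriate for strong instruments; `second_order = TRUE` adds the
#' exposure-side term).
#'
#' @param bx,se_x Variant-exposure association and SE (SD units/allele).
#' @param by,se_y Variant-outcome association and SE (log-odds/allele).
#' @param second_order Include the se_x term of the delta expansion.
#' @return List with `beta` and `se` (log-odds per SD of exposure).
#' @export
wald_ratio <- function(bx, se_x, by, se_y, second_order = FALSE) {
  if (bx == 0) stop("bx = 0: Wald ratio undefined")
  beta <- by / bx
  se <- if (second_order)
    sqrt(se_y^2 / bx^2 + by^2 * se_x^2 / bx^4)
  else se_y / abs(bx)
  list(beta = beta, se = se)
}

#' Inverse-variance-weighted estimate
#'
#' Fixed-effect meta-analysis of the per-variant Wald ratios with weights
#' `w_j = bx_j^2 / se_y_j^2`; equivalently the weighted regression of
#' `by` on `bx` through the origin with weights `1/se_y^2`. The
#' `"random"` model inflates the SE by the multiplicative residual
#' dispersion (floored at 1), appropriate for larger instrument sets with
#' balanced heterogeneity.
#'
#' @param h A [harmonize()]d set (or data.frame with bx, se_x, by, se_y).
#' @param model `"fixed"` (default) or `"random"`.
#' @return One-row MR-result `data.frame` (method, n_snps, beta, se, p,
#'   or_, ci_low_or, ci_high_or; beta is log-odds per SD exposure).
#' @export
mr_ivw <- function(h, model = c("fixed", "random")) {
  model <- match.arg(model)
  check_harmonized(h, 1, "IVW")
  if (any(h$bx == 0)) stop("bx = 0 after harmonisation; remove the variant")
  w <- h$bx^2 / h$se_y^2
  ratio <- h$by / h$bx
  beta <- sum(w * ratio) / sum(w)
  se <- sqrt(1 / sum(w))
  if (model == "random" && nrow(h) > 1) {
    sigma2 <- sum(w * (ratio - beta)^2) / (nrow(h) - 1)
    se <- se * sqrt(max(1, sigma2))
  }
  mr_result("ivw", beta, se, nrow(h))
}

#' MR-Egger regression
#'
#' Weighted least squares of `by` on `bx` with a free intercept and
#' weights `1/se_y^2`, after orienting every variant to a non-negative
#' exposure association (InSIDE convention). The slope estimates the
#' causal effect; the intercept indexes directional horizontal
#' pleiotropy. SEs use the WLS covariance with the multiplicative
#' residual dispersion floored at 1.
#'
#' @inheritParams mr_ivw
#' @return One-row MR-result `data.frame` including `egger_intercept`,
#'   `egger_intercept_se` and `egger_intercept_p`.
#' @export
mr_egger <- function(h) {
  check_harmonized(h, 3, "MR-Egger")
  s <- ifelse(h$bx < 0, -1, 1)
  bx <- h$bx * s
  by <- h$by * s
  if (stats::sd(bx) == 0) stop("no spread in bx; Egger slope undefined")
  w <- 1 / h$se_y^2
  X <- cbind(1, bx)
  A <- crossprod(X, X * w)
  bhat <- solve(A, crossprod(X, by * w))
  resid <- by - X %*% bhat
  k <- nrow(h)
  sigma2 <- sum(w * resid^2) / (k - 2)
  V <- solve(A) * max(1, sigma2)
  mr_result("egger", beta = bhat[2, 1], se = sqrt(V[2, 2]), n_snps = k,
            egger_intercept = bhat[1, 1], egger_intercept_se = sqrt(V[1, 1]))
}

# 50th weighted percentile of sorted ratios via the weighted CDF:
# the smallest ratio whose cumulative weight reaches 1/2, averaging the
# two bracketing ratios when the CDF hits 1/2 exactly at a step boundary.
# Under this convention a variant carrying >50% of the weight returns its
# own ratio, and equal weights reduce to the plain sample median.
weighted_median_point <- function(ratio, w) {
  o <- order(ratio)
  r <- ratio[o]
  cw <- cumsum(w[o]) / sum(w)
  j <- which(cw >= 0.5 - 1e-9)[1]
  if (abs(cw[j] - 0.5) < 1e-9 && j < length(r)) (r[j] + r[j + 1]) / 2
  else r[j]
}

#' Weighted-median estimate
#'
#' The 50th weighted percentile of the per-variant Wald ratios, with
#' weights `bx^2/se_y^2` — consistent when variants contributing at least
#' half of the total weight are valid instruments, even if the rest are
#' pleiotropic. The standard error comes from a seeded parametric
#' bootstrap: `bx` and `by` are re-drawn from normal distributions around
#' their estimates and the weighted median recomputed.
#'
#' @inheritParams mr_ivw
#' @param n_boot Bootstrap draws for the SE (default 5000).
#' @param seed Integer seed for the bootstrap.
#' @return One-row MR-result `data.frame`. If all ratios coincide the SE
#'   can be 0; the estimate row then carries `p = NA`.
#' @export
mr_weighted_median <- function(h, n_boot = 5000, seed = 1L) {
  check_harmonized(h, 3, "weighted median")
  if (any(h$bx == 0)) stop("bx = 0 after harmonisation; remove the variant")
  w <- h$bx^2 / h$se_y^2
  est <- weighted_median_point(h$by / h$bx, w)
  k <- nrow(h)
  set.seed(as.integer(seed))
  boots <- vapply(seq_len(n_boot), function(b) {
    bx <- stats::rnorm(k, h$bx, h$se_x)
    by <- stats::rnorm(k, h$by, h$se_y)
    ok <- bx != 0
    weighted_median_point(by[ok] / bx[ok], bx[ok]^2 / h$se_y[ok]^2)
  }, numeric(1))
  se <- stats::sd(boots)
  out <- mr_result("weighted_median", est, se, k)
  if (se == 0) out$p <- NA_real_
  out
}

#' Annotate an MR result with odds ratios and a Bonferroni flag
#'
#' Ensures `or_ = exp(beta)` with `exp(beta +/- 1.96 se)` bounds and
#' flags whether the p-value passes the Bonferroni threshold
#' `0.05 / bonferroni_m` for the number of exposures tested.
#'
#' @param result MR-result `data.frame` row(s) from [mr_ivw()] and
#'   friends.
#' @param bonferroni_m Number of tests in the family (e.g. 4 exposures
#'   taken forward gives a threshold of 0.0125).
#' @param alpha Familywise level (default 0.05).
#' @return The result with `or_`, `ci_low_or`, `ci_high_or`,
#'   `bonferroni_threshold` and `passes_bonferroni` columns.
#' @export
report_or <- function(result, bonferroni_m, alpha = 0.05) {
  stopifnot(bonferroni_m >= 1)
  result$or_ <- exp(result$beta)
  result$ci_low_or <- exp(result$beta - 1.96 * result$se)
  result$ci_high_or <- exp(result$beta + 1.96 * result$se)
  result$bonferroni_threshold <- alpha / bonferroni_m
  result$passes_bonferroni <- !is.na(result$p) &
    result$p < alpha / bonferroni_m
  result
}

#' Run the full MR method set on one harmonized exposure/outcome pair
#'
#' Applies the Wald ratio (single variant) or IVW plus, when enough
#' variants are available, MR-Egger and the weighted median.
#'
#' @inheritParams mr_weighted_median
#' @param methods Subset of `c("ivw", "egger", "weighted_median")`.
#' @return Stacked MR-result rows.
#' @export
mr_all <- function(h, methods = c("ivw", "egger", "weighted_median"),
                   n_boot = 5000, seed = 1L) {
  rows <- list()
  if ("ivw" %in% methods) rows$ivw <- mr_ivw(h)
  if ("egger" %in% methods && nrow(h) >= 3) rows$egger <- mr_egger(h)
  if ("weighted_median" %in% methods && nrow(h) >= 3)
    rows$wm <- mr_weighted_median(h, n_boot = n_boot, seed = seed)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
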