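# Independent oracles and small fixture builders used across test files.

# Build a trial_dataset directly (bypassing the simulator) from raw
# pieces; matrices may be on any scale.
make_dataset <- function(lyc_arm, gt_arm = NULL, lyc_dose = NULL,
                         gt_dose = NULL, baseline, followup) {
  n <- length(lyc_arm)
  if (is.null(gt_arm)) gt_arm <- rep("placebo", n)
  if (is.null(lyc_dose)) lyc_dose <- rep(0, n)
  if (is.null(gt_dose)) gt_dose <- rep(0, n)
  if (is.null(colnames(followup)))
    colnames(followup) <- colnames(baseline) <-
      sprintf("trait%03d", seq_len(ncol(followup)))
  structure(list(id = sprintf("P%04d", seq_len(n)),
                 lycopene_arm = factor(lyc_arm,
                                       levels = c("placebo", "supplement", "diet")),
                 greentea_arm = factor(gt_arm,
                                       levels = c("placebo", "supplement", "diet")),
                 lycopene_umol_l = lyc_dose,
                 egcg_nm = gt_dose,
                 baseline = baseline,
                 followup = followup,
                 trait_names = colnames(followup)),
            class = "trial_dataset")
}

# Hand-computed HC sandwich covariance for an lm design (independent of
# the sandwich package).
hand_hc <- function(X, y, type = c("HC1", "HC0")) {
  type <- match.arg(type)
  n <- nrow(X); k <- ncol(X)
  XtXi <- solve(crossprod(X))
  b <- XtXi %*% crossprod(X, y)
  e2 <- as.vector(y - X %*% b)^2
  if (type == "HC1") e2 <- e2 * n / (n - k)
  XtXi %*% crossprod(X * e2, X) %*% XtXi
}

# Brute-force weighted median: scan the weighted CDF over candidate
# ratio values rather than using cumulative sums.
bf_weighted_median <- function(ratio, w) {
  w <- w / sum(w)
  cand <- sort(unique(ratio))
  below <- vapply(cand, function(x) sum(w[ratio <= x]), numeric(1))
  j <- which(below >= 0.5 - 1e-9)[1]
  if (abs(below[j] - 0.5) < 1e-9 && j < length(cand))
    (cand[j] + cand[j + 1]) / 2
  else cand[j]
}

# Harmonized-set stand-in for estimator tests.
make_h <- function(bx, by, se_y, se_x = rep(0.01, length(bx))) {
  data.frame(bx = bx, se_x = se_x, by = by, se_y = se_y)
}

# A summary-stats table with explicit alleles, for harmonisation tests.
make_stats <- function(rsid, ea, oa, eaf, beta, se, pval = 1e-10,
                       n = 20000) {
  data.frame(rsid = rsid, chr = 1, pos = seq_along(rsid),
             effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = se, pval = pval, n = n,
             stringsAsFactors = FALSE)
}
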