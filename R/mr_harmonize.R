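# Instrument selection, allele harmonisation and instrument-strength
# arithmetic for two-sample Mendelian randomisation from GWAS summary
# statistics.

#' Select genome-wide-significant instruments
#'
#' Filters an exposure summary-statistics table to variants associated at
#' `p < p_threshold` (default genome-wide significance, 5e-8), preserving
#' the original row order.
#'
#' @param exposure Summary-statistics `data.frame` (columns rsid, chr,
#'   pos, effect_allele, other_allele, eaf, beta, se, pval, n).
#' @param p_threshold Significance cut-off (default `5e-8`).
#' @return The filtered table. An empty result is allowed (a message is
#'   emitted).
#' @export
select_instruments <- function(exposure, p_threshold = 5e-8) {
  stopifnot("pval" %in% names(exposure))
  out <- exposure[exposure$pval < p_threshold, , drop = FALSE]
  if (nrow(out) == 0)
    message("no variants pass p < ", format(p_threshold))
  out
}

allele_complement <- function(a) chartr("ACGT", "TGCA", a)

is_palindromic_pair <- function(effect, other) {
  other == allele_complement(effect)
}

#' Harmonise exposure and outcome summary statistics to a common allele
#'
#' Aligns the outcome records to each exposure record's effect allele.
#' Variants absent from either table are dropped; swapped allele codings
#' flip the outcome beta's sign and its EAF; strand flips (complementary
#' coding) are resolved via complementation; strand-ambiguous palindromic
#' pairs (A/T, C/G) are aligned by effect-allele-frequency agreement when
#' both minor-allele frequencies fall below `palindrome_maf_limit`, and
#' dropped as ambiguous otherwise; irreconcilable allele pairs are
#' dropped with a reason.
#'
#' @param exposure,outcome Summary-statistics `data.frame`s sharing rsids.
#' @param palindrome_maf_limit Palindromic variants with either MAF at or
#'   above this limit (default 0.42) are too close to 0.5 for frequency
#'   alignment and are dropped.
#' @return A `harmonized_set`: `data.frame` with one row per retained
#'   variant (rsid, effect_allele, other_allele, eaf_x, bx, se_x, eaf_y,
#'   by, se_y, palindromic, action in kept/flipped), and an `audit`
#'   attribute listing every input variant with its action and, for
#'   dropped ones, the reason.
#' @export
harmonize <- function(exposure, outcome, palindrome_maf_limit = 0.42) {
  for (tab in list(exposure, outcome))
    stopifnot(all(c("rsid", "effect_allele", "other_allele", "eaf",
                    "beta", "se") %in% names(tab)))
  if (anyDuplicated(exposure$rsid)) stop("duplicate rsid in exposure table")
  if (anyDuplicated(outcome$rsid)) stop("duplicate rsid in outcome table")

  audit <- data.frame(rsid = exposure$rsid, action = "kept",
                      reason = "", stringsAsFactors = FALSE)
  oidx <- match(exposure$rsid, outcome$rsid)
  rows <- vector("list", nrow(exposure))
  for (i in seq_len(nrow(exposure))) {
    if (is.na(oidx[i])) {
      audit$action[i] <- "dropped"; audit$reason[i] <- "missing_in_outcome"
      next
    }
    ex <- exposure[i, ]; ou <- outcome[oidx[i], ]
    ea <- ex$effect_allele; oa <- ex$other_allele
    pal <- is_palindromic_pair(ea, oa)
    by <- ou$beta; eaf_y <- ou$eaf
    action <- NA_character_
    if (pal) {
      same_set <- (ou$effect_allele %in% c(ea, oa)) &&
        (ou$other_allele %in% c(ea, oa)) && ou$effect_allele != ou$other_allele
      if (!same_set) {
        audit$action[i] <- "dropped"; audit$reason[i] <- "allele_mismatch"
        next
      }
      maf_x <- min(ex$eaf, 1 - ex$eaf)
      maf_y <- min(ou$eaf, 1 - ou$eaf)
      if (maf_x >= palindrome_maf_limit || maf_y >= palindrome_maf_limit) {
        audit$action[i] <- "dropped"; audit$reason[i] <- "palindromic_ambiguous"
        next
      }
      # frequency alignment: the effect allele is the one whose frequency
      # sits on the same side of 0.5 in both studies
      if (ou$effect_allele != ea) { by <- -by; eaf_y <- 1 - eaf_y }
      if (sign(ex$eaf - 0.5) != sign(eaf_y - 0.5)) {
        by <- -by; eaf_y <- 1 - eaf_y
        action <- "flipped"
      } else action <- if (ou$effect_allele != ea) "flipped" else "kept"
    } else {
      oe <- ou$effect_allele; oo <- ou$other_allele
      if (oe == ea && oo == oa) {
        action <- "kept"
      } else if (oe == oa && oo == ea) {
        action <- "flipped"; by <- -by; eaf_y <- 1 - eaf_y
      } else if (allele_complement(oe) == ea && allele_complement(oo) == oa) {
        action <- "kept"      # opposite strand, same orientation
      } else if (allele_complement(oe) == oa && allele_complement(oo) == ea) {
        action <- "flipped"; by <- -by; eaf_y <- 1 - eaf_y
      } else {
        audit$action[i] <- "dropped"; audit$reason[i] <- "allele_mismatch"
        next
      }
    }
    audit$action[i] <- action
    rows[[i]] <- data.frame(rsid = ex$rsid, effect_allele = ea,
                            other_allele = oa, eaf_x = ex$eaf,
                            bx = ex$beta, se_x = ex$se,
                            eaf_y = eaf_y, by = by, se_y = ou$se,
                            palindromic = pal, action = action,
                            stringsAsFactors = FALSE)
  }
  miss_out <- setdiff(outcome$rsid, exposure$rsid)
  if (length(miss_out))
    audit <- rbind(audit, data.frame(rsid = miss_out, action = "dropped",
                                     reason = "missing_in_exposure"))
  h <- do.call(rbind, rows)
  if (is.null(h))
    h <- data.frame(rsid = character(), effect_allele = character(),
                    other_allele = character(), eaf_x = numeric(),
                    bx = numeric(), se_x = numeric(), eaf_y = numeric(),
                    by = numeric(), se_y = numeric(),
                    palindromic = logical(), action = character())
  rownames(h) <- NULL
  attr(h, "audit") <- audit
  class(h) <- c("harmonized_set", "data.frame")
  h
}

#' Variance in a standardized exposure explained by one variant
#'
#' For a unit-variance phenotype and per-allele effect `beta`,
#' `r2 = 2 * eaf * (1 - eaf) * beta^2` — the additive genetic variance of
#' a biallelic variant in Hardy-Weinberg proportions.
#'
#' @param eaf Effect-allele frequency in (0,1). Vectorised.
#' @param beta Per-allele effect in SD units of the phenotype.
#' @return Proportion of phenotypic variance explained.
#' @examples
#' snp_r2(0.41, 0.086)   # ~0.0036
#' @export
snp_r2 <- function(eaf, beta) {
  if (any(eaf <= 0 | eaf >= 1)) stop("eaf must lie strictly in (0,1)")
  2 * eaf * (1 - eaf) * beta^2
}

#' Combined instrument strength for one exposure
#'
#' Sums the (unrounded) per-variant r-squared values and converts them to
#' an F-statistic with `k` instruments and the conservative minimum
#' per-variant sample size `N`:
#' `F = (R2/k) / ((1 - R2)/(N - k - 1))`.
#'
#' @param r2_values Per-variant variance explained (from [snp_r2()]).
#' @param n_values Per-variant sample sizes.
#' @return List: `combined_r2`, `f_stat`, `k`, `n_used`.
#' @examples
#' instrument_f(snp_r2(0.12, -0.092), 24742)   # F ~ 44.3
#' @export
instrument_f <- function(r2_values, n_values) {
  stopifnot(length(r2_values) >= 1, all(n_values > 0),
            length(n_values) %in% c(1L, length(r2_values)))
  combined <- sum(r2_values)
  if (combined >= 1) stop("combined r2 >= 1")
  k <- length(r2_values)
  n <- min(n_values)
  f <- (combined / k) / ((1 - combined) / (n - k - 1))
  list(combined_r2 = combined, f_stat = f, k = k, n_used = n)
}
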