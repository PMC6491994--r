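---
title: "Methods: trial metabolome screening, dose IV estimation, and two-sample MR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial metabolome screening, dose IV estimation, and two-sample MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialmr)
```

## Overview

`trialmr` chains three causal-inference stages for dietary-intervention
metabolomics:

1. **Intention-to-treat (ITT) screening.** A 3×3 factorial trial
   (lycopene × green tea; arms placebo / supplement / dietary advice)
   measures an NMR metabolite panel at baseline and six months. Each
   trait's follow-up z-score is regressed on the arm indicators of one
   factor, with robust standard errors and a PCA-based multiplicity
   threshold.
2. **Dose IV estimation.** The randomised arms instrument the serum
   biomarker dose (lycopene in µmol/L, EGCG in nM); two-stage least
   squares (2SLS) estimates the dose effect on each trait, immune to
   confounding of the dose–trait relation.
3. **Two-sample Mendelian randomisation (MR).** Genetic variants
   associated with a trait at genome-wide significance in one GWAS are
   combined with their disease associations from another, via Wald
   ratios, inverse-variance weighting (IVW), MR-Egger and the weighted
   median, to estimate the trait's causal effect on disease risk
   (log-odds per SD of trait).

A synthetic-data generator emulates both data types with known ground
truth, so every estimator has a recovery test that needs no external
download.

## ITT model

Concentrations are converted to z-scores (sample SD, *n*−1 denominator,
computed separately at each time point so the baseline covariate of the
adjusted model is scale-free; original SDs are kept for back-transform
to concentration units). For trait $y$ and factor arms $S$ (supplement)
and $D$ (diet),

$$z(y_i) = \beta_0 + \beta_S S_i + \beta_D D_i + \varepsilon_i ,$$

with placebo the reference and the other factor ignored (marginal
analysis of the balanced factorial; no interaction terms). Standard
errors are heteroskedasticity-consistent, HC1 by default — the flavour
used by standard robust trial regressions — with HC0–HC3 available.
CIs and p-values use the t reference with residual degrees of freedom
by default; a normal (1.96) reference is available. The t default was
chosen because it is what robust-regression software reports and is
slightly better calibrated at $n \approx 128$; the two differ in the
third decimal of a p-value at this sample size. The adjusted
sensitivity analysis adds the baseline z-score as a covariate and uses
complete baseline + follow-up cases; the unadjusted screen uses all
participants with follow-up data.

### Effective number of tests

With ~159 correlated traits, Bonferroni over all traits is far too
severe. `pca_threshold()` performs PCA on the correlation scale of the
complete-case matrix and takes $k$ = the smallest number of components
reaching 95% cumulative variance; the per-test threshold is
$\alpha/k$. For a panel where 14 components suffice this gives
$0.05/14 = 0.0036$ (2 s.f.). The choice of matrix is configurable; the
default is the follow-up matrix, since that is the matrix being
screened. The threshold is invariant to per-trait rescaling.

The correction is well calibrated when the panel really is driven by a
modest number of tight trait blocks (see *Synthetic data* below): the
test suite simulates 500 null trials under the generator's
factor-model defaults (gaussian margins) and asserts that the
familywise error of the supplement-contrast screen at the $\alpha/k$
threshold stays within the Monte-Carlo band of the nominal 0.05, the
small residual excess coming from within-block idiosyncratic noise.
Two caveats are documented rather than asserted: (i) under trait
independence the threshold is anti-conservative by construction (the
familywise rate approaches $\alpha\,p/k$), and (ii) marginal
transformations that weaken Pearson correlations — notably the
log-skew margins the generator can impose, since
corr$(X, e^X) \approx 0.76$ even at latent correlation 1 — effectively
split correlation blocks, raise the effective number of tests above
$k$, and with it the familywise rate.

### Concordance and units

`concordance()` regresses per-trait supplement effects on dietary
advice effects (unweighted least squares); slope 1, intercept 0,
$R^2 = 1$ would mean the two modes of intervention leave the same
metabolic signature. `to_concentration_units()` multiplies a
standardized estimate (and its SE/CI) by the trait's original-unit SD.

## 2SLS dose model

Stage 1 regresses the follow-up biomarker on the two arm indicators
(plus the baseline trait z-score when adjusted — the covariate enters
both stages by default, configurable to either); stage 2 regresses the
trait on the fitted exposure. Coefficients are per one exposure unit
(µmol/L or nM). SEs use the classical 2SLS variance with residuals
taken against the *observed* exposure; an HC option exists. The
first-stage joint F and incremental R² of the instruments are reported,
with a warning flag below F = 10; a Sargan over-identification p-value
is logged but never used for filtering. With a single instrument the
estimator reduces to the Wald ratio of reduced-form to first-stage
coefficients, exactly.

A note on scales: the z-scored trait divides by the sample SD, which
includes any treatment-induced variance. The z-scale ITT coefficient is
therefore attenuated relative to a "true" shift planted on the latent
scale, by the factor $\sqrt{1 + \pi(1-\pi)\delta^2}$ for a shift
$\delta$ affecting a fraction $\pi$ of participants — about 4% for a
−0.62 SD shift in one of three equal arms. Recovery
tests in this package therefore back-transform estimates to
concentration units (β·SD), which is the plain group difference and is
unbiased for the planted value.

## Two-sample MR

**Harmonisation.** Outcome records are aligned to the exposure's effect
allele: swapped codings flip the outcome beta and EAF; opposite-strand
codings are resolved by complementation; palindromic pairs (A/T, C/G)
carry no strand information in their labels, so they are aligned purely
by allele-frequency agreement, and only when both minor-allele
frequencies are below 0.42 (configurable) — otherwise dropped as
ambiguous. Every input variant appears in an audit table with its
action and reason. Re-coding any exposure record to the opposite allele
leaves every downstream estimate unchanged to machine precision.

**Estimators.** For variant $j$ with exposure association $b_{xj}$
(SD/allele) and outcome association $b_{yj}$ (log-odds/allele):

- *Wald ratio*: $\hat\theta_j = b_{yj}/b_{xj}$, SE
  $= se_{yj}/|b_{xj}|$ (first-order delta method; a second-order option
  adds the exposure term).
- *IVW*: fixed-effect meta-analysis of the ratios with weights
  $w_j = b_{xj}^2/se_{yj}^2$ — identical to weighted regression of
  $b_y$ on $b_x$ through the origin. A multiplicative random-effects
  option (dispersion floored at 1) suits larger instrument sets.
- *MR-Egger*: the same weighted regression with a free intercept, after
  orienting all $b_{xj} \ge 0$; the intercept estimates directional
  pleiotropy, and the coefficient covariance uses the residual
  dispersion floored at 1 (so an exact fit does not produce zero SEs).
- *Weighted median*: the 50th weighted percentile of the sorted ratios.
  The percentile is read off the weighted CDF: the smallest ratio whose
  cumulative weight reaches ½, averaging the two bracketing ratios when
  the CDF hits ½ exactly at a step boundary. Under this convention
  equal weights reduce to the plain sample median and a variant
  carrying more than half the weight returns its own ratio exactly —
  the defining robustness property. (A smoothed mid-point interpolation
  variant exists in the literature; the two agree asymptotically, and
  the step convention was chosen for its exact majority property.) Its
  SE comes from a seeded parametric bootstrap (5,000 draws by default)
  re-drawing $b_x$ and $b_y$ from their estimated normals.

**Instrument strength.** For a unit-variance exposure,
$r^2_j = 2p_j(1-p_j)\beta_j^2$ (the additive variance of a biallelic
variant in Hardy–Weinberg proportions), and the combined
$F = \frac{R^2/k}{(1-R^2)/(N-k-1)}$ with $R^2 = \sum_j r^2_j$ and $N$
the *minimum* per-variant sample size — the conservative convention,
which also reproduces published multi-variant F values that the
mean-N convention does not. Published per-variant cells that were
computed from more decimal places than printed can disagree in the
last digit; with the bundled instrument table the formula reproduces
11 of 17 printed R² cells at 4 decimals exactly (the others differ by
one unit in the last digit) and the acetate, pyruvate and valine F
statistics to one decimal.

**Reporting.** Estimates are log-odds per 1 SD of exposure;
`report_or()` exponentiates to OR with $\exp(\beta \pm 1.96\,se)$
bounds and flags Bonferroni significance at $0.05/m$ for $m$ exposures
tested (e.g. $m=4$ gives 0.0125).

## Synthetic data

`simulate_trial()` draws a 3×3 factorial trial. Trait covariance is a
latent factor model with *block-sparse* loadings: each trait loads on
one primary factor plus weak dense cross-loadings. This mirrors how NMR
panels behave — lipid and lipoprotein measures come in families
(particle concentration, total lipid, cholesterol, esters,
triglycerides per subclass) that are near-duplicates of one another,
with the 14 lipoprotein subclasses dominating the correlation
structure. Defaults: 14 factors, primary loading 30, cross-loading
0.005 (within-block correlation ≈ 0.9985), under which a ~128-row
sample shows ~14 principal components for 95% of the panel variance.
Dense isotropic loadings were rejected: they spread 159 traits evenly
across the factor space, which neither matches the panel regime
(~25 PCs would be needed for 95%) nor any setting in which an
effective-number-of-tests correction is usable.

Follow-up latents are $\rho\,\text{base} + \sqrt{1-\rho^2}\,\text{new}$
($\rho = 0.5$ by default), keeping unit variance; planted arm effects
(SD units) are added there, or — with `mediation` — as
$\gamma \times \text{dose}$ so the trait responds only through the
biomarker. A shared participant-level confounder can be injected into
both the doses and the follow-up traits; randomised arms remain clean,
which is exactly the contrast the 2SLS recovery test exploits. A
configurable fraction of traits (default 20%) is exponentiated to give
right-skewed margins; traits receive random concentration locations
U(1,10) and scales U(0.5,2) unless fixed. Default dose models give
supplement/diet increments of 1.0/0.6 µmol/L lycopene (noise 0.25) and
150/100 nM EGCG (noise 40) over small baselines — strong instruments,
first-stage F ≫ 10, as in a trial with good adherence. One integer
seed drives everything through per-stream derived sub-seeds;
identical configurations are bit-reproducible.

`simulate_gwas_pair()` draws per-SNP EAFs uniformly in a range,
exposure effects $b_{xj} \sim N(0, s^2)$ reported without sampling
noise (the no-measurement-error simplification standard in two-sample
MR simulation), exposure SEs $1/\sqrt{2p_j(1-p_j)n}$, outcome SEs from
the case/control formula, and outcome effects
$\theta b_{xj} + \alpha_j + \varepsilon_j$ with optional directional or
balanced pleiotropy $\alpha_j$. Default sample sizes (24,000 exposure;
44,825/27,904 cases/controls) match the scale of published metabolite
and prostate-cancer GWAS. A configurable fraction of variants gets
palindromic allele pairs to exercise the harmonisation rules.

What the generator does *not* emulate: NMR spectral artefacts,
non-normal genotype effect distributions, linkage disequilibrium
between instruments (variants are independent, as a clumped instrument
set would be), selection effects in GWAS, or missingness that is
informative. Passing recovery tests therefore certify estimator
arithmetic and sampling behaviour under the stated models, not
robustness to those features.

## Numerical and design choices

- Degenerate traits (constant, or <2 values) are excluded from
  z-scoring with a warning and an exclusion record, never silently.
- An exact-separation contrast (zero residuals) legitimately yields a
  zero sandwich SE; downstream p-values become 0.
- PCA uses `prcomp` with scaling; components are counted with a
  $10^{-12}$ slack on the cumulative-variance comparison so exact-rank
  data do not lose a component to floating error.
- The weighted-median CDF comparisons use a $10^{-9}$ tolerance so
  equal weights like $1/6$ sum to ½ as intended.
- 2SLS refuses rank-deficient first stages; weak instruments warn but
  still return estimates, with the flag in the output.
- Bonferroni denominators, bootstrap draws, the palindrome MAF limit,
  HC flavour, PCA variance target and all thresholds are arguments, not
  constants.
- Problem sizes in the test suite: recovery suites use 500 replicates
  of the default-size trial (135 participants × 159 traits) or 200-SNP
  summary pairs; the familywise-error suite uses 500 null trials; the
  IVW type-I suite uses 1,000 pairs.

## Known limitations

- The ITT screen is marginal per factor; factorial interactions are out
  of scope.
- The weighted-median bootstrap SE is simulation-based; with very few
  variants (3–4) it can be optimistic.
- MR assumes independent instruments; no LD clumping, proxy lookup,
  Steiger filtering or outlier-robust extensions (e.g. mode-based or
  PRESSO-style) are provided.
- The PCA threshold is a heuristic: well calibrated for block-correlated
  panels, anti-conservative under independence, and sensitive to
  marginal transformations that weaken Pearson correlations.
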