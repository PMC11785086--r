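---
title: "Metabolite-PRS interaction analysis: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolite-PRS interaction analysis: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

A glaucoma polygenic risk score (PRS) stratifies disease risk well, yet
most people in the top risk decile never develop glaucoma. This package
implements a reusable, tested version of an analysis that asks two
questions of a biobank-style cohort with NMR metabolomics: do circulating
metabolites add predictive value on top of clinical covariates and the
PRS, and is there a metabolomic signature of *resilience* — metabolites
whose higher adjusted levels accompany the absence of disease specifically
in people at high genetic risk?

Because the motivating cohort (UK Biobank) is access-restricted, the
package pairs every analysis stage with a synthetic cohort generator that
reproduces the *statistical structure* the analysis assumes. All empirical
claims in this vignette are properties of that synthetic structure, which
the test suite computes; nothing here asserts results about the real
cohort.

## The cohort generator

`generate_cohort()` draws, per participant:

* **Latent metabolites** $z_{ij}$: standard normal in $B$ equal
  exchangeable blocks — within a block, $z = \sqrt{\rho}\,F_b +
  \sqrt{1-\rho}\,\varepsilon$ with a shared block factor $F_b$. Reported
  concentrations are $\exp(\sigma z)$ ($\sigma = 0.5$), giving the skewed,
  strictly positive marginals that make the probit transform non-trivial.
* **PRS**: standard normal, as a standardized score would be.
* **Covariates**: simple parametric families with means and spreads chosen
  to resemble a middle-aged European biobank (age $\sim N(57, 8^2)$
  truncated to 40–73, BMI $\sim N(27.4, 4.8^2)$, ~94% White ethnicity,
  ~46% male, and so on). Covariates are mutually independent except the
  planted age effect on status, which is all the residualization stage
  needs to be exercised.
* **Status**: Bernoulli from
  $\mathrm{logit}\,P = \alpha + \beta_{PRS} P_i + \sum_{j\in R}
  (\beta_m z_{ij} + \gamma P_i z_{ij}) + \textbf{c}'_i\theta$,
  with $\alpha$ solved by monotone root finding
  (`solve_intercept()`) so the *expected* prevalence equals the target
  exactly for the drawn linear predictors.
* **Missingness**: missing completely at random at a fixed cell rate over
  metabolites and covariates, never on status or PRS. Median/mode
  imputation assumes nothing stronger than MCAR, so nothing stronger is
  generated.

### Default study conditions

The defaults are fixed once, from the published cohort structure, and are
not tuning knobs:

| parameter | default | why |
|---|---|---|
| prevalence target | 0.04 | the cohort's ~4% glaucoma prevalence |
| $\beta_{PRS}$ | 1.02 | solved numerically so the logistic model reproduces ~14.4% prevalence in the top PRS decile and ~1.3% in the bottom half at 4% overall |
| panel | 168 metabolites, 27 certified | the NMR platform's absolute-measure panel with its certified diagnostic subset |
| blocks | 12 blocks of 14, $\rho = 0.9$ | population eigenvalues of $1 + 13\rho = 12.7$: 12 components carrying ~91% of total variance, matching the strongly collinear lipoprotein panel for which the effective-tests correction exists (the real matrix showed 9 components / 91.6%) |
| resilience set | lactate, pyruvate, citrate | the glycolysis/TCA trio of interest |
| $\beta_m$, $\gamma$ | 0, −0.15 | a *purely interactive* protective effect: protection grows with PRS and vanishes in the bottom half, the qualitative resilience asymmetry |
| age effect | 0.05 per year | cases ~4 years older, enough to make residualization consequential |
| missing rate | 0.02 | exercises imputation and pairwise-complete correlations without dominating anything |

What the generator deliberately does **not** emulate: genotype-level
structure (the PRS is a scalar), ancestry-correlated metabolite shifts,
informative missingness, measurement batch effects, and the platform's
true marginal distributions (log-normal is a stand-in). Passing tests
therefore certify the *methods* — calibration, error control, recovery of
planted structure — not claims about real biology.

## Preprocessing conventions

* **Probit scores.** The platform's measures are standardized by the
  rank-based inverse-normal transform $\Phi^{-1}((r_i - 0.5)/m)$ with
  average ranks for ties, the standard epidemiology convention. It is
  invariant to any monotone transformation of the input, which the suite
  tests directly.
* **Imputation.** Column median for numeric, most frequent level for
  factors, ties broken by schema level order for determinism. Imputation
  is idempotent.
* **Quartiles.** Empirical 25/50/75th percentiles with linear
  interpolation; intervals are left-open/right-closed on the cutpoints.
  The convention is arbitrary but deterministic; quartile labels are
  invariant to location shifts.
* **Tiered designs.** Tier 1 metabolites only; tier 2 adds demographics
  (age, sex, ethnicity, season, collection time, fasting hours); tier 3
  adds the clinical set (smoking, alcohol, caffeine, activity, BMI,
  systolic BP, diabetes, HbA1c, coronary disease, beta-blocker, oral
  steroid, spherical equivalent); tier 4 adds the PRS. The separate
  residualization covariate list additionally carries age² and the
  fasting category (≤4 / 5–8 / 9+ hours), mirroring the two distinct
  covariate lists of the source analysis.
* Self-reported ethnicity (not genetic ancestry) enters both the tiered
  designs and residualization; the generator draws only one such column,
  so the distinction is nominal here, but the schema keeps the slot
  explicit.

## Statistical kernels

* **AUC and the DeLong test.** AUC is the Mann–Whitney statistic with
  ties counted ½, computed via midranks in $O(n\log n)$; variances and
  the paired two-curve test use DeLong's structural components, so
  arbitrarily correlated curves on the same participants are compared
  validly. Degenerate conventions: all-tied scores give AUC 0.5 with zero
  variance; identical curves give p = 1.
* **Effective number of tests (NEF).** The correlation matrix of the
  tested quantities is computed over pairwise-complete observations,
  eigendecomposed, negative eigenvalues (possible for pairwise-complete
  matrices) clipped at zero, and the Bonferroni multiplier is the count of
  eigenvalues exceeding 1% of the total variance $p$. The multiplier is
  floored at 1: with many near-independent columns every eigenvalue can
  fall below $0.01p$, and a multiplier of zero would be meaningless.
  The correction is computed on the *residual matrix of the stratum being
  tested*, so it reflects the dependence structure of the statistics it
  corrects; recomputing it per stratum is the conservative generalization
  of a single cohort-wide spectrum.
  NEF is mildly anti-conservative by construction; the acceptance suite
  bounds the familywise error of the discovery procedure at ≤ 8% under a
  50-metabolite exchangeable null.
* **Odds ratios.** $(ad)/(bc)$ with Wald CIs on the log scale; any zero
  cell triggers the Haldane–Anscombe +0.5 correction on all four cells,
  flagged in the output. Two ORs are compared by the 1-df Wald chi-square
  on the difference of log-ORs — the only standard two-OR chi-square
  consistent with a quartile-grid description.
* **Welch t.** Unequal-variance t with Satterthwaite df, chosen over the
  pooled test because case and non-case groups differ greatly in size and
  possibly in spread; two-sided throughout. (A vectorized column-wise
  version drives the 168-metabolite loops and is tested against
  `t.test()` column by column.)

## Prediction models

"Five-fold cross-validation and an 80/20 split" is read the only way both
statements can hold simultaneously: a seeded, status-stratified 80/20
split; 5-fold cross-validated deviance *inside the 80%* selects the L1
penalty from a log-spaced grid of ≥ 50 values (minimum-deviance rule, not
1-SE); the model is refit on the full training split; and every reported
AUC, CI and DeLong comparison uses the single shared 20% hold-out. A
shared hold-out is also what makes paired DeLong comparisons between
tiers valid. L1 (lasso) is chosen because the source describes
regularization that *reduced the metabolite set* — a sparsity property.
No class weighting is applied (plain penalized likelihood at ~4%
prevalence), and covariates enter unstandardized (`standardize = FALSE`;
metabolites are already probit-scored — flip the flag if penalizing
heterogeneous covariate scales is a concern).

## Resilience discovery

The source text says metabolite residuals were obtained from "a logistic
regression model"; residuals of a continuous metabolite cannot come from
a logistic outcome model, and the accompanying covariate list is a list
of metabolite determinants. The package therefore residualizes each
probit metabolite by **ordinary least squares** on that covariate list —
the one reading consistent with the quoted covariates and with a t-test
on residuals. Within the top PRS decile (PRS ≥ 90th percentile) and the
bottom half (≤ median), cases and non-cases are compared per metabolite
by Welch's t, NEF-corrected as above; calls use the stated thresholds
(significant < 0.05, suggestive < 0.2). The direction convention is that
a resilience metabolite has the *higher* mean residual among unaffected
participants.

## Scores and interactions

* The **MRS** is a weighted sum of probit scores whose weights come from
  unpenalized logistic fits in 5 stratified folds. The source extracts
  "the beta values" without saying how folds combine; the exported model
  uses the element-wise mean of fold coefficients, and a second,
  `out_of_fold` scoring mode scores each participant with the betas of
  the fold that held them out. In-sample (`full_fit`) scoring biases the
  apparent MRS main effect upward on null data — the suite demonstrates
  this — so out-of-fold is the right choice whenever the score feeds
  further inference on the same cohort.
* The **resilience sum** adds the trio's probit scores first and
  quartiles the continuous sum, matching a quartile table of a continuous
  sum rather than summing per-metabolite quartile indices.
* **Interaction inference** comes from the continuous product term
  (`status ~ PRS*score + covariates`, Wald test); the 16-cell OR grid is
  descriptive, with either the within-PRS-quartile Q1 reference or the
  global (Q1, Q1) reference. Reference cells have OR ≡ 1 by construction
  and cell totals sum to the cohort.
* The **three-way** age × score × PRS term is tested in the top decile
  with age dichotomized at the stratum median (the analysed cohort's
  median was 58 years), all two-way products included.

## Numerical choices and degenerate inputs

Logistic fits use IRLS to tolerance 1e-8 (ridge fallback with penalty
1e-6, flagged, on separation); the intercept solver brackets ±40 on the
log-odds scale and is accurate to 1e-8; rank-deficient residualization
designs drop collinear columns with a warning; constant columns,
single-class strata, all-tied PRS, zero-variance scores and fully missing
columns raise errors rather than propagating nonsense. Quartile ties
follow the right-closed convention; PRS decile ties are kept on the high
side (top) and low side (bottom half).

## Problem sizes used by the test and acceptance suites

Chosen as the smallest sizes at which the asymptotic claims are clean:
kernel oracles at n ≤ a few hundred; type-I suites at 2,000 replicates
(DeLong, n = 500), 500 replicates (interaction, n = 20,000) and 200
replicates (familywise discovery error, 50 metabolites, n = 4,000);
planted-signal recovery at 25 replicates of n = 100,000 under the default
conditions; nested-model ordering at 25 replicates of n = 20,000 with a
12-metabolite panel. Unit tests use further reduced sizes.

## Known limitations

Synthetic covariates are mutually independent, so residualization is
exercised but confounding structure among covariates is not; the MCAR
missingness cannot probe imputation bias under informative missingness;
the log-normal marginals understate the heavy tails of some lipoprotein
measures; and the exchangeable-block correlation gives a cleaner eigen
spectrum than a real panel. None of these affect the kernels, which are
distribution-agnostic, but power numbers measured here should not be read
as power for the real cohort.
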