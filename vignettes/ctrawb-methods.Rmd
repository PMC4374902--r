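---
title: "Relating well-being to CTRA gene expression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relating well-being to CTRA gene expression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctrawb)
```

## The scientific question

The conserved transcriptional response to adversity (CTRA) is a leukocyte
gene-expression signature: up-regulated pro-inflammatory transcripts (IL1B,
IL8, PTGS2, TNF and relatives) together with down-regulated Type I
interferon (IFI-, IFIT-, MX-, OAS-family) and antibody-synthesis (IGJ)
transcripts. The analyses this package implements ask whether individual
differences in psychological well-being — particularly *eudaimonic*
well-being (meaning, purpose, pro-social functioning) as distinct from
*hedonic* well-being (positive affect, satisfaction) — predict average CTRA
expression in peripheral blood mononuclear cells, after adjusting for
demographic and behavioral confounders and for leukocyte-subset composition.

Three statistical components carry the analysis, and each is implemented and
tested here: (1) psychometric scoring of the MHC-SF and Ryff well-being
inventories under several dimensional representations, with reliability and
factor-structure checks; (2) preparation of the expression response
(quantile normalization, log2, gene-wise standardization, sign adjustment);
and (3) a pooled repeated-measures linear model relating the panel of CTRA
indicator genes to subject-level predictors under a structured
within-subject covariance.

## Psychometric scoring

The MHC-SF has 14 items rated 0 ("never") to 5 ("every day"): 3 hedonic,
5 social and 6 psychological. `score_mhcsf()` produces all representations
at once: the 3-d scale means; the 2-d representation whose eudaimonic score
is the mean of the 11 psychological + social items (exactly
`(6*psych + 5*social)/11`); the 1-d mean of all 14 items; and the
categorical *flourishing* classification, which requires at least 1 of 3
hedonic and at least 6 of 11 eudaimonic items experienced "every day" or
"5–6 times a week" (responses of 4 or 5). The Ryff inventory (9-item form)
is scored by `score_ryff()` as six 9-item scale sums (range 9–54, reverse
keying applied from the item map) plus their mean as the total score.
Subjects missing any item of a scale are scored `NA` for that scale and drop
out of downstream complete-case analyses; no imputation is performed, and
the attrition is logged at every stage.

An alternative 3-d item allocation that moves two social items to the
psychological scale is available through
`mhcsf_item_map(variant = "brown")`; which two items move is configurable
because the published sources do not fix them unambiguously.

Reliability uses Cronbach's
$\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_j s_j^2}{s_{\text{total}}^2}\right)$,
and bivariate associations use Pearson/point-biserial correlations or the
ANOVA effect size $r = \sqrt{SS_{\text{between}}/SS_{\text{total}}}$
(`correlate()`). *Eudaimonic predominance* (`sign_test_predominance()`) is
the proportion of subjects with eudaimonic ≥ hedonic score; ties count
toward the proportion (per the "≥" definition) but are excluded from the
exact binomial sign test, the standard convention for sign tests.

## Confirmatory factor analysis

`fit_cfa_ml()` fits congeneric factor models (each item loads on one
factor, factor variances fixed at 1, inter-factor correlations free) by
minimizing the maximum-likelihood discrepancy

$$F_{ML} = \log|\Sigma(\theta)| + \mathrm{tr}\,(S\,\Sigma(\theta)^{-1})
           - \log|S| - p,$$

with quasi-Newton iteration, analytic gradients, and five jittered starts;
the reported statistic is $T = (n-1)\,F_{ML}$ on
$df = p(p+1)/2 - \#\text{free parameters}$ (for 14 items: 77, 76 and 74 df
for the 1-, 2- and 3-factor structures). The $(n-1)$ multiplier is the
standard ML-discrepancy convention; items are treated as continuous and
analyzed on Pearson covariances (ordinal/polychoric CFA is out of scope,
and exact reproduction of published chi-squares can differ slightly under
other estimator conventions).

Two numerical choices deserve note. Uniquenesses are log-parameterized
(positive by construction; solutions within 1e-4 of zero are flagged as
Heywood cases). Factor correlations enter *unconstrained* rather than
through a bounded transform: the nested comparisons fix a correlation at 1
(1-factor = 2-factor with $\phi = 1$; 2-factor = 3-factor with
$\phi_{ps} = 1$), and a $|\phi| < 1$ parameterization would put that
restriction on the boundary of the parameter space, turning the
chi-square-difference statistic into a boundary mixture. The implied
covariance $\Lambda\Phi\Lambda' + \Psi$ remains positive definite slightly
past $|\phi| = 1$ (a Cholesky guard rejects anything further), so the
restriction is interior and `nested_chisq_test()` retains its standard
$\chi^2(\Delta df)$ reference distribution — which the test suite verifies
by simulating under the restricted truth and applying a Kolmogorov–Smirnov
check. Convergence is declared at gradient norm below 1e-6; multistart
protects against local minima.

## Expression preparation

The pipeline order is fixed: quantile-normalize → log2 → standardize within
gene → sign-adjust → long format. Quantile normalization (delegated to
limma) is appropriate for full microarray matrices; for matrices that
contain *only* the indicator panel — such as generator output — rank-mean
normalization across a few dozen rows would erase genuine between-subject
differences, so `prepare_ctra_response(quantile = FALSE)` skips it and the
orchestrator does so automatically for synthetic runs. Log2 uses a
configurable floor (default: clip at 1) to guard non-positive intensities.
Standardization centers each gene and, in the confirmation-study
convention, scales to unit SD; the generalization-study convention
(`scale_sd = FALSE`) retains native log2 dispersion. Sign adjustment
multiplies the 34 interferon/antibody rows by −1 exactly once (re-applying
requires `force = TRUE`), and commutes with SD-standardization — an
invariant the tests assert. Marker transcripts are extracted as subject
covariates *before* the panel is subset, so response rows and marker
covariates never overlap.

## The pooled association model

For subject $i$ with sign-adjusted, standardized response vector $y_i$ over
the $G$ panel genes,

$$y_i = \mu + (x_i'\beta)\,\mathbf{1}_G + \varepsilon_i,\qquad
  \varepsilon_i \sim N(0, \Sigma),$$

with gene-specific intercepts $\mu$, common subject-level slopes $\beta$
(the "average association" over the panel), and a structured $\Sigma$:
heterogeneous compound symmetry (HCS; gene-specific SDs $\sigma_g$, one
common correlation $\rho \in (-1/(G-1), 1)$), compound symmetry, or
unstructured. Fixed effects are profiled out by GLS and the profile
objective is maximized over $(\log\sigma_g, \mathrm{logit}\,\rho)$ by BFGS
with analytic gradients (the envelope theorem makes the profile gradient
equal to the partial derivative at the profiled optimum); the
Sherman–Morrison structure of the compound-symmetry inverse keeps each
evaluation at $O(G^2 n)$. The unstructured fit alternates GLS with the
closed-form covariance update, adding a small ridge when $G$ approaches
$n$. With compound symmetry, homogeneous variances and balanced data the
slope estimate collapses to OLS on the per-subject composite mean — an
exact identity the tests check at 1e-10 — and small instances of both
structured and unstructured fits are verified against a brute-force dense
likelihood optimized generically over all parameters.

**Inference.** Wald $t = b/SE$ and Wald $F$ use the between-within
denominator df convention, $df = n - p - 1$ where $p$ counts subject-level
predictor columns. This convention reproduces the df bookkeeping of
balanced repeated-measures designs exactly (e.g. $n = 122$ with 2 well-being
terms, 7 demographic/behavioral covariates and 8 leukocyte markers gives
$t(104)$; adding a study indicator at $n = 198$ gives $t(179)$; the 6-scale
mutually adjusted model at $n = 107$ gives $t(83)$). Coefficient contrasts
(`contrast_test()`) use the estimated coefficient covariance, which is how
"the eudaimonic association exceeds the hedonic one" is tested.
Multicollinearity is diagnosed by $VIF = (1 - R^2)^{-1}$ from regressing
each predictor on the others, with the conventional threshold of 10.
Unstandardized (log2-scale) coefficients are made interpretable by
`percent_difference_effect(b)` $= 100\,(2^{4b} - 1)$, the percent difference
in average transcript abundance across a −2 SD → +2 SD span of the
predictor.

**Why REML and an adjusted covariance are the defaults.** With $G = 52$
genes, $n = 122$ subjects and 17 subject-level predictors, two small-sample
effects make naive ML Wald tests anti-conservative. First, ML covariance
estimates ignore the $G + p$ estimated fixed effects and shrink by roughly
$(n - p - 1)/n$ in the between-subject direction; REML (the default,
`method = "reml"`) corrects this, and the implementation reproduces
`nlme::gls(method = "REML")` to numerical precision. Second, the
model-based slope covariance $(X'V^{-1}X)^{-1}$ treats the estimated
$\Sigma$ as known; the extra variability of the feasible-GLS estimator is
restored by a Kenward–Roger-type adjustment (`adjust_vcov = TRUE`) that
propagates the covariance-parameter uncertainty — computed from the
observed information — through the sensitivity of the slopes, using
closed-form derivatives of $\Sigma^{-1}$ for the compound-symmetry family
(the second-derivative term of the full Kenward–Roger expression is
omitted). In null simulations at the confirmation scale the Wald test's
type-I error is near 13% under naive ML and near the nominal 5% with both
corrections; the acceptance suite re-measures this on every run. Point
estimates are essentially unaffected by either choice, and `method = "ml"`
with `adjust_vcov = FALSE` recovers the plain ML fit (used when comparing
against the dense-likelihood oracle). Satterthwaite/Kenward–Roger *df*
adjustments are deliberately not implemented: the between-within df are
part of the analysis being reproduced.

## The synthetic-data generator

The generator exists so that every stage runs and is testable with no
external data, under study conditions fixed once:

* **Items.** A factor-structured latent model: item $=$
  $\mu_s + \sigma_s(\lambda\,\eta_f + \sqrt{1-\lambda^2}\,\epsilon)$,
  rounded and clamped into the response range. Loadings
  (.852/.777/.709 for hedonic/psychological/social) and factor correlations
  (.827 between hedonic and the eudaimonic factors, .937 between
  psychological and social) were back-solved from the reported scale
  reliabilities (α .87/.89/.82, 11-item eudaimonic .92) and scale
  correlations (r ≈ .74 and .80), and the location/scale parameters come
  from the reported scale means and SDs (3.63 (1.08), 3.40 (1.11),
  2.70 (1.14)). Rounding cuts (rather than equal-frequency cuts) are used
  precisely so the reported scale means — well above the response midpoint —
  are matched; clamping at the scale ends compresses the tails slightly, so
  generated means run ~0.05–0.08 low. Eudaimonic predominance (~22%)
  emerges from these moments without further tuning. A two-subpopulation
  mixture option (hedonic-shifted) exists but is off by default; its
  parameters are not identified by any reported moment. The Ryff layout
  uses loadings back-solved from the six reported reliabilities
  (.67–.83), a common inter-factor correlation of .62 (mid-range of the
  reported $R^2$ .14–.52), and the reported scale means/SDs.
* **Covariates.** Age ~ N(48.4, 8.8) truncated to the recruitment range
  35–64, 60% female, 76% white, BMI ~ N(27.4, 6.2), 3.3% smokers, 74.6%
  alcohol consumers, illness symptoms Gamma-matched to mean 1.05/SD 0.9 on
  the 0–8 scale, CES-D ~ N(12.5, 9.4) truncated to 0–60 — all from the
  reported sample table, generated independently of well-being.
* **Expression.** $y_{gi} = \mu_g + \sigma_g\,\mathrm{sign}_g\,
  (x_i'\beta + e_{gi})$ on the log2 scale, with $e_i$ unit-variance HCS
  noise at common correlation $\rho = 0.30$ (a realistic shared-variance
  level for co-regulated inflammatory/interferon transcripts; published CTRA
  analyses do not report it). Noise is scaled by $\sqrt{1 - var(x'\beta)}$
  so each gene's total variance is exactly $\sigma_g^2$, which identifies
  `b_true` directly on the standardized-analysis scale — the scale on which
  pooled association coefficients are reported. Eight marker transcripts
  are appended as independent N(8, 1) log2 rows.

**What the generator does *not* emulate.** Probe-level BeadArray artifacts,
batch effects, non-Gaussian expression noise, block-structured gene–gene
correlation (the single-ρ HCS structure is the fitted model's own
assumption), covariate–well-being dependence (e.g. the reported CES-D
correlation with well-being is not induced), and the item-level joint tails
that drive the categorical flourishing rate — the synthetic prevalence runs
near 32–35% rather than the reported 50%, because the reported first- and
second-order moments do not pin down that tail probability. Passing tests
on synthetic data therefore demonstrate the correctness and calibration of
the *procedures* under the stated conditions, not distributional fidelity
of real PBMC arrays.

**Sample standardization and calibration.** Standardizing genes by their
*in-sample* SD couples the response scale to the realized between-subject
variance and adds estimator noise that no model-based standard error can
see. At the confirmation scale this inflates the Wald test's type-I error
from ~5% (data meeting the model's assumptions exactly) to ~8%
(full pipeline); the acceptance suite asserts exact-scale calibration in
[3%, 7%] and, for the full pipeline, the 2-SE coverage property (≥90% over
null replicates). Users should read borderline p-values from the fully
standardized pipeline with this in mind.

## Problem sizes used by tests and the acceptance script

Oracle-equivalence checks run at $G \le 5$, $n \le 40$; parameter recovery
uses 100 replicates and null calibration 500 replicates at the full
confirmation scale (52 genes, 122 subjects, 17 predictors); CFA calibration
uses 500 replicates of a 6-item/2-factor structure at $n = 300$ (the
$\Delta df$ arithmetic is checked on the full 14-item structures); the
moment-fidelity checks use 2000–5000 subjects. These sizes make the full
suite and the acceptance script each run in a few minutes on one CPU while
keeping Monte-Carlo error well inside the asserted tolerances.

## Known limitations

* Inference corrections (REML + adjusted covariance) are implemented for
  the structured covariances; unstructured fits use model-based standard
  errors with a REML-type covariance update, and near $G \approx n$ rely on
  ridge stabilization.
* Ordinal-scale CFA (polychoric) is not implemented; chi-squares from
  continuous-item ML can differ from other estimators' published values.
* The categorical flourishing prevalence of the generator is emergent and
  lower than the reported sample's; analyses of the flourishing indicator
  on synthetic data operate at correspondingly lower base rates.
* Probe→symbol collapsing defaults to the max-mean rule; reproducing
  accession-based results exactly is sensitive to this choice and to the
  identity of the 8 marker transcripts, neither of which the source
  specifies.
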