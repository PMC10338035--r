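---
title: "Biological age clocks in children: models, preprocessing and inference"
author: "omicage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biological age clocks in children: models, preprocessing and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicage)
```

## The problem

Biological age markers try to summarise, in years, where an individual's
molecular state sits relative to their chronological age. In school-age
children this is conceptually delicate — development and ageing overlap —
but operationally the machinery is the same as in adults: train a sparse
linear predictor of chronological age on omic features ("a clock"), define
**delta age** as predicted minus chronological age, and relate delta age
(and relative telomere length) to developmental outcomes and health risk
factors under covariate adjustment.

`omicage` implements that full pipeline for multi-block omics (plasma
proteins, serum metabolites, urinary metabolites, optionally transcripts),
plus qPCR telomere quantification, the association framework with
Benjamini–Hochberg FDR control, over-representation analysis of clock
predictors, and the questionnaire/cognitive scores used to assemble the
cohort table. Because the cohort data this design targets are
access-restricted, the package ships a synthetic-cohort generator with
recorded ground truth; every stage is exercised against it.

## The clock model

Features are mean-centred and unit-scaled (sample SD, $n-1$; one convention
used everywhere), blocks are concatenated column-wise, and the clock is an
elastic net regression of chronological age $y$ on the feature matrix $X$:

$$\hat\beta = \arg\min_\beta \frac{1}{2n}\lVert y - \beta_0 - X\beta\rVert^2
 + \lambda\left(\alpha\lVert\beta\rVert_1 +
   \frac{1-\alpha}{2}\lVert\beta\rVert_2^2\right).$$

Hyperparameters are tuned by a line search for $\alpha$ over
$\{0, 0.1, \dots, 1\}$ (both endpoints included, so pure ridge and pure
lasso are candidates); for each $\alpha$, $\lambda$ is chosen by minimising
10-fold cross-validated mean squared error along the solver's $\lambda$
path. Design choices the procedure leaves open were fixed as follows:

* **CV-MSE minimum, not the one-SE rule** — the selection target is the
  minimiser of cross-validated MSE.
* **Ties** on CV MSE break toward larger $\lambda$, then larger $\alpha$:
  the sparser model.
* **Folds** are stratified by age decile and shared across the whole
  $\alpha$ grid, controlled by one seed, so the line search compares
  like with like and reruns are bit-identical.
* **No internal re-standardisation** — data are scaled once, up front, and
  the stored training means/SDs are *re-applied* (never re-estimated) to
  any test or follow-up data. Scaling is per feature across the
  concatenated matrix rather than per block; with unit-variance features
  the penalty then treats all blocks symmetrically.

Validation reports Pearson's $r$ and mean absolute error against
chronological age on held-out samples, per-group (e.g. per study centre)
correlations, and a paired one-tailed t-test of whether predicted
biological age increased between the baseline visit and a follow-up visit
roughly half a year later.

## Preprocessing

Each block runs through the assay-appropriate pipeline before scaling:

* **Quantifiability filters.** Proteins are kept only when more than 30% of
  measurements lie in the linear range between the lower and upper limits
  of quantification (LOQ1, LOQ2). Serum metabolites are dropped only when
  *both* the coefficient of variation exceeds 30% *and* more than 30% of
  values fall below the limit of detection — either condition alone keeps
  the feature. Transcripts drop samples with call rate < 40% before
  features with call rate < 1% (the two rules are order-ambiguous in
  general; this order is fixed and documented).
* **log2** transform of raw concentrations, with LOD/LOQ bounds transformed
  alongside the values.
* **Plate centering**: for each feature, subtract the plate mean minus the
  feature's grand mean, so every plate mean equals the grand mean
  afterwards. The operation is idempotent and grand-mean preserving; a
  feature with no data on some plate is left untouched there with a
  warning.
* **Truncated-normal imputation** of censored cells: per feature, the mean
  and SD are estimated from the in-range values only (a deliberate
  simplification; at a few percent censoring the bias is negligible), and
  below-LOQ1 / above-LOQ2 cells are drawn from the fitted normal truncated
  to $(-\infty, \mathrm{LOQ1}]$ / $[\mathrm{LOQ2}, \infty)$ by inverse-CDF
  sampling — every draw respects its bound exactly, uncensored cells are
  never altered, and the draws are seed-deterministic. Features with fewer
  than three in-range values are un-imputable and dropped with a reason
  code. Plate correction runs *before* imputation, so the truncation moments
  come from batch-corrected values.
* **Median-fold-change (probabilistic quotient) normalization** for the
  urinary block, which is diluted by hydration state: each sample's
  dilution factor is the median over features of its ratio to a reference
  profile (the feature-wise median sample by default; configurable), values
  are divided by the factor, offset by half the minimal positive value of
  the normalized block, and expressed as log2. The estimator is
  scale-equivariant: multiplying a sample by $c$ multiplies its factor by
  $c$.

## Telomere length

Relative telomere length is the efficiency-corrected, calibrator-normalized
T/S ratio. Amplification efficiency per target comes from a serial-dilution
standard curve, $E = 10^{-1/\text{slope}} - 1$. Each replicate well's
relative quantity is $Q = (1+E)^{\,Cq_{\mathrm{ref}} - Cq}$ with
$Cq_{\mathrm{ref}}$ the run's inter-run-calibrator mean for that target;
replicates average per sample, T/S is the ratio, each run is divided by the
geometric mean of its calibrator T/S values (geometric, because T/S is a
ratio-scale quantity), and finally every ratio is divided by the cohort
mean, so the sample-set average is exactly 1. The original analysis used a
proprietary package for this arithmetic; this is a reimplementation of the
standard model, not a byte-level clone. Replicate CVs are reported on the
quantity scale (the scale is stated because published triplicate CVs do not
always say); no replicate-outlier rejection is applied by default.

## The association framework

Markers enter the analysis as delta age in years; relative telomere length
is multiplied by −1 and unit-scaled, so its coefficients read as SD of
telomere *shortening*, directionally aligned with the clocks. Developmental
outcomes are the dependent variable (linear regression; logistic for
puberty onset); for risk-factor models the marker is the dependent
variable. All models adjust for chronological age, sex, ethnicity and study
centre on complete cases, and report Wald 95% intervals (odds ratios for
logistic fits). Continuous outcomes are centred and unit-scaled *except*
BMI and height z-scores, which are already on a reference scale; behaviour
checklist (CBCL) scores are log-transformed, implemented as $\log(x+1)$
because raw scores include zeros.

BH q-values are computed across the pooled family of all primary
marker-outcome and marker-risk-factor models. Sensitivity variants (sex
stratification, cell-fraction adjustment, risk-factor adjustment, centre
stratification) re-run every base model but are excluded from the FDR
family — whether the original family included them is not documented, and
excluding them keeps the primary q-values invariant to how many variants
are requested; the choice is configurable. Partial correlations between
markers residualise both variables on the covariate model matrix and use a
t reference with $n - 2 - k$ degrees of freedom, $k$ the number of
covariate columns.

## Enrichment

Over-representation uses the exact hypergeometric upper tail
$P(X \ge k)$ for the overlap $k$ between the clock's gene set and each
collection set, within an explicit, caller-supplied universe (all measured,
annotated genes). The original web-tool background was implicit; here the
universe is mandatory, because the p-value is meaningless without it. A set
is flagged significant only when the BH q-value is below 0.05 *and* the
overlap has at least 3 genes. Only the one-sided over-representation test
is offered.

## Derived scores

The questionnaire/cognitive scoring rules are implemented exactly as
published: KIDMED as (+1 per endorsed pro-Mediterranean item, −1 per
endorsed anti-Mediterranean item; range −4..11, verified exhaustively over
all $2^{15}$ patterns), the Family Affluence Scale category split 0–2 /
3–5 / 6–9, the pubertal development mean with the girls' menarche item at
its 1/4 coding and onset defined as mean > 1, working-memory
$d' = \Phi^{-1}(\mathrm{hit}) - \Phi^{-1}(\mathrm{fa})$ (rates of exactly 0
or 1 are clamped to $[1/2n, 1 - 1/2n]$ only when the trial count is
supplied — the published analysis does not state its correction, so without
a trial count the package refuses rather than guess), and the hit-reaction-
time standard error $\mathrm{SD}/\sqrt{n}$. CBCL subscale membership is not
public; subscale totals are accepted as inputs and only the log transform
is implemented.

## What the generator emulates — and what it does not

`simConfig()` / `generateStudy()` produce a cohort of `n_children` (default
1000) with ages uniform on 5–12 years across six centres. The printed
cohort description gives a mean near 7.9 and SD near 1.5 but no
distribution; uniform is the simplest shape spanning the printed range.
Each child has a latent **true delta age** (SD 1 year), and features follow

$$x_{sf} = \text{baseline}_f + \beta_f \cdot (\text{age}_s + \delta_s)
  + \text{plate}_{p(s),f} + \varepsilon_{sf}$$

on the log2 scale, exponentiated to the raw assay scale. Driving features
by *biological* age (chronological + delta) rather than chronological age
alone is deliberate: it is what makes the planted delta-age → outcome
effects recoverable by a clock at all. Outcomes are linear predictors in
covariates plus the configured delta effects plus noise; the urinary block
is multiplied by per-sample lognormal dilution factors; protein values
outside per-feature quantile-based LOQ bounds are masked and flagged; a
configurable fraction of non-signal features per block gets poor assay
quality so the QC filters have real work. qPCR wells are triplicates with
run shifts, eight inter-run calibrators and a six-point standard curve per
run. A panel subset is re-simulated at age + 0.5 years from the *same*
generating model (same coefficients, baselines, plate effects and LOQ
bounds, fresh noise), giving an honest temporal test set.

Default block sizes (36 proteins, 177 serum, 44 urinary metabolites) match
the assays this design targets. True age-feature counts default to 8/30/10:
deliberately a minority, both because selected-predictor counts in real
clocks exceed the true signal set (the penalized fit recruits correlated
noise), and because median-fold-change normalization presumes most features
are not systematically age-shifted. The signal scale (0.3 log2-units/year
against noise SD 1) was calibrated once against the package's own recovery
suite — panel-visit correlation, true-predictor recall, dilution-factor
recovery — and then frozen; it is not tuned per run.

Known non-realism, hence what passing tests do *not* show about real data:
features are conditionally independent given age (no correlation structure
beyond the shared age signal; an optional shared factor is out of scope),
effects are exactly linear in age, noise is Gaussian, censoring is
quantile-based rather than instrument-driven, covariate missingness is
completely at random, and the epigenetic-age column is simulated directly
rather than derived from methylation. Results on this generator certify the
*machinery* — estimators, filters, calibration, error control — not
biological conclusions.

## Numerical choices and degenerate inputs

* Sample SD ($n-1$) everywhere; stated once, used everywhere.
* One pseudo-random stream per generator component, split from the master
  seed, so enabling a block or component never perturbs the others' draws.
* Truncated-normal draws by inverse CDF (no rejection sampling, so draw
  counts are deterministic).
* Zero-variance features are dropped with a reason code before scaling;
  constant predictions are reported as "correlation undefined" with a flag
  rather than NaN propagation; perfect logistic separation flags the result
  instead of crashing; collinear covariates raise an error naming the
  aliased term.
* Dilution-standard curves require at least three points and a negative
  slope; the cross-validated line search requires $n \ge$ folds.
* The elastic-net line search records the full (α, λ, CV-MSE) path in the
  fitted object, so selection is auditable after the fact.

## Problem sizes in the shipped tests

The test-suite and acceptance-script simulations use the default study
(n = 1000, 257 features) once, and batches of reduced studies (n = 150–250,
6 features per block) for replicate-based checks: 200 replicates for CI
coverage of a planted delta-age effect, about 2000 tests each for the
association-stage and partial-correlation null-calibration rates, and 300
replicates for the progression-test null. These sizes were chosen so the
Monte-Carlo error of each check is comfortably below the margin it
asserts.

## Limitations

Array-level normalization, methylation clock training, cell-type
deconvolution, WHO growth references and spirometry curve QC are out of
scope — their outputs are accepted as input columns. The clock targets
chronological age, with the usual caveat that a near-perfect age predictor
leaves little residual variance in delta age; second-generation clocks
trained on clinical endpoints are not implemented.
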