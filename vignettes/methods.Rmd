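---
title: "Screening, imputing and predicting adolescent myopia with myoscreen"
author: "myoscreen maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening, imputing and predicting adolescent myopia with myoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myoscreen)
```

## The problem

School-age myopia develops gradually: a child's refraction (RA, in
diopters; negative values are myopic) drifts downward from grade 1 to
grade 6 at a rate shaped by parental myopia, ocular biometry (axial length,
corneal curvature), behaviour (indoor/outdoor activity, reading habits) and
diet. Screening programmes collect many candidate factors per child per
year, but the records are incomplete — senior-grade diopter measurements
are the worst affected — and only a minority of factors genuinely matter.

`myoscreen` implements a complete analysis pipeline for such cohorts:

1. **Factor selection** — a two-stage correlation screen;
2. **Data curation** — REP-guided gradient-boosted-tree (GBRT) imputation
   of missing diopters, factor-type-specific longitudinal reduction and
   min–max normalization;
3. **Model construction** — a linear-kernel SVM predicting whether a child
   is myopic by grade 6, with a full evaluation harness.

Because real school cohorts of this kind are not publicly deposited, the
package ships a first-class synthetic cohort generator that reproduces the
documented *shape* of such data, so every downstream stage is testable.

## The synthetic cohort generator

`simulateCohort()` draws, for each student, a latent annual progression

$$\Delta_i \;=\; \mathrm{drift} \;-\; \sigma \sum_k e_k\, z_{ik},$$

where $z_{ik}$ is the standardized reduced value (grades 1–5) of factor
$k$, $e_k$ a signed standardized effect, and $\sigma$ the per-grade
measurement noise SD (`noiseSd`). RA is measured around the linear trend:
$RA_{i,1} \sim N(\mu_0, \sigma_0^2)$ and, for $g>1$,
$RA_{i,g} = RA_{i,1} + (g-1)\Delta_i + \varepsilon_{i,g}$ with iid
$\varepsilon_{i,g} \sim N(0,\sigma^2)$ (grade 1 is recorded exactly).
Negative effects are protective, positive effects are risk factors, and a
null cohort (all $e_k = 0$) carries no signal at all: we chose measurement
noise around a per-student linear trend, rather than a random walk of
yearly increments, precisely so that the grade 1–5 progression feature
shares no noise with the grade-6 outcome — under a random walk even a null
cohort would be partially "predictable", which is an artefact of the noise
model and not of the biology.

Defaults (all configurable in `cohortConfig()`):

| parameter | default | why |
|---|---|---|
| `nStudents` | 3112 | the documented cohort size this generator emulates |
| `maleFraction` | 0.578 | documented sex ratio |
| `baselineMean`, `baselineSd` | +0.50, 0.75 D | grade-1 children are mildly hyperopic on average |
| `driftPerYear` | −0.15 D/yr | yields ≈ 40 % grade-6 myopia prevalence, matching the reported rise of myopia rates across primary school |
| `noiseSd` | 0.25 D | typical repeatability of school refraction screening |
| `missingRateMean`, `missingRateMax` | 0.15, 0.40 | documented per-factor mean and maximum missing rates |
| effect sizes | ±0.3–0.55 | see below |

Effect sizes are **standardized**: one SD of a factor's reduced value
shifts $\Delta_i$ by $e_k \sigma$ diopters/year. The default panel plants
fourteen non-zero effects whose *signs* follow the published multivariate
screening pattern (DAI, GENDER, JG, YW, AL, K1, K2, WHIM, EGG protective;
JTR, YTR, PULSE, COLA, REDM risk), with magnitudes 0.3–0.55 graded by
their published significance. The remaining eleven panel factors are
zero-effect nuisance columns, and `defaultFactorSet(nNuisance = n)` adds
more for the "wide data" regime (screening programmes collect ~200
factors, most of them irrelevant).

Missingness is missing-at-random conditional on grade only — the
mechanism is deliberately the simplest one consistent with the documented
rates: RA missingness rises linearly from 0 at grade 1 to
`missingRateMax` at grade 6; every other factor is missing at a flat rate
over grades 2+ calibrated so its overall rate is `missingRateMean`.

What the generator does **not** emulate: real factor marginals (they are
unpublished), informative missingness (children lost to follow-up because
they became myopic), measurement drift across schools, and non-linear or
interacting effects. A pipeline that passes on this generator is
calibrated and correct on linear-Gaussian MAR data; that is evidence of
correctness of the machinery, not of clinical performance on any real
cohort.

## Two-stage factor screening

Stage 1 (`univariateScreen`) computes the Pearson correlation of each
reduced factor with the target — the point-biserial correlation, since the
default target is the binary grade-6 myopia label — and a two-sided
p-value from $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df. Stage 2
(`multivariateFit`) refits the stage-1 survivors jointly by OLS and keeps
factors significant in the joint model (`selectFinal`), with RA forced in
by convention: diopter history is the key myopia predictor regardless of
its regression p-value. Both stages use **strict** `p < alpha`.

Design choices that were genuinely open:

* *the screening target*: taken as the binary grade-6 label, consistent
  with the prediction goal; a numeric grade-6 RA target is a one-line
  change.
* *the reduction level*: screening operates on the same per-student
  grades 1–5 reductions the predictor uses (sum/mean/progress), computed
  available-case before imputation (sums rescaled by $5/n_{obs}$), because
  selection runs before curation in the pipeline's phase order.
* *no multiple-testing correction*: the two-stage design is itself the
  false-positive filter; stage-1 calibration is verified by Monte-Carlo
  tests.

The myopia label uses the standard spherical-equivalent cutoff: myopic iff
grade-6 $RA \le -0.5$ D, boundary inclusive, configurable.

## GBRT imputation and the REP statistic

Missing diopters are filled with a from-scratch gradient-boosted
regression tree ensemble (`gbrtFit`): squared loss, $f_0 = \bar y$,
pseudo-residuals $r_{im} = y_i - f_{m-1}(x_i)$, depth-bounded CART trees
grown by exhaustive greedy variance-reduction splits, leaf values equal to
the leaf's mean residual, update
$f_m = f_{m-1} + \nu \sum_j c_{mj} I(x \in R_{mj})$. Defaults:
100 rounds, shrinkage $\nu = 0.1$, depth 3, minimum leaf 5 — conventional
small-tree boosting settings; all configurable.

One row of the imputation design is a (student, grade ≥ 2) cell. Its
predictors are the grade, the always-observed grade-1 RA, the student's
*other* observed RA values distilled into a per-student least-squares line
(its value extrapolated at the target grade, its slope, and the count of
supporting points — the target cell itself is always excluded, so training
rows never see their own value), and the student's reduced selected
factors.

Model selection follows the REP flow: the complete rows $D$ are split **by
student** into train/test at each proportion $p$ of a grid
(default 0.1–0.9 by 0.1); the fitted model is scored on the test rows by

$$REP = \frac{R^2}{r}, \qquad
R^2 = \frac{\sum_i (f(x_i)-\bar x)^2}{\sum_i (x_i-\bar x)^2}, \qquad
r = 1 - \frac{\#\{|x_i - f(x_i)| < y\}}{n},$$

with $\bar x$ the mean of the actual values and $y$ a predefined error
tolerance (default 0.5 D — half a diopter is the clinically meaningful
refraction difference). Note that this $R^2$ is a *spread ratio*, not
$1-SSE/SST$: it is 1 when predictions equal the data, 0 for a constant
prediction at the data mean, and can exceed 1 for over-dispersed
predictions (the package warns when it does). A zero error rate gives
$REP = \infty$, the best possible score, and ties break toward larger $p$
(more training data). The winning proportion's model is refitted on the
same deterministic split and used by `fillMissing()`; filled cells are
flagged, and cells whose predictors are unavailable are left missing and
logged rather than guessed.

Residual missing cells of *non-RA* factors (the published method fills
diopters only) are filled by the student's own mean over observed grades,
falling back to the per-grade cohort median — a deliberately simple,
deterministic rule.

## Feature transformation

`buildFeatureMatrix` reduces each selected factor by its kind:

* **RA** → mean annual progress over grades 1–5 (consecutive differences,
  next − previous, so negative = progressing; telescopes to
  $(RA_5-RA_1)/4$ on complete series). Grade 6 is never used — it defines
  the label.
* **behavioural/diet frequencies** (JG, YW, COLA, EGG, REDM, WHIM, …) →
  the grade 1–5 sum, accumulating the child's total exposure.
* **continuous ocular/physiological measures** (JTR, YTR, PULSE, AL, K1,
  K2, …) → the grade 1–5 mean, these quantities being slowly varying.
* **objective attributes** (DAI, GENDER) → the grade-1 value unchanged.

Features are then min–max normalized to $[0,1]$ with statistics learned on
the **training rows only** (avoiding leakage through the scaling; the
parameters are kept so `denormalizeFeatures` is an exact round-trip); a
degenerate feature (min = max) maps to 0.

## Classifier and evaluation

The predictor is a soft-margin SVM with linear kernel and penalty
$C = 1.0$ — high-dimensional screened-and-reduced features are close to
linearly separable, and the fixed default penalty avoids overfitting the
small positive margin. SVMs do not natively emit probabilities, so
Platt-type sigmoid calibration is used and the decision is
probability $> 0.5$, **strict** (a probability exactly at the threshold is
a negative call).

`evalReport` derives accuracy, precision, sensitivity, specificity and f1
from the confusion counts, the ROC by a threshold sweep over unique scores
(ties step simultaneously) with trapezoidal AUC — identical to the
normalized Mann–Whitney statistic — and stratified, seeded 10-fold
cross-validation. Undefined metric denominators report 0 with a recorded
note instead of failing. `runBaselines` evaluates logistic regression,
naive Bayes, 5-NN, random forest and a single-hidden-layer (16 unit)
backprop network under the identical stratified 80/20 holdout and CV
harness, with library-default hyper-parameters.

Two evaluation orders are available. The default mirrors the published
phase order — select and impute on the full data, then evaluate — which
leaks some information into the CV estimate. `runPipeline(nested = TRUE)`
re-runs selection, imputation-model fitting and normalization inside each
fold on its training students only; it is slower but leakage-free. Both
are deliberately kept: the first reproduces the method as described, the
second quantifies what the shortcut is worth.

## Numerical and reproducibility choices

* One master seed per pipeline run; every stage derives its own seed by
  stage-name hashing, so stages re-run independently yet reproducibly and
  two runs with the same config are bit-identical (manifests differ only
  in timings).
* GBRT split search pre-sorts each feature once per fit and scans nodes in
  sorted order with cumulative sums; ties in split gain go to the first
  feature and leftmost cut. Split points are midpoints between adjacent
  distinct values.
* Zero-variance factors screen to correlation 0, p = 1; collinear columns
  are dropped from the OLS refit with a warning naming them; a constant
  regression target yields an ensemble that predicts $f_0$ everywhere.
* Simulated RA is clamped to the plausible interval $[-12, +8]$ D, the
  same range the default cleaning rules enforce on real input.

## Problem sizes used in the shipped checks

The package's statistical property tests run at the generator's native
cohort scale ($n = 3000$–3112) for calibration, power, imputation-recovery
and end-to-end discrimination checks (20–200 replicates where a rate is
being estimated), and at $n = 200$–800 for structural unit tests; boosting
uses 25–60 rounds in the heavier sweeps. These sizes are the package's own
choice of a benchmark large enough for stable rates while keeping the
default suite quick to run.

## Known limitations

* The spread-ratio $R^2$ can exceed 1; REP is therefore not scale-free
  across wildly over-dispersed models. It is implemented as defined, with
  a warning.
* Evaluation of the default (non-nested) order inherits the published
  method's optimism; use `nested = TRUE` for honest error bars.
* The simple fill of non-RA factors ignores between-factor correlation.
* Performance numbers obtained on synthetic cohorts characterize the
  machinery under its own generative assumptions only.
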