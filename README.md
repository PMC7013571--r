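# myoscreen

Risk screening, missing-data imputation and prediction of adolescent
myopia from longitudinal school-cohort data.

Children followed from grade 1 to grade 6 accumulate yearly records of
refraction (RA, diopters; negative = myopic) alongside dozens to hundreds
of candidate risk factors — parental myopia, axial length, keratometry,
accommodation, activity, reading habits, diet. Two practical obstacles
stand between such data and a usable prediction model: most collected
factors are irrelevant, and the records are incomplete (senior-grade
diopter measurements worst of all, with per-factor missing rates around
15% and up to 40%). `myoscreen` is an R package, built in Bioconductor
style on `SummarizedExperiment`, for epidemiologists and biostatisticians
working with such cohorts.

## What it implements

1. **Two-stage factor selection.** Each factor, reduced to one value per
   student, is screened by point-biserial/Pearson correlation with a
   two-sided p-value from `t = r * sqrt((n-2)/(1-r^2))`; survivors
   (`p < alpha`, strict) are refitted jointly by OLS and the final subset
   keeps the jointly significant factors, with RA forced in.

2. **GBRT imputation selected by REP.** Missing diopters are filled with a
   from-scratch gradient-boosted regression tree ensemble (squared loss,
   `f0 = mean(y)`, greedy variance-reduction CART trees on
   pseudo-residuals, shrinkage update). The train proportion `p` is chosen
   by sweeping a grid and maximizing

   ```
   REP = R^2 / r,   R^2 = sum((f(x_i) - xbar)^2) / sum((x_i - xbar)^2),
   r = 1 - #{|x_i - f(x_i)| < y} / n
   ```

   on the held-out rows — a spread-ratio fitting goodness divided by the
   rate of errors at least the tolerance `y` (default 0.5 D).

3. **Factor-type transforms and a linear SVM.** RA becomes the mean annual
   progress over grades 1–5; behavioural frequencies are summed; continuous
   ocular measures are averaged; objective attributes pass through. After
   train-fitted min–max normalization, a linear-kernel SVM (`C = 1.0`) with
   Platt-calibrated probabilities (myopic iff `P > 0.5`, strict) is
   evaluated with confusion metrics, ROC/trapezoidal AUC, stratified
   10-fold CV and a baseline harness (logistic regression, naive Bayes,
   KNN, random forest, BP neural network).

Because cohorts of this type are not publicly deposited, the package
includes a first-class synthetic cohort generator (`simulateCohort`,
`applyMissingness`) reproducing the documented shape of such data —
planted signed effects on annual progression, grade-biased MAR
missingness — so the whole pipeline is testable end to end. See the
methods vignette (`vignettes/methods.Rmd`) for the model, defaults and
design choices.

## Worked example

```r
library(myoscreen)

cfg <- pipelineConfig(
  cohort_config = cohortConfig(nStudents = 600, seed = 42),
  pGrid = c(0.6, 0.7, 0.8, 0.9),
  gbrt  = list(rounds = 50, shrinkage = 0.1, maxDepth = 3, minLeaf = 5),
  model = list(C = 1, threshold = 0.5, folds = 5),
  seed = 42)
run <- runPipeline(cfg)
print(run)
```

```
== myoscreen pipeline report ==
master seed: 42

-- imputation sweep (p, R2, r, REP) --
   p        R2         r      REP
 0.6 0.8936002 0.1269147 7.040953
 0.7 0.8877997 0.1215227 7.305629
 0.8 0.8631658 0.1183932 7.290668
 0.9 0.8768315 0.1130435 7.756586
chosen train proportion: 0.90 (tolerance y = 0.50 D)

-- final feature subset --
  DAI [multivariate]
  GENDER [multivariate]
  ...
  RA [forced]

-- evaluation --
  accuracy: 0.884
  precision: 0.839
  sensitivity: 0.904
  specificity: 0.870
  f1: 0.870
  auc: 0.948
  5-fold cv accuracy: 0.857
```

Reading the output: the sweep shows, per train proportion, the held-out
spread-ratio `R2`, the fraction `r` of imputed diopters off by ≥ 0.5 D,
and their ratio REP — here `p = 0.9` wins (REP 7.76, only 11% of held-out
diopters off by half a diopter or more). The screen recovered 13 of the 14
planted factors plus forced RA at this modest cohort size, and the SVM
separates eventual sixth-grade myopes from non-myopes with AUC 0.948 on
the 20% holdout. With the generator's full default size (n = 3112) the
selected panel is complete and AUC rises above 0.95.

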