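---
title: "Lactation-intensity omics: methods and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lactation-intensity omics: methods and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lactomics)
```

This vignette documents the statistical model behind each stage of the
pipeline, the default parameters and why they have those values, and the
design decisions that affect numerical results.

## Study design being modeled

The pipeline targets a prospective postpartum cohort of women with
recent gestational diabetes (GDM), in which a **nested case-control
subset** is assayed: all (or a sample of) women who later developed type
2 diabetes (T2D) are cases, and controls are sampled within coarse
matching strata. Because controls are sampled with known, unequal
probabilities, cohort-level inference requires inverse-probability
weighting.

## Lactation intensity scoring

`feedingMonth()`, `monthlyIntensityRatio()`, and `lir2Month()` implement
the lactation intensity/duration ratio (LIR):

- monthly ratio = breast-milk feeds / (breast-milk + formula feeds) per
  24 h, a number in [0, 1]; it is undefined (an error) when no liquid
  feeds are recorded;
- the LIR score is the **sum over postpartum months 1 and 2**, range
  [0, 2];
- score ≥ **1.45** (the published cut-off, kept as the default) defines
  intensive breastfeeding (IBF); below it, intensive formula / mixed
  feeding (IFF/Mixed). The boundary itself classifies as IBF.

`feedingCategory()` adds the four-level view: *exclusive BF* (no
formula), *mostly BF* (formula ≤ 6 oz/day), *mostly FF/Mixed*
(formula > 6 oz/day), *exclusive FF* (no breast feeds). Reported
averages strictly between 6 and 7 oz are assigned to the mixed
category: the source scale jumps from "≤ 6 oz" to "> 6 oz", so the gap
is resolved by treating 6 oz as the last "mostly BF" value.

## Preprocessing

Order of operations (the order matters and is fixed):

1. **Missingness filter** — drop analytes missing in strictly more than
   `threshold` of non-control samples (defaults: 0.40 for metabolomics,
   0.05 for lipidomics at baseline;
   `filterMissingnessLongitudinal()` applies the rule at both
   timepoints and keeps the intersection).
2. **Half-LOD imputation** — remaining missing cells are replaced by
   half the analyte's limit of detection, the standard left-censoring
   convention for targeted panels.
3. **Total-sum normalization** — each sample is divided by its analyte
   total, then **log2** transformed and per-analyte **mean-centered**.
   Log base 2 makes effects directly readable as fold changes (a
   difference of −0.5 is a 1.4-fold depletion). Mean-centering removes
   the analyte-specific location so that group contrasts, which are
   location-invariant, are unchanged, while displays and
   cross-analyte comparisons are on a common scale.

**Compositional caveat.** Total-sum normalization makes abundances
relative: if a class carrying a real effect contributes a fraction *f*
of the panel total, the recovered log2 fold change of its members is
biased toward zero by roughly `0.42 × f × |effect|`. With realistic
panel shares (TAG ≈ 8% of analytes) the bias is a few hundredths of a
log2 unit; the acceptance tests budget for it.

**Batch correction.** Each assay batch carries an internal control
("IC") sample — a pooled-panel reference measured without biological
variation. `batchCorrect()` subtracts the per-analyte log2 difference
between the follow-up and baseline IC from the follow-up samples,
recovering the planted batch offsets exactly in simulation.

**Separation check.** `separationCheck()` is a two-component PLS-DA
(NIPALS; the weight vector is the first left singular vector of
`X'Y`) whose statistic is the between-centroid distance divided by the
mean within-group distance in score space, with an empirical
permutation p-value `(1 + #{perm ≥ obs}) / (1 + nPerm)` and
`nPerm = 1000` by default — enough resolution for the 0.05 level while
staying fast. A small internal NIPALS is used instead of a heavyweight
PLS dependency because only the two-component score projection is
needed inside the permutation loop.

## Design-weighted differential abundance

`weightedDiffAbundance()` fits, per analyte,
`value ~ group + covariates` by weighted least squares with weights
`1/π` (`samplingWeights()`), and tests the group term **marginally**
(Type III — the covariates are retained under the null, implemented as
a full-vs-reduced model comparison rather than sequential ANOVA).

Two variance regimes:

- **Constant weights** — the classical F-test; with unit weights the
  result is numerically identical to `anova(lm(reduced), lm(full))`.
- **Unequal design weights** — inverse-probability weights are *not*
  precision weights: the model-based variance understates the true
  sampling variance by the design effect of the weights (Kish factor
  `n Σw² / (Σw)²`), which inflates every test and compounds across an
  analyte family. The group test therefore switches to a
  **heteroskedasticity-robust HC3 sandwich Wald F-test**
  (leverage-adjusted squared residuals; F reference with the residual
  degrees of freedom). This keeps the family-wise rate of FDR < 0.05
  calls under the null generator consistent with Benjamini–Hochberg
  control.

When the data are complete, all analytes share one design matrix, so
both tests are vectorized through shared QR decompositions; the
per-analyte fallback (used when cells are missing) calls the same
routine and agrees exactly.

The reported `log2FC` is the weighted group-mean contrast with the
**last factor level as reference**, so with alphabetical `IBF` /
`IFF/Mixed` labels the sign convention reads "IBF relative to
IFF/Mixed". `bhFDR()` is Benjamini–Hochberg step-up (a thin wrapper
over `p.adjust` with input validation, verified against a brute-force
reference).

## Lipid structure

`parseLipidName()` accepts three dialects — Biocrates
(`PC aa C30:0`, `SM (OH) C22:2`, `lysoPC a C18:2`), Metabolon-style
(`TAG52:2-FA18:1`, `CE16:0`), and bare fatty acids (`FA 16:0`) — and
rejects chemically infeasible species (double bonds exceeding
`carbons %/% 2`). `aggregateByStructure()` places species on a class ×
carbon-number × double-bond grid (median log2FC, minimum FDR, and an
up/down/ns flag per cell); `fattyAcidCompositionMatrix()` crosses lipid
class with component fatty acid. `chainLengthBin()` uses the standard
convention: medium < 14 carbons, long 14–20, very-long ≥ 22.

The simulated lipid panel reproduces a realistic published class
composition; the printed per-class species counts in the source
material sum to more than the stated panel total, and the discrepancy
is resolved by reducing the phosphatidylethanolamine (PE) count to 97
so the classes sum to the stated 1008.

## Longitudinal screening

`mixedModelScreen()` fits, per analyte,

```
value ~ group * timepoint + lactationDuration + (1 | participant)
```

by REML with **Satterthwaite** degrees of freedom, and reports the
group × timepoint interaction — the test of whether a baseline feeding
difference persists at follow-up. Satterthwaite is the right reference
here: in the balanced two-timepoint design with positive
random-intercept variance the interaction t-statistic and its df
coincide *exactly* with the regression of within-participant change on
group, so the mixed model adds robustness to imbalance without
changing the balanced-case answer. Participants observed at a single
timepoint are excluded; singular fits fall back to the
paired-difference regression (`status = "paired-fallback"`).

## Signature selection

`repeatedSelection()` implements repeated down-sampled random-forest
selection with the published procedure numbers as defaults:

- a fixed hold-out of **25 per class** (`splitHoldout()`; from a 98
  case / 118 control cohort this leaves 73/93 for training);
- per repeat, the training majority class is down-sampled to balance
  (73/73), a **500-tree** random forest is fit, and the **top 30**
  analytes by Gini importance are logged;
- over **100 repeats**, analytes are ranked by selection frequency
  (ties: mean importance rank, then name — fully deterministic) and the
  top **10** form the signature;
- `evaluateSignature()` refits per repeat on the signature only and
  reports hold-out AUC, accuracy, F1, precision, sensitivity,
  specificity as medians with 2.5/97.5 percentile intervals, plus
  clinical-covariate baselines (rank AUC of the raw covariate) and a
  combined signature + clinical model.

The hold-out is drawn once and never touched during selection;
corrupting hold-out rows provably does not change the selected
signature (tested). Note that a single modest hold-out makes
permuted-label AUC estimates noisy — chance structure in one split
shifts all repeats coherently — so null checks should average over
several permutations.

## Cohort reporting

`summarizeCohort()` builds the standard baseline-characteristics table:
categorical variables as n (%) with **chi-square tests without
continuity correction** (the uncorrected test reproduces the published
glucose-tolerance p = 0.004; Yates' correction would give 0.006),
normal variables as mean (SD) with Welch t-tests, skewed variables as
median (IQR) with Mann–Whitney tests.

## The synthetic cohort generator

`simConfig()` / `simulateCohort()` / `simulateOmics()` generate:

- participant covariates (age, pre-pregnancy BMI, race/ethnicity, OGTT
  z-score sum, GDM treatment) with study-like marginal distributions,
  incident T2D at a configurable marginal rate (default 0.17) enriched
  in impaired glucose tolerance, and lactation propensity
  anti-correlated with BMI;
- feeding diaries for six months, from which LIR scores and feeding
  groups derive;
- nested case-control subsets with **exactly known** inclusion
  probabilities: control quotas per matching bin (age decade × BMI
  class × race) proportional to the bin's case count via largest
  remainder, capped at availability, with `π = quota / available`
  recorded per participant. Controls in bins with no quota have π = 0,
  so Horvitz–Thompson identities hold over the *covered* strata;
- two-timepoint log-normal abundances (log2 means ~ N(5, 1), SDs
  uniform on `sdRange = c(0.2, 0.6)`), planted per-class log2 effects
  in the IBF group at baseline (attenuated by `attenuationT2d`,
  default 0.5, in future-T2D women; shrunk by `followupShrink`,
  default 0, at follow-up), per-analyte follow-up batch offsets
  ~ N(0, `batchOffsetSd`), LOD-censoring plus
  missing-completely-at-random cells, and a noiseless internal-control
  column per batch. All planted truth is stored in
  `metadata(ae)$groundTruth`.

**What it does not emulate:** assay heteroskedasticity beyond
log-normality, correlated analyte blocks (analytes are independent
given class means), informative missingness beyond LOD censoring,
confounding of feeding group with the planted effects, loss to
follow-up, or measurement drift within a batch. It is a test harness
for the pipeline's statistical machinery, not a generative model of
plasma biochemistry.

Default cohort sizes in examples and tests (hundreds of participants,
100–200 analytes) are the package's own choice: large enough for the
asymptotics the tests rely on, small enough for a laptop-scale test
suite.

## Reproducibility

Every stochastic entry point takes an explicit seed (`simConfig(seed=)`,
`nestedCaseControlSample(seed=)`, `signatureConfig(seed=)`), and
`runPipeline()` writes an md5 manifest of all artifacts so identical
configurations produce identical checksums.
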