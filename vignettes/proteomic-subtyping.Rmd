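---
title: "Proteomic subtyping of SCLC cohorts: models, parameters, design choices"
author: "ProteoSubtype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteomic subtyping of SCLC cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProteoSubtype)
```

# Overview

ProteoSubtype implements a proteomic stratification workflow for small
cell lung cancer (SCLC) cohorts profiled by label-free mass spectrometry:

1. **Quantification** — raw protein intensities are converted to iBAQ
   (intensity / theoretical observable peptides) and then to FOT
   (fraction of total: each protein's iBAQ divided by the sample's iBAQ
   sum), a per-sample normalization that makes abundances comparable
   across experiments. Undetected proteins are imputed with one tenth of
   the sample's smallest positive FOT.
2. **Feature selection** — the union of each sample's 1100 most abundant
   detected proteins, filtered to proteins detected in more than 10% of
   samples with a coefficient of variation above 1.9.
3. **Consensus NMF subtyping** — KL-divergence multiplicative-update NMF
   ("brunet") restarted 50 times per cluster number `k`; co-clustering
   frequencies form a consensus matrix, labels come from average-linkage
   hierarchical clustering of `1 - consensus`, and `k` is chosen among
   candidates 2–6 by stability, class size and prognostic gates.
4. **Signatures and classifier** — one-vs-rest Wilcoxon + fold-change
   signatures per subtype (fold change above 3, 3, 10 for S-I, S-II,
   S-III); a random-forest classifier on a Welch-t/BH-selected panel with
   stratified 10-fold cross-validation, applicable to external cohorts.
5. **Survival analyses** — Kaplan–Meier, multi-group log-rank, Cox
   proportional hazards with Wald statistics; chemotherapy benefit within
   TNM II/III; first-line immunotherapy PFS comparisons; IHC scoring.

Because patient-level data cannot ship with the package, a synthetic
cohort generator reproduces the statistical structure such cohorts have,
so every stage is testable end to end.

# The synthetic cohort generator

`cohortDesign()` fixes the *study conditions*; `simulateCohort()` draws a
cohort from them. The default design emulates a discovery cohort of 75
FFPE samples and 7000 proteins with three latent subtypes (mixture
37/27/36%), planted overexpression signatures with fold changes (3, 3,
10), heavy abundance-dependent missingness, and exponential survival with
subtype-specific chemotherapy interactions.

## Abundance and dropout model

Each protein has a log-normal baseline intensity
(`baseAbundanceLogMean = log(1e6)`, `baseAbundanceLogSD = 2` on the
natural-log scale, spanning roughly four orders of magnitude), shared by
all samples; each measurement multiplies it by log-normal sample noise
(`noiseLogSD = 0.8`). Detection is Bernoulli with logistic probability in
the latent log intensity (midpoint `log(1e6) + 0.5`, slope 2.5); an
undetected entry is recorded as 0 with the detection mask kept alongside,
matching the pipeline's "identified" semantics. Dropout acts on the
latent value *before* observation, so imputation and detection-frequency
filters face the same censoring a real search-engine output shows.

Signature proteins are anchored at a common *activated* abundance
(`signatureLogMean = log(1e6) + 0.6`, sd 0.5); their resting baseline is
the activated level divided by the subtype's fold change. This mirrors
marker biology — a 10-fold overexpressed marker has a low resting level,
not an extreme activated one — and places resting markers near or below
the detection midpoint, giving them the on/off behaviour (and hence the
high coefficient of variation) that real subtype markers show in
label-free FFPE data. Each subtype plants 150 markers, consistent with
the one-to-two hundred subtype-specific proteins such cohorts yield.

Under these defaults a simulated cohort reproduces the structure the
pipeline was built for: roughly 43% of the intensity matrix detected,
~2900 of 7000 proteins detected in more than half the samples, a
top-1100 union of ~3100–3400 proteins, and ~350–450 clustering features
after the frequency and CV filters.

The proteome — marker identity, per-protein baselines, peptide counts —
is seeded by the *design*, while the cohort seed governs sampling. Two
cohorts drawn from one design with different seeds therefore share their
biology and can serve as discovery/validation pairs, which is exactly how
the classifier-transfer analyses are exercised.

## Survival model

Overall survival is exponential: subtype `s` with treatment flag `z` has
hazard `hazardRates[s] * exp(treatmentLogHR[s] * z)` per year, with
independent exponential censoring (0.08/year) capped at 8 years of
follow-up. The default hazards (0.0575, 0.21, 0.66)/year give five-year
survival of about 75%, 35% and 4%, spanning the best-to-worst prognosis
range such cohorts show. Chemotherapy log hazard ratios (-1.2, +0.7, 0)
encode a strong benefit in the best-prognosis subtype, a detriment in the
middle one, and insensitivity in the worst. Clinical covariates (age,
gender, smoking, lymph-node metastasis, TNM, VALG) are drawn
independently of subtype by default so that Cox adjustment isolates the
subtype effect; the staging mixture is a design knob because the joint
distribution of staging and molecular subtype is not identifiable from
aggregate descriptions. Progression-free survival uses its own
per-subtype exponential rates (default twice the OS hazards) and is
reported for ICI-treated patients.

What the generator deliberately does **not** model: peptide-level
variation, batch effects, correlated marker blocks, non-proportional
hazards and informative censoring. Passing tests therefore demonstrate
the pipeline's correctness and its ability to recover planted structure,
not performance guarantees on any real cohort.

# Quantification choices

- "Minimum/10" imputation reads the *sample's* global non-zero minimum:
  each sample gets its own imputation constant. A dataset-global variant
  is deliberately not offered as a default; the per-sample rule keeps
  imputed mass below every detected value in that sample and makes
  `imputeMissing()` idempotent.
- Normalization runs before imputation and columns are not re-normalized
  afterwards: FOT is defined over identified proteins, so detected
  entries of each sample sum to exactly 1 and imputed entries add a small
  remainder.
- Proteins never detected anywhere in a cohort are dropped with a warning
  rather than imputed — there is no information to impute from.

# Feature selection choices

- Detection thresholds are strict fractions ("more than 10%", "more than
  25%") of the cohort size; at 75 samples the 10% rule is equivalent to
  "at least 8 samples".
- Ties at the top-N abundance boundary are all kept, so the union is
  deterministic and invariant to protein ordering.
- The CV uses the sample standard deviation (n-1) over the mean and is
  computed on the imputed matrix across **all** samples: a detected-only
  CV would be undefined for singleton detections, and the on/off pattern
  a dropout-censored marker shows *is* its variability signal.

# Consensus NMF choices

- Input scaling: each retained protein is min–max scaled to [0, 1] across
  samples. FOT spans orders of magnitude and unscaled KL-NMF is dominated
  by the few most abundant proteins; scaling gives every retained feature
  comparable leverage. This is a configurable preprocessing step
  (`nmfInput()`), not part of the factorization itself.
- Initialization is uniform-random in (0, 1] per seed; run `r` of a
  consensus uses `baseSeed + r - 1`. Convergence: relative divergence
  change below 1e-6 over a 10-iteration window, capped at 2000 sweeps. In
  the KL objective, entries with observed 0 contribute only their
  reconstruction, and reconstructions are floored at 1e-12 inside logs.
- Per-run sample assignment is the argmax over the k coefficient rows;
  consensus labels come from average-linkage hierarchical clustering of
  `1 - consensus`; silhouettes are computed on the same dissimilarity
  (singletons score 0).
- The 50 restarts follow the convention that a consensus over a single
  run is meaningless; "iterations" of a consensus NMF here means random
  restarts, not inner update sweeps.
- Both the consensus machinery and the classifier canonicalize sample
  order internally (ids sorted before seeding), which makes the entire
  path equivariant to column permutations of the input — identical
  cohorts loaded in different orders give identical results.

## Choosing the number of clusters

A candidate `k` must pass three *gates*: average silhouette above 0.8,
at least 10 members in the smallest class, and a k-group log-rank test on
overall survival below 0.01. Among gated candidates the default rule
(`rule = "finest"`) returns the **largest** eligible `k`.

The rationale: on consensus matrices, coarser solutions are structurally
favoured by raw stability. When one subgroup separates cleanly, every
random restart at `k = 2` agrees on splitting it off and the consensus
matrix is exactly 0/1 — average silhouette 1.0 — even though a finer,
equally stable and still prognostic stratification exists. Treating the
silhouette as an objective to maximize therefore collapses well-separated
cohorts to two clusters; treating it as a stability gate and then taking
the finest stratification that remains stable, adequately populated and
prognostic matches how the cluster number is chosen in practice. The
literal max-silhouette rule is available as `rule = "max-silhouette"`.

Recovered clusters are then named S-I, S-II, ... in order of increasing
crude event hazard (events per person-year), so "S-I" is always the
best-prognosis subtype and naming is reproducible across runs and
cohorts.

# Signature and classifier choices

- Fold changes are ratios of arithmetic means of imputed FOT (not
  log-space means): "fold change above 3" then reads literally as a
  3-fold abundance ratio. One-vs-rest contrasts with pooled rest; with
  three groups and thresholds of at least 3 the signature sets are
  provably disjoint, and the code asserts this on every run.
- "Adjusted t-test" is implemented as a Welch t-test on log10 FOT with
  Benjamini–Hochberg adjustment across the candidate panel, the
  field-standard reading; the Wilcoxon signatures use raw p below 0.05
  with the fold-change threshold carrying most of the selectivity.
- The random forest uses 500 trees; candidate-features-per-split is tuned
  over {sqrt(p), p/4, p/2} by stratified 10-fold cross-validation, ties
  resolved toward the smaller value. Folds are size-balanced within one
  sample and stratified by subtype. All randomness flows from one integer
  seed.
- Predicting an external cohort fills panel proteins that are absent (or
  undetected) with the per-sample imputation constant; if more than half
  of the panel is entirely missing the model refuses to predict rather
  than guessing.

# Survival analysis choices

- Cox ties: Efron by default (clinical follow-up times are often
  year-granular and heavily tied); Breslow selectable. Efron and Breslow
  agree exactly when no event times tie.
- The multi-group log-rank uses the full covariance matrix of the group
  event counts, not the sum of marginal variances, which matters at
  k > 2.
- The chemotherapy-benefit analysis is restricted to TNM II/III before
  any test is run, because stage I and IV dominate prognosis on their
  own; subtypes with an empty treatment arm are reported as not evaluable
  instead of erroring.
- Multivariate Cox encodes TNM as a categorical covariate with stage I as
  the reference.
- IHC scores bin as: below 10 → "0", 10–40 → "1+", above 40 to 140 →
  "2+", above 140 → "3+"; positivity requires a score strictly above 10.
  A score of exactly 10 is thus bin "1+" yet negative — a deliberate,
  literal implementation of the published scoring convention.

# Problem sizes used by the test suite

The packaged tests exercise two scales, chosen as a compromise between
statistical resolution and a test suite that runs in minutes: a small
design (60 samples x 600 proteins, 25 markers/subtype) for module-level
checks, and the full emulated conditions (75 x 7000, 150 markers/subtype,
50 NMF restarts, k = 2..6, ten seeds) for the recovery suites. Power
checks (log-rank, Cox recovery, planted treatment effects) use n =
150–600 with 10–20 replicate seeds and thresholds that tolerate the
expected binomial wiggle.

# Known limitations

- The generator's independence assumptions (markers independent given
  subtype, covariates independent of subtype) make recovery easier than
  in real cohorts with correlated programs and confounded staging.
- Exponential survival cannot express late-crossing hazards; the
  treatment interactions are proportional by construction.
- KL-NMF is run on min–max scaled data; other scalings (rank, z-score on
  logs) would change the retained-feature geometry and are not explored.
- The k-selection gates inherit the arbitrariness of their thresholds
  (0.8 silhouette, 10 members, P < 0.01); they are exposed as arguments
  rather than hidden constants.
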