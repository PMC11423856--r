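# ProteoSubtype

Proteomic subtyping and survival stratification of small cell lung
cancer (SCLC) cohorts profiled by label-free mass spectrometry.

SCLC is an aggressive neuroendocrine lung cancer whose genomic and
transcriptomic classifications correlate poorly with outcome. Proteomic
stratification — clustering patients on normalized protein abundance —
separates cohorts into subtypes with distinct prognosis, chemotherapy
benefit and immunotherapy response. This package implements that
workflow end to end for researchers analysing protein-level label-free
quantification of tumor cohorts with clinical follow-up:

- **Quantification.** iBAQ (raw intensity divided by the number of
  theoretically observable peptides), FOT normalization
  (`FOT_ij = iBAQ_ij / sum_i iBAQ_ij`, so each sample's identified
  proteins sum to 1), and per-sample minimum/10 imputation of
  undetected entries.
- **Feature selection.** Union of each sample's top-1100 most abundant
  detected proteins, filtered by detection frequency (> 10% of samples)
  and coefficient of variation (> 1.9).
- **Consensus NMF subtyping.** Multiplicative-update NMF minimizing the
  generalized Kullback–Leibler divergence `D(V‖WH)` (the "brunet"
  algorithm, implemented in C++), 50 random restarts per cluster number
  `k`; samples co-clustering across restarts define a consensus matrix;
  `k` (range 2–6) is chosen by stability (average silhouette > 0.8 on
  `1 − consensus`), class size (≥ 10) and prognostic association
  (log-rank P < 0.01). Subtypes are named S-I, S-II, … by ascending
  event hazard.
- **Signatures & classifier.** One-vs-rest Wilcoxon + fold-change
  signature proteins (FC > 3 / 3 / 10); a random-forest classifier on a
  Welch-t/Benjamini–Hochberg feature panel (FC > 1.5, adjusted
  P < 0.05, detection > 25%) with stratified 10-fold cross-validation,
  transferable to independent cohorts.
- **Survival analyses.** Kaplan–Meier, multi-group log-rank with full
  covariance, Cox proportional hazards (Efron ties) with Wald CIs;
  chemotherapy-benefit tests restricted to TNM II/III; first-line
  immunotherapy PFS comparisons; IHC score arithmetic (intensity ×
  percent positive, bins 0/1+/2+/3+, positive if > 10).
- **Synthetic cohorts.** `cohortDesign()` / `simulateCohort()` generate
  cohorts with the statistical structure this analysis assumes — latent
  subtypes, planted marker signatures, abundance-dependent dropout,
  subtype-dependent survival with treatment interactions — so the whole
  pipeline can be exercised and tested without patient data.

## Worked example

```r
library(ProteoSubtype)

design <- cohortDesign()          # 75 samples x 7000 proteins, 3 subtypes
sim <- simulateCohort(design, seed = 1)
run <- runDiscovery(sim$intensity, sim$clinical, params = list(seed = 1))

run$kSelection$report
#>   k averageSilhouette minClassSize logrankP eligible
#> 1 2             1.000           32 7.90e-12     TRUE
#> 2 3             0.991           19 2.39e-12     TRUE
#> 3 4             0.803            7 1.35e-11    FALSE
#> 4 5             0.392            1 2.31e-26    FALSE
#> 5 6             0.382            2 6.01e-11    FALSE

table(run$subtypes)
#>  S-I S-II S-III
#>   24    19    32

cvAccuracy(run$classifier)
#> [1] 0.92

head(run$survival$cox[, c("term", "hazard_ratio", "ci95_low",
                          "ci95_high", "wald_p")], 2)
#>           term hazard_ratio ci95_low ci95_high    wald_p
#> 1  subtypeS-II        7.839    2.009     30.59 3.035e-03
#> 2 subtypeS-III       30.207    8.197    111.32 3.035e-07
```

Reading the output: the consensus is essentially block-perfect at
`k = 2` and `k = 3`, but only those two pass all three gates
(silhouette, class size, prognosis), and the finest gated stratification
is `k = 3` — the 24/19/32 split matching the planted subtypes (adjusted
Rand index 0.97 against the planted labels). The random forest separates
the subtypes with 92% cross-validated accuracy, and the adjusted Cox
model estimates a hazard ratio of ~30 for S-III vs S-I — wide CI at
n = 75; the planted rates (0.66 vs 0.0575 per year) plus the planted
chemotherapy benefit in S-I imply a true adjusted ratio above 11.5.

Classify an independent cohort with the trained model:

```r
val_sim <- simulateCohort(design, seed = 2)
val <- runValidation(run$classifier, val_sim$intensity, val_sim$clinical)
table(val$predictions$label)
val$logrank$p_value
```

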