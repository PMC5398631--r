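# scnacompare

Comparative analysis of somatic copy-number alterations (SCNAs) between
tumor cohorts, from segmented SNP-array profiles.

Two patient populations can differ in tumor purity, in the prevalence of
the chromosomal-instability (CIN) subtype, and in overall focal event
burden — and each of these mimics a genuine biological difference in
copy-number landscapes. `scnacompare` implements the analysis chain that
separates real cohort-differential events from these confounders:

* **ISAR correction** — in-silico admixture removal. Observed copies are
  modeled as `c = (α·q + 2(1−α)) / D` with purity α, tumor copy `q`,
  normalization factor `D = (α·τ + 2(1−α))/2` and ploidy τ; the correction
  inverts this exactly given (α, τ).
* **Genomic disruption** — fraction of the autosomal genome deviating from
  the sample's length-weighted median copy level by more than 0.1 copies;
  SCNA segments and arm-level gains/losses called at a strict 0.2-copy
  threshold; focal vs arm-level scope split at half an arm's length.
* **Ancestry assignment** — EIGENSTRAT-normalized genotype PCA, exact 1-D
  two-means clustering of PC1 with a robust (median/MAD) outlier pass.
* **CIN classification** — RBF-kernel SVM (σ = 1, i.e. γ = 0.5) on the 39
  arm-level median copy features, C chosen by cross-validation.
* **Recurrent regions** — marker-grid G-scores of focal amplitude over a
  0.1-copy noise floor, cyclic-shift permutation null pooled across
  markers, BH FDR, minimum-q peak reporting, overlap/nearest gene
  association.
* **Cohort comparison** — rate-difference statistic with a permutation
  null stratified on CIN class × focal-disruption quartiles (49,000
  permutations by default), an underpowered-event filter based on the most
  extreme achievable allocation, and BH FDR over powered events only.
* **Synthetic cohorts** — a generator that plants arm events, focal events
  at cohort-specific rates, Beta-distributed purity and Balding–Nichols
  two-population genotypes, with full ground truth, so every stage above
  is validated against known answers.

## Worked example

```r
library(scnacompare)

params <- simulation_params(n_east = 250, n_west = 230, seed = 1)
sim <- simulate_cohort(params)          # profiles, genotypes, purity, truth

arms      <- autosomal_arms(sim$arms)
corrected <- isar_correct(sim$profiles, sim$purity)
disr      <- genomic_disruption(corrected, arms)

feats   <- arm_feature_matrix(corrected, arms)
labeled <- sim$metadata$sample_id[sim$metadata$subtype_label != "UNKNOWN"]
model   <- train_cin_svm(feats[labeled, ],
                         sim$metadata$subtype_label[match(labeled, sim$metadata$sample_id)])
cin     <- predict_cin(model, feats)

em      <- build_event_matrix(corrected, arms, sim$regions)
strata  <- assign_strata(sim$metadata, disr, cin_labels = cin)
results <- compare_cohorts(em, sim$metadata, strata, n_perm = 49000, seed = 1)
head(results, 3)
#>          event_id rate_east rate_west statistic   p_perm    q_bh powered
#> 1 del_diff_9p:del     0.140     0.300    0.1600 4.08e-05 0.00331    TRUE
#> 2         5p:gain     0.116     0.187    0.0710 4.49e-02 1.00000    TRUE
#> 3         6p:gain     0.112     0.174    0.0619 6.38e-02 1.00000    TRUE
```

The planted differential deletion (`del_diff_9p`, simulated at 27% West vs
11% East) is the only event among 84 tested reaching q < 0.05 (observed at
30% vs 14% in this realization); arm events and background focal regions,
simulated at equal rates between cohorts, stay null. Rate differences that
merely reflect the cohorts' different CIN prevalence (e.g. the nominally
inflated arm gains above) are absorbed by the stratified null and survive
nowhere after FDR. The same chain runs
from a single YAML config via `run_pipeline()` or the wrapper script
`inst/scripts/scna-pipeline.R`, which writes all tables plus a manifest of
parameters, seeds and output checksums (same config + seed ⇒ bit-identical
outputs).

See the vignette (`vignettes/comparative-scna-analysis.Rmd`) for the
models, parameter defaults, and the design decisions behind them.

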