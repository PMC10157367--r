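# coexcell

Single-cell oncogene coexpression subpopulations in lymphoma: quantification,
spatial statistics, probabilistic inference, and pooled survival analysis.

## What this solves

Diffuse large B-cell lymphoma (DLBCL) routinely over-expresses the oncogenes
MYC, BCL2 and BCL6, but clinical assays (chromogenic IHC, bulk expression)
score each marker in isolation and say nothing about which *cells* coexpress
them. Multiplexed fluorescent immunohistochemistry (mfIHC) yields per-cell
intensities for all markers at once, so each CD20⁺ B cell can be assigned one
of the eight MYC/BCL2/BCL6 positivity permutations (`M+2+6+`, `M+2+6-`, …,
`M-2-6-`) and each tumor summarized by the **percentage extent** of every
subpopulation. `coexcell` is for computational pathology and lymphoma
researchers who have segmented cell tables (or only single-marker scores, or
only bulk mRNA) and want the full quantitative chain:

- **Quantification** — per-cell positivity against per-image thresholds
  (strictly above threshold), subpopulation labeling, per-patient extents as
  cell-weighted means across cores, and field-sampling stability of the
  dichotomized call.
- **Spatial statistics** — pair correlation function g(r) in 10-µm rings up
  to 250 µm with translation edge correction (g = 1 under complete spatial
  randomness), deviations Δ% of each cell's 20-nearest-neighbour composition
  from whole-tissue extents, 8×8 interaction matrices, label-permutation
  nulls, and Ward (minimum-variance) clustering of interaction profiles.
- **The independence metric** — if positivity is independent across cells,
  the extent of any subpopulation is predictable from single-marker scores:

  `predicted(M+2+6−) = 100 · (pM/100) · (p2/100) · (1 − p6/100)`

  and analogously for all eight patterns. This turns routine single-marker
  scores into an estimate of, e.g., the prognostic `M+2+6-` subpopulation.
- **eCDF mapping** — bulk mRNA values are converted to inferred protein
  extents by matching percentiles of the (Gaussian-smoothed, bandwidth = 1%
  of range) mRNA eCDF to a consensus protein eCDF, independently per
  dataset; mapped marginals feed the independence metric.
- **Survival meta-analysis** — extents as 5%-unit increments (units
  [0,1], (1,5], (5,10], …) in Cox proportional-hazards models per cohort,
  pooled by a Paule-Mandel random-effects model with Bonferroni correction
  over the 8 subpopulations; Kaplan-Meier/log-rank at fixed (15%) or
  scanned optimal cutoffs; multivariate adjustment for IPI Risk Group and
  MYC FISH status.
- **Transcriptome correlates** — gene-wise Spearman correlation with the
  `M+2+6-` metric pooled across cohorts on the Fisher-z scale (hits at
  |ρ| ≥ 0.2 and FDR ≤ 0.001), and single-cell expression-status assignment
  with a Wilcoxon marker test.

A synthetic cohort generator (`generate_cohort()`) reproduces the
statistical structure every stage assumes — patient-level marginals,
independent/interdependent/exclusive per-cell co-positivity, CSR or Thomas
clustered placement, thresholdable intensities, survival tied to the true
`M+2+6-` extent, and mRNA linked monotonically to the true marginals — so
the whole pipeline is testable with known ground truth and no patient data.

## Worked example

```r
library(coexcell)

cfg <- synthetic_config(n_patients = 40, cores_per_patient = 2,
                        cells_per_core = 800, seed = 7)
cohort <- generate_cohort(cfg)

flagged  <- call_positivity(cohort$cells, cohort$thresholds)
profiles <- patient_extents(flagged)$profiles
round(profiles[1, c("M+2+6-", "pM", "p2", "p6")], 1)
#>   M+2+6-   pM   p2   p6
#> 1    1.4 12.6 23.5 53.9

# independence metric from that patient's own single-marker scores
predict_profile(profiles$pM[1], profiles$p2[1], profiles$p6[1])[["M+2+6-"]]
#> [1] 1.367155

# concordance of observed and predicted extents across the cohort
round(range(concordance(profiles)$rho), 3)
#> [1] 0.987 0.998

# per-cohort unit-increment Cox fits, pooled with Paule-Mandel
surv <- merge(cohort$survival, profiles, by = "patient_id")
set.seed(1)
surv$cohort <- sample(rep(c("A", "B"), length.out = nrow(surv)))
fits <- do.call(rbind, lapply(split(surv, surv$cohort), function(d)
  fit_cox(extent_to_units(d[["M+2+6-"]]), d$os_months, d$os_event)))
pool_random_effects(fits, n_hypotheses = 8)
#>   pooled_log_hr pooled_se pooled_hr  ci95_lo  ci95_hi tau2   pooled_p bonferroni_p k
#> 1     0.2641461 0.1467705  1.302318 0.976751 1.736404    0 0.07190447    0.5752357 2
```

The first patient's observed `M+2+6-` extent (1.4% of CD20⁺ cells) is close
to the 1.37% the independence metric predicts from their single-marker
scores alone; across 40 patients the observed and predicted extents of all
eight subpopulations correlate at Spearman ρ ≥ 0.987. The pooled Cox model
estimates HR 1.30 per 5%-unit of `M+2+6-` extent (the generator's true
value is 1.3), with τ² = 0 between the two sub-cohorts; at this small n the
Bonferroni-corrected p is not significant, as expected.

## The analysis workflow

The numbered drivers under `analysis/` run the whole study on synthetic
cohorts and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # cohorts + ground truth
Rscript analysis/02_quantify.R      # positivity, extents, field stability
Rscript analysis/03_spatial.R       # PCF, Δ%, interaction matrices, clustering
Rscript analysis/04_metric.R        # marginal correlations, concordance
Rscript analysis/05_map_mrna.R      # consensus eCDFs, inferred metrics
Rscript analysis/06_survival.R      # Cox units, PM pooling, KM, cutoff scan
Rscript analysis/07_transcriptome.R # pooled gene correlates, single cell
```

Each script prints what it found (e.g. `02` reports the mean absolute error
of observed vs true `M+2+6-` extent; `06` reports the strongest pooled
association and the 15%-cutoff Kaplan-Meier log-rank p). Intermediate
cohort files are cached under `scratch/`.

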