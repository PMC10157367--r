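#!/usr/bin/env Rscript
# Simulate the synthetic mfIHC cohorts used throughout the analysis and
# export them in the plain-text exchange formats (CSV/TSV/JSON/YAML).

source("analysis/00_common.R")

coh <- get_cohort(main_config(), "cohort_main")
sp <- get_cohort(spatial_config(), "cohort_spatial")

write_cohort(coh, file.path(SCRATCH_DIR, "cohort_main"))
write_cohort(sp, file.path(SCRATCH_DIR, "cohort_spatial"))

truth <- data.frame(
  patient_id = coh$truth$patient_id,
  pM_true = 100 * coh$truth$marginals_frac[, "myc"],
  p2_true = 100 * coh$truth$marginals_frac[, "bcl2"],
  p6_true = 100 * coh$truth$marginals_frac[, "bcl6"],
  m2p6n_true = coh$truth$true_m2p6n_extent_pct
)
write.csv(truth, file.path(RESULTS_DIR, "01_truth_marginals.csv"),
          row.names = FALSE)

cat(sprintf("main cohort: %d patients, %d cells, %d images\n",
            coh$config$n_patients, nrow(coh$cells),
            length(unique(coh$cells$image_id))))
cat(sprintf("spatial cohort: %d patients, %d cells (Thomas sigma %g um)\n",
            sp$config$n_patients, nrow(sp$cells),
            sp$config$thomas_params$sigma_um))
cat(sprintf("true M+2+6- extent: median %.1f%%, IQR %.1f-%.1f%%\n",
            median(truth$m2p6n_true),
            quantile(truth$m2p6n_true, 0.25),
            quantile(truth$m2p6n_true, 0.75)))
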