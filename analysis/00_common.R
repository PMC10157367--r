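# Shared setup for the analysis drivers: the study-condition cohort
# configuration and a cached cohort under scratch/ so the numbered scripts
# can be run in sequence or individually.

suppressPackageStartupMessages(library(coexcell))

RESULTS_DIR <- "results"
SCRATCH_DIR <- "scratch"
dir.create(RESULTS_DIR, showWarnings = FALSE)
dir.create(SCRATCH_DIR, showWarnings = FALSE)

# Main cohort: independent (stochastic) coexpression, two 1400 x 1000 um
# fields per patient, ~10% CD20-negative background cells.
main_config <- function(seed = 2023) {
  synthetic_config(
    n_patients = 60,
    cores_per_patient = 2,
    cells_per_core = 600,
    dependence_mode = "independent",
    spatial_process = "csr",
    mrna_model = list(link = "affine", intercept = 3, slope = 0.1,
                      noise_sd = 0.2, n_noise_genes = 20),
    seed = seed
  )
}

# Spatially clustered cohort for the interaction analyses (Thomas process).
spatial_config <- function(seed = 2024) {
  synthetic_config(
    n_patients = 6,
    cores_per_patient = 2,
    cells_per_core = 1200,
    spatial_process = "thomas",
    thomas_params = list(parent_per_mm2 = 40, sigma_um = 15),
    seed = seed
  )
}

get_cohort <- function(config, name) {
  cache <- file.path(SCRATCH_DIR, paste0(name, ".rds"))
  if (file.exists(cache)) return(readRDS(cache))
  coh <- generate_cohort(config)
  saveRDS(coh, cache)
  coh
}
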