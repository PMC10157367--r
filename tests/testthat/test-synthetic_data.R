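test_that("independent mode matches product of marginals at 1e5 cells", {
  cfg <- synthetic_config(n_patients = 1, cores_per_patient = 1,
                          cells_per_core = 1e5, background_frac = 0,
                          fixed_marginals = c(0.5, 0.4, 0.2), seed = 2)
  coh <- generate_cohort(cfg)
  flagged <- call_positivity(coh$cells, coh$thresholds)
  freq <- table(factor(flagged$pattern, levels = subpop_patterns()))
  # M+2+6- close to 0.5 * 0.4 * 0.8 = 16%
  expect_equal(unname(freq[["M+2+6-"]]) / 1e5, 0.16, tolerance = 0.05)
  # chi-square goodness of fit against the product law not rejected
  expected <- true_pattern_probs(c(0.5, 0.4, 0.2), "independent")
  gof <- chisq.test(as.numeric(freq), p = expected)
  expect_gt(gof$p.value, 0.01)
})

test_that("exclusive mode yields no double-positive cells and errors when infeasible", {
  cfg <- synthetic_config(n_patients = 2, cores_per_patient = 1,
                          cells_per_core = 2000, background_frac = 0,
                          dependence_mode = "exclusive",
                          fixed_marginals = c(0.3, 0.3, 0.3), seed = 4)
  coh <- generate_cohort(cfg)
  flagged <- call_positivity(coh$cells, coh$thresholds)
  n_pos <- flagged$myc_pos + flagged$bcl2_pos + flagged$bcl6_pos
  expect_true(all(n_pos <= 1))

  bad <- synthetic_config(n_patients = 1, dependence_mode = "exclusive",
                          fixed_marginals = c(0.5, 0.4, 0.3), seed = 4)
  expect_error(generate_cohort(bad), "P001")
})

test_that("interdependent mode is comonotone: positivity is nested", {
  cfg <- synthetic_config(n_patients = 1, cores_per_patient = 1,
                          cells_per_core = 5000, background_frac = 0,
                          dependence_mode = "interdependent",
                          fixed_marginals = c(0.2, 0.6, 0.4), seed = 8)
  coh <- generate_cohort(cfg)
  fl <- call_positivity(coh$cells, coh$thresholds)
  # marginals ordered bcl2 > bcl6 > myc: a MYC+ cell must be BCL2+ and BCL6+
  expect_true(all(!fl$myc_pos | (fl$bcl2_pos & fl$bcl6_pos)))
  expect_true(all(!fl$bcl6_pos | fl$bcl2_pos))
})

test_that("same config and seed give identical cohorts", {
  cfg <- synthetic_config(n_patients = 3, cells_per_core = 100, seed = 33)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
})

test_that("thresholding the emitted intensities reproduces intended flags", {
  cfg <- synthetic_config(n_patients = 2, cells_per_core = 500,
                          threshold_jitter = 0.05, seed = 12)
  coh <- generate_cohort(cfg)
  flagged <- call_positivity(coh$cells, coh$thresholds)
  prof <- patient_extents(flagged)$profiles
  # truth states were drawn before intensity emission; frequencies must agree
  # to binomial error (no threshold misclassification on top)
  obs <- prof[["M+2+6-"]] / 100
  tru <- coh$truth$pattern_probs[, "M+2+6-"]
  n_b <- prof$n_cells
  expect_true(all(abs(obs - tru) < 4 * sqrt(tru * (1 - tru) / n_b) + 0.01))
  # CD20 background fraction close to configured 10%
  expect_lt(abs(mean(!flagged$cd20_pos) - 0.10), 0.02)
})

test_that("CSR nearest-neighbour distances match the analytic Poisson form", {
  set.seed(14)
  n <- 1e4
  w <- c(2000, 2000)
  pts <- sim_points(n, w)
  # nearest neighbour distance for each point (interior points only, to
  # avoid edge effects in the analytic comparison)
  d2 <- as.matrix(dist(cbind(pts$x_um, pts$y_um)))
  diag(d2) <- Inf
  nn <- apply(d2, 1, min)
  interior <- pts$x_um > 100 & pts$x_um < 1900 & pts$y_um > 100 & pts$y_um < 1900
  lambda <- n / prod(w)
  # G(r) = 1 - exp(-lambda * pi * r^2)
  # mutual nearest neighbours duplicate a few distances; the KS tie warning
  # is expected and immaterial at n = 1e4
  ks <- suppressWarnings(
    ks.test(nn[interior], function(r) 1 - exp(-lambda * pi * r^2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("thomas process produces visibly clustered patterns", {
  set.seed(15)
  pts <- sim_points(2000, c(1000, 1000), "thomas",
                    list(parent_per_mm2 = 40, sigma_um = 15))
  pp <- point_pattern(pts$x_um, pts$y_um, window = c(1000, 1000))
  g <- estimate_pcf(pp)
  expect_gt(mean(g$g[g$r <= 20]), 1.5)
})

test_that("cohorts round-trip to disk in plain-text formats", {
  cfg <- synthetic_config(n_patients = 2, cells_per_core = 50, seed = 9,
                          mrna_model = list(link = "affine", intercept = 3,
                                            slope = 0.1, noise_sd = 0.2,
                                            n_noise_genes = 5))
  coh <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(all(file.exists(file.path(dir,
    c("cells.csv", "thresholds.csv", "survival.csv", "expression.tsv",
      "truth.json", "config.yaml")))))
  cells2 <- read_cell_table(file.path(dir, "cells.csv"))
  expect_equal(nrow(cells2), nrow(coh$cells))
  expr2 <- read_expression_tsv(file.path(dir, "expression.tsv"))
  expect_equal(dim(expr2), dim(coh$expression))
  expect_equal(unname(expr2["MYC", ]), unname(coh$expression["MYC", ]),
               tolerance = 1e-6)
  cfg2 <- yaml::read_yaml(file.path(dir, "config.yaml"))
  expect_equal(cfg2$n_patients, 2)
})
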