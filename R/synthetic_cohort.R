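#' Configuration for a synthetic multiplexed-IHC cohort
#'
#' Bundles every knob of the synthetic cohort generator: cohort layout
#' (patients, cores, cells), patient-level marker marginal priors, the
#' per-cell dependence structure of MYC/BCL2/BCL6 co-positivity, the spatial
#' point process used to place cells in a core, the intensity/threshold
#' model, the survival model linked to the true M+2+6- extent, and the
#' mRNA link. Defaults emulate a two-core tissue-microarray cohort imaged
#' in 1400 x 1000 um fields with roughly stochastic (independent) oncogene
#' coexpression, the regime the downstream independence metric assumes.
#'
#' @param n_patients Number of patients.
#' @param cores_per_patient Cores (= images) per patient; a single count or a
#'   `c(min, max)` range sampled per patient.
#' @param cells_per_core Cells per core; a single count or a range.
#' @param marker_marginal_priors Named list `myc`/`bcl2`/`bcl6` of
#'   `c(shape1, shape2)` Beta parameters for the patient-level positivity
#'   fractions.
#' @param fixed_marginals Optional override of the priors: a length-3 vector
#'   (shared by all patients) or an `n_patients` x 3 matrix of fractions
#'   (MYC, BCL2, BCL6 order).
#' @param dependence_mode `"independent"` (product of marginals per cell),
#'   `"interdependent"` (a shared per-cell latent uniform drives all three
#'   markers: comonotone, maximal positive dependence) or `"exclusive"`
#'   (at most one marker positive per cell).
#' @param spatial_process `"csr"` (uniform placement) or `"thomas"`
#'   (Thomas cluster process with fixed total count).
#' @param thomas_params List: `parent_per_mm2` (parent intensity per mm^2),
#'   `sigma_um` (Gaussian cluster dispersion, um). Offspring are the core's
#'   cells assigned uniformly to parents, so the mean offspring count per
#'   parent is `cells_per_core / n_parents`.
#' @param window_um `c(width, height)` of the imaging field in um.
#' @param background_frac Fraction of CD20-negative non-B "background" cells.
#' @param intensity_model Per-marker list of `meanlog_neg`, `meanlog_pos`,
#'   `sdlog` for the log-normal negative/positive intensity components.
#' @param threshold_jitter Per-image thresholds are the mixture crossing
#'   point (geometric mean of the component medians) jittered uniformly by
#'   this relative amount (default +/-5%).
#' @param survival_model List: `baseline_hazard` (events/month at unit 0),
#'   `log_hr_per_unit` (true log hazard ratio per 5%-unit of M+2+6- extent),
#'   `censoring_frac` (approximate random-censoring fraction, in \[0,1)),
#'   `max_followup_months` (administrative censoring).
#' @param mrna_model List: `link` (`"affine"` or `"log"`, both monotone),
#'   `intercept`, `slope`, `noise_sd` (Gaussian noise on the linked value)
#'   and `n_noise_genes` (extra unlinked genes rows).
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return A `synthetic_config` list, validated.
#' @export
synthetic_config <- function(n_patients = 150,
                             cores_per_patient = 2,
                             cells_per_core = 1000,
                             marker_marginal_priors = list(
                               myc = c(2, 4), bcl2 = c(3, 2), bcl6 = c(2, 3)),
                             fixed_marginals = NULL,
                             dependence_mode = c("independent", "interdependent", "exclusive"),
                             spatial_process = c("csr", "thomas"),
                             thomas_params = list(parent_per_mm2 = 50, sigma_um = 15),
                             window_um = c(width = 1400, height = 1000),
                             background_frac = 0.10,
                             intensity_model = default_intensity_model(),
                             threshold_jitter = 0.05,
                             survival_model = list(baseline_hazard = 0.01,
                                                   log_hr_per_unit = log(1.3),
                                                   censoring_frac = 0.25,
                                                   max_followup_months = 120),
                             mrna_model = list(link = "affine", intercept = 3,
                                               slope = 0.1, noise_sd = 0.2,
                                               n_noise_genes = 0),
                             seed = 1L) {
  dependence_mode <- match.arg(dependence_mode)
  spatial_process <- match.arg(spatial_process)
  stopifnot(n_patients >= 1,
            all(cores_per_patient >= 1), length(cores_per_patient) %in% 1:2,
            all(cells_per_core >= 1), length(cells_per_core) %in% 1:2,
            background_frac >= 0, background_frac < 1,
            threshold_jitter >= 0, threshold_jitter < 1,
            thomas_params$sigma_um > 0, thomas_params$parent_per_mm2 > 0,
            length(window_um) == 2, all(window_um > 0),
            survival_model$censoring_frac >= 0, survival_model$censoring_frac < 1,
            survival_model$baseline_hazard > 0,
            survival_model$max_followup_months > 0)
  if (!is.null(fixed_marginals)) {
    fm <- if (is.matrix(fixed_marginals)) fixed_marginals
          else matrix(fixed_marginals, nrow = n_patients, ncol = 3, byrow = TRUE)
    stopifnot(ncol(fm) == 3, nrow(fm) == n_patients,
              all(fm >= 0), all(fm <= 1))
    fixed_marginals <- fm
  }
  structure(list(
    n_patients = as.integer(n_patients),
    cores_per_patient = cores_per_patient,
    cells_per_core = cells_per_core,
    marker_marginal_priors = marker_marginal_priors,
    fixed_marginals = fixed_marginals,
    dependence_mode = dependence_mode,
    spatial_process = spatial_process,
    thomas_params = thomas_params,
    window_um = c(width = unname(window_um[1]), height = unname(window_um[2])),
    background_frac = background_frac,
    intensity_model = intensity_model,
    threshold_jitter = threshold_jitter,
    survival_model = survival_model,
    mrna_model = mrna_model,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Default log-normal intensity components per marker
#' @return Named list of per-marker component parameters.
#' @export
default_intensity_model <- function() {
  one <- list(meanlog_neg = log(1), meanlog_pos = log(8), sdlog = 0.5)
  list(cd20 = one, myc = one, bcl2 = one, bcl6 = one, ki67 = one)
}

#' True pattern probabilities implied by marginals and a dependence mode
#'
#' @param p Length-3 vector of positivity fractions (MYC, BCL2, BCL6).
#' @param mode Dependence mode (see [synthetic_config()]).
#' @return Named length-8 probability vector in [subpop_patterns()] order.
#' @export
true_pattern_probs <- function(p, mode = c("independent", "interdependent", "exclusive")) {
  mode <- match.arg(mode)
  stopifnot(length(p) == 3, all(p >= 0), all(p <= 1))
  pats <- subpop_patterns()
  fl <- pattern_flags(pats)
  out <- switch(mode,
    independent = vapply(seq_along(pats), function(j) {
      prod(ifelse(fl[j, ], p, 1 - p))
    }, numeric(1)),
    interdependent = vapply(seq_along(pats), function(j) {
      # marker k positive iff shared u < p_k
      lo <- if (any(!fl[j, ])) max(p[!fl[j, ]]) else 0
      hi <- if (any(fl[j, ])) min(p[fl[j, ]]) else 1
      max(0, hi - lo)
    }, numeric(1)),
    exclusive = {
      if (sum(p) > 1) stop("exclusive mode infeasible: marginals sum to more than 1")
      v <- numeric(8)
      v[match(c("M+2-6-", "M-2+6-", "M-2-6+", "M-2-6-"), pats)] <-
        c(p[1], p[2], p[3], 1 - sum(p))
      v
    })
  names(out) <- pats
  out
}

# Draw per-cell joint (MYC, BCL2, BCL6) states for one patient.
draw_joint_states <- function(n, p, mode) {
  if (mode == "independent") {
    cbind(myc = stats::runif(n) < p[1],
          bcl2 = stats::runif(n) < p[2],
          bcl6 = stats::runif(n) < p[3])
  } else if (mode == "interdependent") {
    u <- stats::runif(n)
    cbind(myc = u < p[1], bcl2 = u < p[2], bcl6 = u < p[3])
  } else {
    probs <- c(p, 1 - sum(p))
    state <- sample.int(4, n, replace = TRUE, prob = probs)
    cbind(myc = state == 1L, bcl2 = state == 2L, bcl6 = state == 3L)
  }
}

#' Simulate cell positions in a rectangular window
#'
#' @param n Number of points.
#' @param window `c(width, height)` in um.
#' @param process `"csr"` for uniform placement, `"thomas"` for a Thomas
#'   cluster process with the total count fixed at `n` (parents Poisson over
#'   the window, offspring displaced by an isotropic Gaussian and reflected
#'   at the window edges).
#' @param thomas_params List with `parent_per_mm2` and `sigma_um`.
#' @return Data frame with `x_um`, `y_um`.
#' @export
sim_points <- function(n, window = c(1400, 1000), process = c("csr", "thomas"),
                       thomas_params = list(parent_per_mm2 = 50, sigma_um = 15)) {
  process <- match.arg(process)
  w <- window[1]; h <- window[2]
  if (process == "csr") {
    return(data.frame(x_um = stats::runif(n, 0, w), y_um = stats::runif(n, 0, h)))
  }
  area_mm2 <- w * h / 1e6
  n_parents <- max(1L, stats::rpois(1, thomas_params$parent_per_mm2 * area_mm2))
  px <- stats::runif(n_parents, 0, w)
  py <- stats::runif(n_parents, 0, h)
  parent <- sample.int(n_parents, n, replace = TRUE)
  x <- px[parent] + stats::rnorm(n, sd = thomas_params$sigma_um)
  y <- py[parent] + stats::rnorm(n, sd = thomas_params$sigma_um)
  data.frame(x_um = reflect_into(x, w), y_um = reflect_into(y, h))
}

# Reflect coordinates into [0, len] (repeatedly, for far excursions).
reflect_into <- function(x, len) {
  x <- x %% (2 * len)
  ifelse(x > len, 2 * len - x, x)
}

# Truncated log-normal draws: above (positive) or at/below (negative) a
# threshold, via inverse-CDF sampling. Guarantees thresholding reproduces
# the intended flags exactly.
rlnorm_trunc <- function(n, meanlog, sdlog, threshold, above) {
  if (n == 0L) return(numeric(0))
  f <- stats::plnorm(threshold, meanlog, sdlog)
  u <- if (above) stats::runif(n, min = f, max = 1) else stats::runif(n, min = 0, max = f)
  # guard against u == 1 / 0 rounding onto the boundary
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  x <- stats::qlnorm(u, meanlog, sdlog)
  if (above) pmax(x, threshold * (1 + 1e-9)) else pmin(x, threshold)
}

#' Simulate survival under a proportional-hazards model on 5%-units
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(log_hr_per_unit * extent_to_units(extent))`, so the
#' proportional-hazards assumption holds exactly on the unit scale.
#' Censoring combines an independent exponential censoring process
#' calibrated so that roughly `censoring_frac` of patients are censored at
#' the baseline hazard, and administrative censoring at
#' `max_followup_months`.
#'
#' @param extent_pct Per-patient true M+2+6- extents (%).
#' @param baseline_hazard Events per month at unit 0.
#' @param log_hr_per_unit True log hazard ratio per 5%-unit.
#' @param censoring_frac Target random-censoring fraction in \[0, 1).
#' @param max_followup_months Administrative censoring time.
#' @return Data frame: `os_months`, `os_event` (1 = death), `units`.
#' @export
sim_survival <- function(extent_pct, baseline_hazard = 0.01,
                         log_hr_per_unit = log(1.3), censoring_frac = 0.25,
                         max_followup_months = 120) {
  n <- length(extent_pct)
  units <- extent_to_units(extent_pct)
  hazard <- baseline_hazard * exp(log_hr_per_unit * units)
  t_event <- stats::rexp(n, rate = hazard)
  t_cens <- if (censoring_frac > 0) {
    stats::rexp(n, rate = baseline_hazard * censoring_frac / (1 - censoring_frac))
  } else rep(Inf, n)
  t_cens <- pmin(t_cens, max_followup_months)
  data.frame(os_months = pmin(t_event, t_cens),
             os_event = as.integer(t_event <= t_cens),
             units = units)
}

#' Generate a synthetic cohort
#'
#' Draws patient-level marker marginals from the configured priors, assigns
#' each cell a joint MYC/BCL2/BCL6 state under the configured dependence
#' mode, places cells by the configured point process, emits intensities from
#' truncated log-normal components so that per-image thresholding reproduces
#' the intended flags exactly, links survival to the patient's true M+2+6-
#' extent through an exponential proportional-hazards model on 5%-units, and
#' links per-marker mRNA monotonically to the true marginals with Gaussian
#' noise. Fully deterministic given `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return List with `cells` (cell table), `thresholds` (per-image, per-marker),
#'   `survival` (per patient: `os_months`, `os_event`, `ipi_group`,
#'   `myc_fish`), `expression` (genes x samples matrix; rows `MYC`, `BCL2`,
#'   `BCL6` plus any noise genes), `truth` (per-patient latent values), and
#'   the `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  np <- config$n_patients
  priors <- config$marker_marginal_priors

  marg <- if (!is.null(config$fixed_marginals)) config$fixed_marginals else
    cbind(stats::rbeta(np, priors$myc[1], priors$myc[2]),
          stats::rbeta(np, priors$bcl2[1], priors$bcl2[2]),
          stats::rbeta(np, priors$bcl6[1], priors$bcl6[2]))
  colnames(marg) <- c("myc", "bcl2", "bcl6")

  if (config$dependence_mode == "exclusive") {
    bad <- which(rowSums(marg) > 1)
    if (length(bad)) {
      stop("exclusive mode infeasible (marginals sum > 1) for patient(s): ",
           paste(sprintf("P%03d", bad), collapse = ", "))
    }
  }

  draw_count <- function(spec) {
    if (length(spec) == 2L) sample(seq.int(spec[1], spec[2]), 1L) else as.integer(spec)
  }

  cells_list <- vector("list", np)
  thr_list <- vector("list", np)
  truth_probs <- matrix(NA_real_, np, 8,
                        dimnames = list(NULL, subpop_patterns()))
  markers <- c("cd20", "myc", "bcl2", "bcl6", "ki67")
  im <- config$intensity_model

  for (i in seq_len(np)) {
    pid <- sprintf("P%03d", i)
    p <- marg[i, ]
    truth_probs[i, ] <- true_pattern_probs(p, config$dependence_mode)
    n_cores <- draw_count(config$cores_per_patient)
    per_core <- vector("list", n_cores)
    per_thr <- vector("list", n_cores)
    for (cc in seq_len(n_cores)) {
      img <- sprintf("%s_core%d", pid, cc)
      n <- draw_count(config$cells_per_core)
      pos <- sim_points(n, config$window_um, config$spatial_process,
                        config$thomas_params)
      is_b <- stats::runif(n) >= config$background_frac
      states <- draw_joint_states(n, p, config$dependence_mode)
      states[!is_b, ] <- FALSE   # background cells carry no oncogene positivity
      # Ki-67 proliferation enriched in BCL6-positive cells
      ki67 <- is_b & (stats::runif(n) < ifelse(states[, "bcl6"], 0.6, 0.2))
      flags <- cbind(cd20 = is_b, states, ki67 = ki67)

      thr <- vapply(markers, function(m) {
        cross <- exp((im[[m]]$meanlog_neg + im[[m]]$meanlog_pos) / 2)
        cross * stats::runif(1, 1 - config$threshold_jitter,
                             1 + config$threshold_jitter)
      }, numeric(1))
      intens <- sapply(markers, function(m) {
        out <- numeric(n)
        k <- flags[, m]
        out[k] <- rlnorm_trunc(sum(k), im[[m]]$meanlog_pos, im[[m]]$sdlog,
                               thr[[m]], above = TRUE)
        out[!k] <- rlnorm_trunc(sum(!k), im[[m]]$meanlog_neg, im[[m]]$sdlog,
                                thr[[m]], above = FALSE)
        out
      })
      per_core[[cc]] <- data.frame(patient_id = pid, core_id = img,
                                   image_id = img,
                                   x_um = pos$x_um, y_um = pos$y_um,
                                   intens, stringsAsFactors = FALSE)
      per_thr[[cc]] <- data.frame(image_id = img, marker = markers,
                                  threshold = unname(thr),
                                  stringsAsFactors = FALSE)
    }
    cells_list[[i]] <- do.call(rbind, per_core)
    thr_list[[i]] <- do.call(rbind, per_thr)
  }

  cells <- do.call(rbind, cells_list)
  thresholds <- do.call(rbind, thr_list)
  rownames(cells) <- rownames(thresholds) <- NULL

  # --- survival linked to the true M+2+6- extent -------------------------
  sm <- config$survival_model
  true_extent <- 100 * truth_probs[, "M+2+6-"]
  units <- extent_to_units(true_extent)
  survival <- cbind(
    patient_id = sprintf("P%03d", seq_len(np)),
    sim_survival(true_extent,
                 baseline_hazard = sm$baseline_hazard,
                 log_hr_per_unit = sm$log_hr_per_unit,
                 censoring_frac = sm$censoring_frac,
                 max_followup_months = sm$max_followup_months),
    ipi_group = sample(c("Low", "Intermediate", "High"), np, replace = TRUE,
                       prob = c(0.3, 0.45, 0.25)),
    myc_fish = sample(c("Negative", "Positive"), np, replace = TRUE,
                      prob = c(0.85, 0.15))
  )

  # --- mRNA monotonically linked to the true marginals -------------------
  mm <- config$mrna_model
  link <- function(x_pct) {
    switch(mm$link,
           affine = mm$intercept + mm$slope * x_pct,
           log = mm$intercept + mm$slope * log1p(x_pct),
           stop("unknown mrna link: ", mm$link))
  }
  expr <- rbind(
    MYC = link(100 * marg[, "myc"]) + stats::rnorm(np, sd = mm$noise_sd),
    BCL2 = link(100 * marg[, "bcl2"]) + stats::rnorm(np, sd = mm$noise_sd),
    BCL6 = link(100 * marg[, "bcl6"]) + stats::rnorm(np, sd = mm$noise_sd)
  )
  if (mm$n_noise_genes > 0) {
    noise <- matrix(stats::rnorm(mm$n_noise_genes * np), mm$n_noise_genes, np)
    rownames(noise) <- sprintf("GENE%04d", seq_len(mm$n_noise_genes))
    expr <- rbind(expr, noise)
  }
  colnames(expr) <- survival$patient_id

  truth <- list(
    marginals_frac = marg,
    pattern_probs = truth_probs,
    true_m2p6n_extent_pct = unname(true_extent),
    units = unname(units),
    log_hr_per_unit = sm$log_hr_per_unit,
    patient_id = survival$patient_id
  )
  list(cells = cells, thresholds = thresholds, survival = survival,
       expression = expr, truth = truth, config = config)
}

#' Write a synthetic cohort to disk
#'
#' Cell, threshold and survival tables as CSV; the expression matrix as TSV
#' (genes x samples); the truth record as JSON; the configuration as YAML.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$cells, file.path(dir, "cells.csv"), row.names = FALSE)
  utils::write.csv(cohort$thresholds, file.path(dir, "thresholds.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$survival, file.path(dir, "survival.csv"),
                   row.names = FALSE)
  utils::write.table(cohort$expression, file.path(dir, "expression.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  truth <- cohort$truth
  truth$marginals_frac <- as.data.frame(truth$marginals_frac)
  truth$pattern_probs <- as.data.frame(truth$pattern_probs)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- cohort$config
  cfg$fixed_marginals <- if (is.null(cfg$fixed_marginals)) NULL else
    as.data.frame(cfg$fixed_marginals)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
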