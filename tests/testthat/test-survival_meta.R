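test_that("5%-unit binning has the compressed first unit and closed right edges", {
  expect_identical(extent_to_units(c(0, 0.5, 1)), c(0L, 0L, 0L))
  expect_identical(extent_to_units(c(1.01, 5)), c(1L, 1L))
  expect_identical(extent_to_units(c(5.01, 7, 10)), c(2L, 2L, 2L))
  expect_identical(extent_to_units(c(16, 100)), c(4L, 20L))
  expect_error(extent_to_units(101), "\\[0, 100\\]")
  # monotone nondecreasing and surjective onto 0..20
  x <- seq(0, 100, by = 0.25)
  u <- extent_to_units(x)
  expect_true(all(diff(u) >= 0))
  expect_identical(sort(unique(u)), 0:20)
})

test_that("fit_cox estimates the unit effect and guards degenerate input", {
  set.seed(61)
  extents <- runif(400, 0, 40)
  surv <- sim_survival(extents, log_hr_per_unit = log(1.3))
  fit <- fit_cox(surv$units, surv$os_months, surv$os_event)
  expect_equal(fit$hr, 1.3, tolerance = 0.15)
  expect_equal(fit$ci95_lo, exp(fit$log_hr - 1.96 * fit$se))
  expect_error(fit_cox(rep(2, 10), rexp(10), rep(0, 10)), "no events")
  expect_error(fit_cox(rep(2, 10), rexp(10), rep(1, 10)), "constant")
})

test_that("multivariate adjustment keeps the unit effect with complete cases", {
  set.seed(62)
  extents <- runif(300, 0, 40)
  surv <- sim_survival(extents, log_hr_per_unit = log(1.4))
  ipi <- sample(c("Low", "Intermediate", "High"), 300, replace = TRUE)
  fish <- sample(c("Negative", "Positive", NA), 300, replace = TRUE,
                 prob = c(0.7, 0.2, 0.1))
  fit <- fit_cox(surv$units, surv$os_months, surv$os_event,
                 ipi_group = ipi, myc_fish = fish)
  expect_lt(fit$n, 300)  # complete-case
  expect_equal(fit$hr, 1.4, tolerance = 0.2)
})

test_that("Paule-Mandel pooling matches the grid-search oracle", {
  # identical fits: tau2 = 0, passthrough of the common effect
  same <- data.frame(log_hr = rep(0.3, 3), se = rep(0.1, 3))
  p <- pool_random_effects(same)
  expect_equal(p$pooled_log_hr, 0.3)
  expect_equal(p$tau2, 0)
  # the spec'd two-study instance against the brute-force oracle
  two <- data.frame(log_hr = c(0.26, 0.47), se = c(0.10, 0.19))
  p2 <- pool_random_effects(two)
  oracle <- pm_grid_oracle(two$log_hr, two$se, step = 1e-6)
  expect_lt(abs(p2$pooled_log_hr - oracle[["pooled"]]), 1e-5)
  # 20 random instances, k in 2..8
  set.seed(63)
  for (i in 1:20) {
    k <- sample(2:8, 1)
    theta <- rnorm(k, 0.2, 0.25)
    se <- runif(k, 0.05, 0.3)
    got <- pool_random_effects(data.frame(log_hr = theta, se = se))
    want <- pm_grid_oracle(theta, se, step = 1e-6)
    expect_lt(abs(got$pooled_log_hr - want[["pooled"]]), 1e-5)
  }
})

test_that("Paule-Mandel agrees with metafor's implementation", {
  skip_if_not_installed("metafor")
  set.seed(64)
  theta <- rnorm(5, 0.3, 0.2)
  se <- runif(5, 0.08, 0.25)
  got <- pool_random_effects(data.frame(log_hr = theta, se = se))
  ref <- metafor::rma(yi = theta, sei = se, method = "PM")
  expect_equal(got$pooled_log_hr, as.numeric(ref$beta), tolerance = 1e-4)
  expect_equal(got$tau2, ref$tau2, tolerance = 1e-3)
})

test_that("pooling edge cases: single fit, bad se, Bonferroni cap", {
  one <- data.frame(log_hr = 0.5, se = 0.2)
  p <- pool_random_effects(one)
  expect_equal(p$pooled_log_hr, 0.5)
  expect_equal(p$pooled_se, 0.2)
  expect_equal(p$tau2, 0)
  expect_error(pool_random_effects(data.frame(log_hr = c(1, 2), se = c(0.1, 0))),
               "positive")
  null_fit <- data.frame(log_hr = c(0.01, -0.01), se = c(0.5, 0.5))
  expect_equal(pool_random_effects(null_fit)$bonferroni_p, 1)
  # Stouffer alternative returns a valid p
  ps <- pool_random_effects(null_fit, p_method = "stouffer")
  expect_true(ps$pooled_p > 0 && ps$pooled_p <= 1)
})

test_that("KM curves start at 1 and the log-rank test behaves", {
  set.seed(65)
  t1 <- rexp(50, 0.02); t2 <- rexp(50, 0.02)
  # identical times/events in both groups -> chi-square 0, p = 1
  km <- km_logrank(c(t1, t1), rep(1, 100), rep(c("a", "b"), each = 50))
  expect_equal(km$logrank_p, 1)
  for (grp in c("a", "b")) {
    cur <- km$curves[km$curves$group == grp, ]
    expect_lte(max(cur$surv), 1)
  }
  expect_error(km_logrank(t1, rep(1, 50), rep("a", 50)), "2 non-empty")
  # hazard ratio 3 between groups: strong separation
  set.seed(66)
  reps <- replicate(20, {
    ta <- rexp(200, 0.01); tb <- rexp(200, 0.03)
    km_logrank(c(ta, tb), rep(1, 400), rep(c("a", "b"), each = 200))$logrank_p
  })
  expect_gte(mean(reps < 0.01), 0.95)
})

test_that("cutoff scan grid includes 15 and honours the group-size guard", {
  set.seed(67)
  extents <- runif(200, 0, 30)
  surv <- sim_survival(extents, log_hr_per_unit = 0)
  res <- scan_cutoff(extents, surv$os_months, surv$os_event)
  expect_true(15 %in% res$table$cutoff)
  frac_high <- res$table$n_high / 200
  expect_true(all(frac_high >= 0.1 & frac_high <= 0.9))
  expect_error(scan_cutoff(extents[1:10], surv$os_months[1:10],
                           surv$os_event[1:10]), "20 patients")
})

test_that("under the null few scanned cutoffs exclude HR = 1", {
  set.seed(68)
  frac_signif <- replicate(15, {
    extents <- runif(120, 0, 30)
    surv <- sim_survival(extents, log_hr_per_unit = 0)
    tab <- scan_cutoff(extents, surv$os_months, surv$os_event)$table
    mean(tab$ci95_lo > 1 | tab$ci95_hi < 1)
  })
  expect_lt(mean(frac_signif), 0.15)
})
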